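# Shared helpers: total-variation distance, embedding a joint table into a
# larger rectangle, and rate choices for the oracle networks (k_minus = 1
# sets the time unit; k_plus = 1/K_d).

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# embed a joint_dist into a full rectangle [0, n1-1] x [0, n2-1]
embed_joint <- function(j, n1, n2) {
  out <- matrix(0, n1, n2)
  out[j$o1 + seq_len(nrow(j$p)), j$o2 + seq_len(ncol(j$p))] <- j$p
  out
}

# embed a discrete_dist into 0..(n-1)
embed_dist <- function(d, n) {
  out <- numeric(n)
  out[d$offset + seq_along(d$probs)] <- d$probs
  out
}

net_single <- function(K_d) network_single_target(1 / K_d, 1)
net_two <- function(K1_d, K2_d) network_two_target(1 / K1_d, 1, 1 / K2_d, 1)
net_inhib <- function(K_d, a, k_cat = 0)
  network_inhibition(1 / K_d, 1, a, 1, k_cat = k_cat)
net_two_enz <- function(K1_d, K2_d, a1, a2)
  network_two_enzyme(list(k_plus = 1 / K1_d, k_minus = 1, k_f_cs = a1, k_r = 1),
                     list(k_plus = 1 / K2_d, k_minus = 1, k_f_cs = a2, k_r = 1))

# Gaussian extrinsic noise shorthand
gnoise <- function(mean, sigma) noise_spec("gaussian", mean = mean, sigma = sigma)
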