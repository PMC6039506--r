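#' Quasi-equilibrium joint steady state of competitive inhibition
#'
#' State `(T_A, C)`: active (substrate-bound) enzymes and inhibitor-bound
#' complexes, with free enzymes `T_F = T_T - T_A - C` and free inhibitor
#' `S = S_T - C`. With catalysis much slower than binding and activation,
#' the remaining network is reversible and detailed balance gives the
#' product form
#' `P(T_A, C) = a^T_A (1/K_d)^C T_T! / ((T_T - T_A - C)! T_A! C!) /
#'  (S_T - C)! / N`
#' on `T_A >= 0`, `C >= 0`, `T_A + C <= T_T`, `C <= S_T`. Both reversible
#' reactions satisfy detailed balance edge by edge (binding:
#' `(1/K_d) T_F (S_T - C) P(T_A, C) = (C + 1) P(T_A, C + 1)`; activation:
#' `a T_F P(T_A, C) = (T_A + 1) P(T_A + 1, C)`), which the test suite
#' asserts against this closed form and against the master-equation oracle.
#'
#' @param params an [inhibition_params()].
#' @return a [joint_dist()] with axes `(T_A, TS)`.
#' @export
inhibition_joint <- function(params) {
  stopifnot(inherits(params, "inhibition_params"))
  p <- params
  ta <- 0:p$T_T
  cc <- 0:min(p$T_T, p$S_T)
  lwa <- ta * log(p$a) - lgamma(ta + 1)
  lwc <- -cc * log(p$K_d) - lgamma(cc + 1) - lgamma(p$S_T - cc + 1)
  free <- outer(ta, cc, function(x, y) p$T_T - x - y)
  feas <- free >= 0
  logw <- outer(lwa, lwc, `+`) + lgamma(p$T_T + 1) -
    lgamma(pmax(free, 0) + 1)
  joint_from_logw(0L, 0L, logw, feas, axes = c("T_A", "TS"))
}

#' Marginal distributions of active and inhibitor-bound enzyme
#'
#' Marginals of the quasi-equilibrium joint over `(T_A, C)`, optionally
#' mixed over an extrinsic-noise law on the total inhibitor `S_T` by the law
#' of total probability.
#'
#' @param params an [inhibition_params()] (its `S_T` is ignored when `noise`
#'   is given).
#' @param noise optional [noise_spec()] or [discrete_dist()] over `S_T`.
#' @return list with elements `active` and `complex`, both
#'   [discrete_dist()].
#' @export
inhibition_marginals <- function(params, noise = NULL) {
  stopifnot(inherits(params, "inhibition_params"))
  if (is.null(noise)) {
    j <- inhibition_joint(params)
    return(list(active = joint_marginal(j, 1), complex = joint_marginal(j, 2)))
  }
  if (inherits(noise, "noise_spec")) noise <- discretise_noise(noise)
  svals <- dist_support(noise)
  acc_a <- numeric(params$T_T + 1L)
  acc_c <- numeric(min(params$T_T, max(svals)) + 1L)
  for (i in seq_along(svals)) {
    if (noise$probs[i] == 0) next
    pp <- params
    pp$S_T <- svals[i]
    j <- inhibition_joint(pp)
    acc_a <- acc_a + noise$probs[i] * rowSums(j$p)
    cs <- colSums(j$p)
    acc_c[seq_along(cs)] <- acc_c[seq_along(cs)] + noise$probs[i] * cs
  }
  list(active = discrete_dist(0L, acc_a / sum(acc_a)),
       complex = discrete_dist(0L, acc_c / sum(acc_c)))
}

#' Joint steady state of two enzyme species sharing one inhibitor
#'
#' Four-axis quasi-equilibrium distribution over
#' `(T_1A, C_1, T_2A, C_2)` with product-form weight
#' `a1^T_1A a2^T_2A (1/K1_d)^C_1 (1/K2_d)^C_2
#'  * prod_i T_iT! / ((T_iT - T_iA - C_i)! T_iA! C_i!)
#'  / (S_T - C_1 - C_2)!`
#' on the feasible set `T_iA + C_i <= T_iT`, `C_1 + C_2 <= S_T`. The dense
#' table is guarded by a configurable state-count cap. The `(T_1A, T_2A)`
#' projection is returned alongside for correlation and mutual-information
#' analyses.
#'
#' @param params a [two_enzyme_params()].
#' @param max_states cap on the dense table size (default `5e7`).
#' @return list of class `"two_enzyme_joint"` with the 4-axis probability
#'   array `p4` (dims `T_1A`, `C_1`, `T_2A`, `C_2`, all offset 0) and the
#'   projected [joint_dist()] `active`.
#' @export
two_enzyme_joint <- function(params, max_states = 5e7) {
  stopifnot(inherits(params, "two_enzyme_params"))
  p <- params
  n1a <- p$T_1T + 1L; nc1 <- min(p$T_1T, p$S_T) + 1L
  n2a <- p$T_2T + 1L; nc2 <- min(p$T_2T, p$S_T) + 1L
  n_states <- as.numeric(n1a) * nc1 * n2a * nc2
  if (n_states > max_states)
    stop("two-enzyme state space has ", format(n_states, big.mark = ","),
         " cells, exceeding max_states = ", format(max_states))
  l1 <- enzyme_log_block(p$T_1T, p$a1, p$K1_d, nc1)   # [T_1A, C_1]
  l2 <- enzyme_log_block(p$T_2T, p$a2, p$K2_d, nc2)   # [T_2A, C_2]
  cvals1 <- 0:(nc1 - 1L); cvals2 <- 0:(nc2 - 1L)
  csum <- outer(cvals1, cvals2, `+`)
  cross <- ifelse(csum <= p$S_T, -lgamma(pmax(p$S_T - csum, 0) + 1), -Inf)
  logw <- outer(l1, l2, `+`) +                         # [T1A, C1, T2A, C2]
    aperm(array(cross, dim = c(nc1, nc2, n1a, n2a)), c(3, 1, 4, 2))
  feas <- is.finite(logw)
  m <- max(logw[feas])
  p4 <- array(0, dim = dim(logw))
  p4[feas] <- exp(logw[feas] - m)
  p4 <- p4 / sum(p4)
  active <- joint_dist(0L, 0L, apply(p4, c(1, 3), sum),
                       axes = c("T_1A", "T_2A"))
  structure(list(p4 = p4, offsets = c(0L, 0L, 0L, 0L),
                 axes = c("T_1A", "C_1", "T_2A", "C_2"),
                 active = active, params = params),
            class = "two_enzyme_joint")
}

# Per-enzyme log-weight block over (T_A, C): activation, binding and
# multinomial occupancy terms; -Inf where T_A + C exceeds the total.
enzyme_log_block <- function(T_T, a, K_d, nc) {
  ta <- 0:T_T
  cc <- 0:(nc - 1L)
  free <- outer(ta, cc, function(x, y) T_T - x - y)
  lw <- outer(ta * log(a) - lgamma(ta + 1),
              -cc * log(K_d) - lgamma(cc + 1), `+`) +
    lgamma(T_T + 1) - lgamma(pmax(free, 0) + 1)
  lw[free < 0] <- -Inf
  lw
}

#' Projected active-enzyme joint without materializing the 4-axis table
#'
#' Computes the `(T_1A, T_2A)` marginal of [two_enzyme_joint()] by summing
#' the shared-inhibitor coupling over `(C_1, C_2)` with two matrix products
#' (the per-enzyme blocks factorize and only the `(S_T - C_1 - C_2)!` term
#' couples the complexes). Identical to projecting the dense table, at a
#' fraction of the memory and time; used by the sweep drivers.
#'
#' @param params a [two_enzyme_params()].
#' @return a [joint_dist()] with axes `(T_1A, T_2A)`.
#' @export
two_enzyme_active_joint <- function(params) {
  stopifnot(inherits(params, "two_enzyme_params"))
  p <- params
  nc1 <- min(p$T_1T, p$S_T) + 1L
  nc2 <- min(p$T_2T, p$S_T) + 1L
  l1 <- enzyme_log_block(p$T_1T, p$a1, p$K1_d, nc1)
  l2 <- enzyme_log_block(p$T_2T, p$a2, p$K2_d, nc2)
  u1 <- exp(l1 - max(l1[is.finite(l1)]))              # [T_1A, C_1]
  u2 <- exp(l2 - max(l2[is.finite(l2)]))              # [T_2A, C_2]
  csum <- outer(0:(nc1 - 1L), 0:(nc2 - 1L), `+`)
  lcr <- ifelse(csum <= p$S_T, -lgamma(pmax(p$S_T - csum, 0) + 1), -Inf)
  M <- exp(lcr - max(lcr[is.finite(lcr)]))            # [C_1, C_2]
  tab <- u1 %*% M %*% t(u2)                           # [T_1A, T_2A]
  joint_dist(0L, 0L, tab / sum(tab), axes = c("T_1A", "T_2A"))
}

#' Active-enzyme correlation sweep for two competing enzymes
#'
#' Pearson correlation between the active-enzyme counts `(T_1A, T_2A)` as a
#' function of the total abundance of enzyme 1, for the pure intrinsic case
#' (`noise = NULL`) or mixed over an extrinsic-noise law on the shared
#' inhibitor total.
#'
#' @param T_1T_values integer vector of enzyme-1 totals.
#' @param T_2T enzyme-2 total (fixed).
#' @param S_T inhibitor total (ignored when `noise` is given).
#' @param K1_d,K2_d inhibitor dissociation constants.
#' @param a1,a2 activation ratios.
#' @param noise optional [noise_spec()] or [discrete_dist()] on `S_T`.
#' @return data frame with columns `T_1T`, `rho`.
#' @export
two_enzyme_correlation_sweep <- function(T_1T_values, T_2T, S_T,
                                         K1_d, K2_d, a1, a2, noise = NULL) {
  if (length(T_1T_values) == 0L) stop("empty sweep range")
  if (!is.null(noise) && inherits(noise, "noise_spec"))
    noise <- discretise_noise(noise)
  rows <- lapply(as.integer(T_1T_values), function(t1t) {
    j <- if (is.null(noise)) {
      two_enzyme_active_joint(two_enzyme_params(t1t, T_2T, S_T,
                                                K1_d, K2_d, a1, a2))
    } else {
      svals <- dist_support(noise)
      acc <- matrix(0, t1t + 1L, T_2T + 1L)
      for (i in seq_along(svals)) {
        if (noise$probs[i] == 0) next
        jj <- two_enzyme_active_joint(two_enzyme_params(
          t1t, T_2T, svals[i], K1_d, K2_d, a1, a2))
        acc <- acc + noise$probs[i] * jj$p
      }
      joint_dist(0L, 0L, acc / sum(acc), axes = c("T_1A", "T_2A"))
    }
    data.frame(T_1T = t1t, rho = pearson(j))
  })
  do.call(rbind, rows)
}

# Maximum relative detailed-balance residual of the inhibition product form
# over both reaction edges (binding to the inhibitor and activation by the
# substrate). Used by the validation suite.
inhibition_db_residual <- function(params, joint = inhibition_joint(params)) {
  p <- params
  tab <- joint$p
  worst <- 0
  for (ta in 0:p$T_T) {
    for (cc in 0:(min(p$T_T, p$S_T))) {
      tf <- p$T_T - ta - cc
      if (tf < 0 || tab[ta + 1, cc + 1] <= 0) next
      if (cc + 1 <= min(p$T_T, p$S_T) && tf >= 1 && p$S_T - cc >= 1) {
        lhs <- (1 / p$K_d) * tf * (p$S_T - cc) * tab[ta + 1, cc + 1]
        rhs <- (cc + 1) * tab[ta + 1, cc + 2]
        worst <- max(worst, abs(lhs - rhs) / max(lhs, rhs))
      }
      if (ta + 1 <= p$T_T && tf >= 1) {
        lhs <- p$a * tf * tab[ta + 1, cc + 1]
        rhs <- (ta + 1) * tab[ta + 2, cc + 1]
        worst <- max(worst, abs(lhs - rhs) / max(lhs, rhs))
      }
    }
  }
  worst
}
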