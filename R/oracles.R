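#' Mass-action reaction network
#'
#' Minimal description of a closed mass-action network: reactant and product
#' stoichiometries per reaction, rate constants, and the conservation laws
#' (integer linear combinations of species that every reaction preserves).
#' Used by the brute-force master-equation solver and the Gillespie sampler
#' that serve as independent oracles for the analytic steady states.
#'
#' @param species character vector of species names.
#' @param reactants,products integer matrices (reactions x species) of
#'   stoichiometries.
#' @param rates positive rate constants, one per reaction.
#' @param conservation integer matrix (laws x species); every reaction's
#'   change vector must annihilate every law.
#' @return An object of class `"reaction_network"`.
#' @export
reaction_network <- function(species, reactants, products, rates,
                             conservation) {
  stopifnot(is.matrix(reactants), is.matrix(products),
            ncol(reactants) == length(species),
            ncol(products) == length(species),
            nrow(reactants) == nrow(products),
            length(rates) == nrow(reactants), all(rates > 0),
            is.matrix(conservation), ncol(conservation) == length(species))
  change <- products - reactants
  if (any(conservation %*% t(change) != 0))
    stop("a reaction violates a conservation law")
  structure(list(species = species, reactants = reactants,
                 products = products, change = change,
                 rates = as.numeric(rates), conservation = conservation),
            class = "reaction_network")
}

#' @rdname reaction_network
#' @param k_plus,k_minus binding/unbinding rates.
#' @export
network_single_target <- function(k_plus, k_minus) {
  sp <- c("T", "S", "TS")
  reaction_network(sp,
    reactants = rbind(c(1, 1, 0), c(0, 0, 1)),
    products = rbind(c(0, 0, 1), c(1, 1, 0)),
    rates = c(k_plus, k_minus),
    conservation = rbind(T_T = c(1, 0, 1), S_T = c(0, 1, 1)))
}

#' @rdname reaction_network
#' @param k_plus1,k_minus1,k_plus2,k_minus2 per-target rates.
#' @export
network_two_target <- function(k_plus1, k_minus1, k_plus2, k_minus2) {
  sp <- c("T1", "T2", "S", "T1S", "T2S")
  reaction_network(sp,
    reactants = rbind(c(1, 0, 1, 0, 0), c(0, 0, 0, 1, 0),
                      c(0, 1, 1, 0, 0), c(0, 0, 0, 0, 1)),
    products = rbind(c(0, 0, 0, 1, 0), c(1, 0, 1, 0, 0),
                     c(0, 0, 0, 0, 1), c(0, 1, 1, 0, 0)),
    rates = c(k_plus1, k_minus1, k_plus2, k_minus2),
    conservation = rbind(T_1T = c(1, 0, 0, 1, 0),
                         T_2T = c(0, 1, 0, 0, 1),
                         S_T = c(0, 0, 1, 1, 1)))
}

#' @rdname reaction_network
#' @param k_f_cs substrate-binding pseudo-first-order rate `c_s * k_f`.
#' @param k_r deactivation rate.
#' @param k_cat catalytic (product-formation) rate; 0 gives the
#'   quasi-equilibrium network, a positive value adds the slow irreversible
#'   `T_A -> T_F` step (substrate and product pools are not tracked).
#' @export
network_inhibition <- function(k_plus, k_minus, k_f_cs, k_r, k_cat = 0) {
  sp <- c("TF", "TA", "TS", "S")
  re <- rbind(c(1, 0, 0, 1), c(0, 0, 1, 0), c(1, 0, 0, 0), c(0, 1, 0, 0))
  pr <- rbind(c(0, 0, 1, 0), c(1, 0, 0, 1), c(0, 1, 0, 0), c(1, 0, 0, 0))
  rates <- c(k_plus, k_minus, k_f_cs, k_r)
  if (k_cat > 0) {
    re <- rbind(re, c(0, 1, 0, 0))
    pr <- rbind(pr, c(1, 0, 0, 0))
    rates <- c(rates, k_cat)
  }
  reaction_network(sp, re, pr, rates,
    conservation = rbind(T_T = c(1, 1, 1, 0), S_T = c(0, 0, 1, 1)))
}

#' @rdname reaction_network
#' @param r1,r2 named lists of per-enzyme rates (`k_plus`, `k_minus`,
#'   `k_f_cs`, `k_r`).
#' @export
network_two_enzyme <- function(r1, r2) {
  sp <- c("T1F", "T1A", "T1S", "T2F", "T2A", "T2S", "S")
  z <- rep(0, 7)
  row <- function(...) { v <- z; idx <- c(...); v[idx] <- 1; v }
  re <- rbind(row(1, 7), row(3), row(1), row(2),
              row(4, 7), row(6), row(4), row(5))
  pr <- rbind(row(3), row(1, 7), row(2), row(1),
              row(6), row(4, 7), row(5), row(4))
  reaction_network(sp, re, pr,
    rates = c(r1$k_plus, r1$k_minus, r1$k_f_cs, r1$k_r,
              r2$k_plus, r2$k_minus, r2$k_f_cs, r2$k_r),
    conservation = rbind(T_1T = c(1, 1, 1, 0, 0, 0, 0),
                         T_2T = c(0, 0, 0, 1, 1, 1, 0),
                         S_T = c(0, 0, 1, 0, 0, 1, 1)))
}

#' Enumerate all states compatible with the conservation laws
#'
#' Depth-first enumeration of nonnegative integer states `x` with
#' `conservation %*% x == totals`, in deterministic lexicographic order of
#' the species as listed in the network.
#'
#' @param network a [reaction_network()].
#' @param totals numeric vector of conserved totals, one per law.
#' @param max_states guard on the enumeration size.
#' @return integer matrix (states x species) with species as column names.
#' @export
enumerate_states <- function(network, totals, max_states = 2e5) {
  A <- network$conservation
  stopifnot(length(totals) == nrow(A), all(totals >= 0),
            all(totals == round(totals)))
  ns <- ncol(A)
  states <- list()
  x <- integer(ns)
  recurse <- function(j, rem) {
    if (j > ns) {
      if (all(rem == 0)) {
        states[[length(states) + 1L]] <<- x
        if (length(states) > max_states)
          stop("state enumeration exceeded max_states = ", max_states)
      }
      return(invisible())
    }
    pos <- A[, j] > 0
    ub <- if (any(pos)) min(rem[pos] %/% A[pos, j]) else 0L
    for (v in 0:ub) {
      x[j] <<- v
      recurse(j + 1L, rem - A[, j] * v)
    }
    x[j] <<- 0L
  }
  recurse(1L, as.integer(totals))
  out <- do.call(rbind, states)
  colnames(out) <- network$species
  out
}

# Mass-action propensity of every reaction at one state: rate times the
# falling-factorial count of each reactant.
propensities <- function(network, state) {
  vapply(seq_along(network$rates), function(r) {
    s <- network$reactants[r, ]
    f <- 1
    for (j in which(s > 0)) {
      for (k in 0:(s[j] - 1L)) f <- f * (state[j] - k)
    }
    network$rates[r] * max(f, 0)
  }, numeric(1))
}

#' Brute-force master-equation steady state
#'
#' Enumerates the reachable state space, assembles the sparse transition
#' generator from the mass-action propensities and solves for its unique
#' normalized null vector (one balance equation is replaced by the
#' normalization constraint). This is an independent oracle for the analytic
#' product-form distributions.
#'
#' @param network a [reaction_network()].
#' @param totals conserved totals, one per conservation law.
#' @param max_states enumeration guard.
#' @return list of class `"me_solution"` with `states` (matrix) and `p`
#'   (probabilities summing to 1).
#' @export
me_steady_state <- function(network, totals, max_states = 2e5) {
  states <- enumerate_states(network, totals, max_states)
  n <- nrow(states)
  if (n == 1L)
    return(structure(list(states = states, p = 1), class = "me_solution"))
  key <- apply(states, 1, paste, collapse = ",")
  idx <- setNames(seq_len(n), key)
  tri <- vector("list", n)
  diag_out <- numeric(n)
  for (s in seq_len(n)) {
    a <- propensities(network, states[s, ])
    act <- which(a > 0)
    if (length(act) == 0L) next
    tgt_keys <- vapply(act, function(r)
      paste(states[s, ] + network$change[r, ], collapse = ","), character(1))
    t_idx <- idx[tgt_keys]
    if (anyNA(t_idx)) stop("reaction left the enumerated state space")
    tri[[s]] <- list(i = unname(t_idx), j = rep(s, length(act)), x = a[act])
    diag_out[s] <- sum(a[act])
  }
  tri <- tri[!vapply(tri, is.null, logical(1))]
  ii <- unlist(lapply(tri, `[[`, "i"))
  jj <- unlist(lapply(tri, `[[`, "j"))
  xx <- unlist(lapply(tri, `[[`, "x"))
  Q <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, -diag_out), dims = c(n, n))
  # replace the last balance row by sum(p) = 1
  Q[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- as.numeric(Matrix::solve(Q, b))
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-9)
    stop("null-space solve failed (non-unique or ill-conditioned generator)")
  p <- pmax(p, 0)
  structure(list(states = states, p = p / sum(p)), class = "me_solution")
}

#' Project a master-equation solution onto chosen species
#'
#' Aggregates the state probabilities over the counts of the named species,
#' for comparison with the analytic marginals and joints.
#'
#' @param sol an `"me_solution"` from [me_steady_state()].
#' @param species one or two species names.
#' @return for one species, a [discrete_dist()]; for two, a [joint_dist()].
#' @export
me_project <- function(sol, species) {
  stopifnot(length(species) %in% c(1L, 2L),
            all(species %in% colnames(sol$states)))
  if (length(species) == 1L) {
    v <- sol$states[, species]
    lo <- min(v); hi <- max(v)
    p <- numeric(hi - lo + 1L)
    for (i in seq_along(sol$p)) p[v[i] - lo + 1L] <- p[v[i] - lo + 1L] + sol$p[i]
    return(discrete_dist(lo, p / sum(p)))
  }
  v1 <- sol$states[, species[1]]; v2 <- sol$states[, species[2]]
  o1 <- min(v1); o2 <- min(v2)
  tab <- matrix(0, max(v1) - o1 + 1L, max(v2) - o2 + 1L)
  for (i in seq_along(sol$p))
    tab[v1[i] - o1 + 1L, v2[i] - o2 + 1L] <-
      tab[v1[i] - o1 + 1L, v2[i] - o2 + 1L] + sol$p[i]
  joint_dist(o1, o2, tab / sum(tab), axes = species)
}

#' Gillespie sampling configuration
#'
#' @param seed mandatory integer seed (all SSA randomness flows from it).
#' @param burn_in_time relaxation time discarded before sampling, in units
#'   of the unbinding rate.
#' @param n_samples number of sampled states.
#' @param sample_interval time between samples.
#' @return list of class `"ssa_config"`.
#' @export
ssa_config <- function(seed, burn_in_time = 50, n_samples = 1e4,
                       sample_interval = 5) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' is mandatory")
  stopifnot(n_samples >= 1, sample_interval > 0, burn_in_time >= 0)
  structure(list(seed = as.integer(seed), burn_in_time = burn_in_time,
                 n_samples = as.integer(n_samples),
                 sample_interval = sample_interval),
            class = "ssa_config")
}

#' Gillespie stochastic simulation of a network
#'
#' Direct-method trajectories of the mass-action network, sampled every
#' `sample_interval` time units after `burn_in_time`. The initial state is
#' the lexicographically smallest feasible state; conservation laws hold
#' exactly at every sample (integer arithmetic). Reproducible given the
#' config seed.
#'
#' @param network a [reaction_network()].
#' @param totals conserved totals.
#' @param config an [ssa_config()].
#' @return integer matrix (`n_samples` x species) of sampled states.
#' @export
gillespie_sample <- function(network, totals, config) {
  stopifnot(inherits(config, "ssa_config"))
  init <- enumerate_states(network, totals)[1, ]
  set.seed(config$seed)
  out <- ssa_run_cpp(network$reactants, network$change, network$rates,
                     as.integer(init), config$burn_in_time,
                     config$n_samples, config$sample_interval)
  colnames(out) <- network$species
  out
}

# Empirical joint histogram of two sampled species on a fixed grid,
# returned as a joint_dist for total-variation comparisons.
sample_joint <- function(samples, species, o1, o2, n1, n2) {
  v1 <- samples[, species[1]]; v2 <- samples[, species[2]]
  tab <- matrix(0, n1, n2)
  for (i in seq_along(v1))
    tab[v1[i] - o1 + 1L, v2[i] - o2 + 1L] <-
      tab[v1[i] - o1 + 1L, v2[i] - o2 + 1L] + 1
  joint_dist(o1, o2, tab / sum(tab), axes = species)
}
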