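#' Feasible copy-number ranges for the two-target network
#'
#' Conservation of the three totals restricts each free count: a state
#' `(T_1, T_2)` is feasible iff `0 <= T_i <= T_iT` and the implied free
#' sequestrant `S = S_T - (T_1T - T_1) - (T_2T - T_2)` is nonnegative.
#'
#' @param params a [two_target_params()].
#' @return list with per-species `c(min, max)` ranges (`T1`, `T2`, `S`) and
#'   a `feasible(T_1, T_2)` predicate (vectorized).
#' @export
feasible_region <- function(params) {
  stopifnot(inherits(params, "two_target_params"))
  p <- params
  list(
    T1 = c(max(0L, p$T_1T - p$S_T), p$T_1T),
    T2 = c(max(0L, p$T_2T - p$S_T), p$T_2T),
    S = c(max(0L, p$S_T - p$T_1T - p$T_2T), p$S_T),
    feasible = function(T_1, T_2) {
      T_1 >= 0 & T_1 <= p$T_1T & T_2 >= 0 & T_2 <= p$T_2T &
        (p$S_T - (p$T_1T - T_1) - (p$T_2T - T_2)) >= 0
    })
}

#' Exact joint steady state of two targets competing for one sequestrant
#'
#' Detailed balance of the two reversible binding reactions yields the
#' equilibrium law
#' `P(T_1, T_2) = K1_d^T1 K2_d^T2 choose(T_1T, T_1) choose(T_2T, T_2) /
#'  (S_T + T_1 + T_2 - T_1T - T_2T)! / N2`
#' over the feasible region, the grand-canonical form for an ideal mixture.
#' The table is materialized over the full rectangle
#' `[0, T_1T] x [0, T_2T]` with exact zeros outside the feasible region;
#' weights are computed in log space.
#'
#' @param params a [two_target_params()].
#' @return a [joint_dist()] with axes `(T_1, T_2)`.
#' @export
joint_distribution <- function(params) {
  stopifnot(inherits(params, "two_target_params"))
  p <- params
  t1 <- 0:p$T_1T
  t2 <- 0:p$T_2T
  lw1 <- t1 * log(p$K1_d) + lchoose(p$T_1T, t1)
  lw2 <- t2 * log(p$K2_d) + lchoose(p$T_2T, t2)
  sfree <- outer(t1, t2, function(a, b) p$S_T + a + b - p$T_1T - p$T_2T)
  feas <- sfree >= 0
  logw <- outer(lw1, lw2, `+`) - lgamma(pmax(sfree, 0) + 1)
  joint_from_logw(0L, 0L, logw, feas, axes = c("T_1", "T_2"))
}

#' Joint steady state mixed over extrinsic sequestrant noise
#'
#' Law of total probability applied to the joint table:
#' `P(T_1, T_2) = sum_S P(T_1, T_2 | S_T = S) P(S_T = S)`. Every
#' conditional shares the rectangle `[0, T_1T] x [0, T_2T]`, so the mixture
#' is an elementwise convex combination.
#'
#' @param params a [two_target_params()]; its `S_T` field is ignored in
#'   favour of the noise law.
#' @param noise a [noise_spec()] or a [discrete_dist()] over `S_T`.
#' @return the mixed [joint_dist()].
#' @export
mixed_joint <- function(params, noise) {
  stopifnot(inherits(params, "two_target_params"))
  if (inherits(noise, "noise_spec")) noise <- discretise_noise(noise)
  stopifnot(inherits(noise, "discrete_dist"))
  svals <- dist_support(noise)
  acc <- matrix(0, params$T_1T + 1L, params$T_2T + 1L)
  for (i in seq_along(svals)) {
    if (noise$probs[i] == 0) next
    pp <- params
    pp$S_T <- svals[i]
    acc <- acc + noise$probs[i] * joint_distribution(pp)$p
  }
  joint_dist(0L, 0L, acc / sum(acc), axes = c("T_1", "T_2"))
}

#' Correlation (and mutual-information) sweep over total target 1
#'
#' For each value of `T_1T`, computes the exact (optionally noise-mixed)
#' joint distribution and records the Pearson coefficient and, on request,
#' the mutual information in bits together with its Gaussian-equivalent
#' value at the measured correlation.
#'
#' @param T_1T_values integer vector of total target-1 copy numbers.
#' @param T_2T total target-2 copy number (fixed).
#' @param S_T total sequestrant copy number (ignored when `noise` is given).
#' @param K1_d,K2_d dissociation constants.
#' @param noise optional [noise_spec()] or [discrete_dist()] on `S_T`.
#' @param include_mi if `TRUE`, adds `mi_bits` and `gauss_mi_bits` columns.
#' @return data frame with columns `T_1T`, `rho` and optionally `mi_bits`,
#'   `gauss_mi_bits`.
#' @export
correlation_sweep <- function(T_1T_values, T_2T, S_T, K1_d, K2_d,
                              noise = NULL, include_mi = FALSE) {
  if (length(T_1T_values) == 0L) stop("empty sweep range")
  if (!is.null(noise) && inherits(noise, "noise_spec"))
    noise <- discretise_noise(noise)
  rows <- lapply(as.integer(T_1T_values), function(t1t) {
    pars <- two_target_params(t1t, T_2T, S_T, K1_d, K2_d)
    j <- if (is.null(noise)) joint_distribution(pars)
         else mixed_joint(pars, noise)
    out <- data.frame(T_1T = t1t, rho = pearson(j))
    if (include_mi) {
      out$mi_bits <- mutual_information(j)
      out$gauss_mi_bits <- gaussian_equivalent_mi(out$rho)
    }
    out
  })
  do.call(rbind, rows)
}

#' Locus of the correlation maximum under extrinsic noise
#'
#' For each total abundance of the second target, locates the total
#' abundance of the first target that maximizes the Pearson correlation of
#' the noise-mixed joint distribution. Ties are broken toward the smaller
#' `T_1T` so locus tables are reproducible.
#'
#' @param T_2T_values integer vector of second-target totals.
#' @param T_1T_values integer search range for the first-target total.
#' @param K1_d,K2_d dissociation constants.
#' @param noise a [noise_spec()] or [discrete_dist()] on `S_T`.
#' @return data frame with columns `T_2T`, `T_1T_star`, `rho_max`.
#' @export
correlation_maximum_locus <- function(T_2T_values, T_1T_values,
                                      K1_d, K2_d, noise) {
  if (length(T_1T_values) == 0L) stop("empty T_1T search range")
  if (inherits(noise, "noise_spec")) noise <- discretise_noise(noise)
  rows <- lapply(as.integer(T_2T_values), function(t2t) {
    sw <- correlation_sweep(T_1T_values, t2t, S_T = 0L,
                            K1_d = K1_d, K2_d = K2_d, noise = noise)
    ok <- which(!is.na(sw$rho))
    i <- ok[which.max(sw$rho[ok])]
    data.frame(T_2T = t2t, T_1T_star = sw$T_1T[i], rho_max = sw$rho[i])
  })
  do.call(rbind, rows)
}
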