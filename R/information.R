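#' Mutual information of a joint distribution
#'
#' `I = sum P(x1, x2) log2( P(x1, x2) / (P(x1) P(x2)) )` with the limit
#' convention `0 log 0 = 0` (zero-probability cells contribute exactly 0 and
#' are excluded before any logarithm is taken). Measured in bits by default;
#' `I` is nonnegative and bounded by the log of the smaller marginal support
#' size.
#'
#' @param joint a [joint_dist()].
#' @param unit `"bits"` (base-2, default) or `"nats"` (natural log).
#' @return nonnegative numeric.
#' @export
mutual_information <- function(joint, unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  p <- joint$p
  p1 <- rowSums(p)
  p2 <- colSums(p)
  pr <- outer(p1, p2)
  nz <- p > 0
  i <- sum(p[nz] * log(p[nz] / pr[nz]))
  i <- max(i, 0)
  if (unit == "bits") i / log(2) else i
}

#' Mutual information of a bivariate Gaussian with correlation rho
#'
#' `-1/2 * log2(1 - rho^2)`: the mutual information two jointly Gaussian
#' variables with Pearson coefficient `rho` would carry. Used as a
#' linear-dependence baseline for the exact discrete mutual information.
#' Symmetric in the sign of `rho`, zero at `rho = 0`, strictly increasing in
#' `|rho|`, and infinite at `|rho| = 1`.
#'
#' @param rho Pearson correlation; `NA` propagates.
#' @param unit `"bits"` (default) or `"nats"`.
#' @return nonnegative numeric; `Inf` when `|rho| >= 1`.
#' @export
gaussian_equivalent_mi <- function(rho, unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  out <- ifelse(is.na(rho), NA_real_,
                ifelse(abs(rho) >= 1, Inf, -0.5 * log(1 - rho^2)))
  if (unit == "bits") out / log(2) else out
}
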