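#' Discrete distribution on consecutive integers
#'
#' Container for a probability distribution supported on consecutive
#' integers `offset, offset + 1, ...`. All constructors in the package
#' return normalized vectors; `discrete_dist()` validates and renormalizes
#' within a strict tolerance.
#'
#' @param offset integer, smallest support value.
#' @param probs numeric vector of probabilities for consecutive integers
#'   starting at `offset`; must be nonnegative and sum to 1 within `1e-12`
#'   (exact renormalization is applied).
#' @return An object of class `"discrete_dist"` with fields `offset` and
#'   `probs`.
#' @export
discrete_dist <- function(offset, probs) {
  stopifnot(length(offset) == 1L, is.finite(offset), offset == round(offset))
  if (length(probs) < 1L || any(!is.finite(probs)))
    stop("'probs' must be a nonempty finite vector")
  if (any(probs < 0)) {
    if (min(probs) < -1e-15) stop("'probs' must be nonnegative")
    probs <- pmax(probs, 0)
  }
  s <- sum(probs)
  if (abs(s - 1) > 1e-12) stop("'probs' must sum to 1 within 1e-12 (got ", s, ")")
  # renormalize only when measurably off so serialization round-trips
  # bit-exactly
  if (abs(s - 1) > 1e-14) probs <- probs / s
  structure(list(offset = as.integer(offset), probs = probs),
            class = "discrete_dist")
}

#' @rdname discrete_dist
#' @param x a `discrete_dist`.
#' @export
dist_support <- function(x) x$offset + seq_along(x$probs) - 1L

#' @rdname discrete_dist
#' @export
dist_mean <- function(x) sum(dist_support(x) * x$probs)

#' @rdname discrete_dist
#' @export
dist_var <- function(x) {
  m <- dist_mean(x)
  sum((dist_support(x) - m)^2 * x$probs)
}

#' @export
print.discrete_dist <- function(x, ...) {
  cat("Discrete distribution on {", x$offset, ", ..., ",
      x$offset + length(x$probs) - 1L, "}\n", sep = "")
  cat("  mean ", format(dist_mean(x)), ", var ", format(dist_var(x)),
      ", modes ", count_modes(x), "\n", sep = "")
  invisible(x)
}

# Build a discrete_dist from unnormalized log-weights on consecutive
# integers (log-sum-exp with max shift, so copy numbers of order 1e4 stay
# finite).
dist_from_logw <- function(offset, logw) {
  m <- max(logw)
  w <- exp(logw - m)
  discrete_dist(offset, w / sum(w))
}

#' Joint distribution on a rectangular integer grid
#'
#' Probabilities over consecutive integer pairs `(o1 + i, o2 + j)`. Entries
#' outside the feasible region of the generating network are exactly zero.
#'
#' @param o1,o2 integer offsets of the two axes.
#' @param p numeric matrix of probabilities; rows index axis 1, columns
#'   axis 2. Must be nonnegative and sum to 1 within `1e-12`.
#' @param axes optional character vector of length 2 naming the axes.
#' @return An object of class `"joint_dist"`.
#' @export
joint_dist <- function(o1, o2, p, axes = c("x1", "x2")) {
  stopifnot(is.matrix(p), all(is.finite(p)))
  if (any(p < 0)) {
    if (min(p) < -1e-15) stop("probabilities must be nonnegative")
    p <- pmax(p, 0)
  }
  s <- sum(p)
  if (abs(s - 1) > 1e-12) stop("joint table must sum to 1 within 1e-12 (got ", s, ")")
  if (abs(s - 1) > 1e-14) p <- p / s
  structure(list(o1 = as.integer(o1), o2 = as.integer(o2), p = p,
                 axes = axes),
            class = "joint_dist")
}

joint_from_logw <- function(o1, o2, logw, feasible, axes = c("x1", "x2")) {
  m <- max(logw[feasible])
  p <- matrix(0, nrow(logw), ncol(logw))
  p[feasible] <- exp(logw[feasible] - m)
  joint_dist(o1, o2, p / sum(p), axes = axes)
}

#' @rdname joint_dist
#' @param x a `joint_dist`.
#' @param margin 1 or 2, which axis to keep.
#' @return `joint_marginal()` returns the `discrete_dist` of one axis.
#' @export
joint_marginal <- function(x, margin) {
  stopifnot(margin %in% c(1, 2))
  if (margin == 1) discrete_dist(x$o1, rowSums(x$p))
  else discrete_dist(x$o2, colSums(x$p))
}

#' Moments of a joint distribution
#'
#' Exact means, variances and covariance computed by summation over the
#' probability table.
#'
#' @param joint a [joint_dist()].
#' @return list with `mean` (length 2), `var` (length 2) and `cov`.
#' @export
joint_moments <- function(joint) {
  v1 <- joint$o1 + seq_len(nrow(joint$p)) - 1
  v2 <- joint$o2 + seq_len(ncol(joint$p)) - 1
  p1 <- rowSums(joint$p)
  p2 <- colSums(joint$p)
  m1 <- sum(v1 * p1)
  m2 <- sum(v2 * p2)
  var1 <- sum((v1 - m1)^2 * p1)
  var2 <- sum((v2 - m2)^2 * p2)
  cv <- as.numeric(t(v1 - m1) %*% joint$p %*% (v2 - m2))
  list(mean = c(m1, m2), var = pmax(c(var1, var2), 0), cov = cv)
}

#' Pearson correlation of a joint distribution
#'
#' Ratio of the covariance to the product of the two standard deviations.
#' When either marginal is degenerate (zero variance) the coefficient is
#' undefined and `NA_real_` is returned rather than an error.
#'
#' @param joint a [joint_dist()].
#' @return numeric in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
pearson <- function(joint) {
  mo <- joint_moments(joint)
  if (any(mo$var <= 0)) return(NA_real_)
  r <- mo$cov / sqrt(mo$var[1] * mo$var[2])
  max(-1, min(1, r))
}

#' @export
print.joint_dist <- function(x, ...) {
  cat("Joint distribution (", x$axes[1], ", ", x$axes[2], ") on [",
      x$o1, ", ", x$o1 + nrow(x$p) - 1L, "] x [",
      x$o2, ", ", x$o2 + ncol(x$p) - 1L, "]\n", sep = "")
  mo <- joint_moments(x)
  cat("  means ", format(mo$mean[1]), ", ", format(mo$mean[2]),
      "; pearson ", format(pearson(x)), "\n", sep = "")
  invisible(x)
}

#' Summary statistics of a discrete distribution
#'
#' @param dist a [discrete_dist()].
#' @return list with `mean`, `variance`, `n_modes`, `support_min`,
#'   `support_max`, suitable for JSON serialization.
#' @export
dist_summary <- function(dist) {
  list(mean = dist_mean(dist),
       variance = dist_var(dist),
       n_modes = count_modes(dist),
       support_min = dist$offset,
       support_max = dist$offset + length(dist$probs) - 1L)
}
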