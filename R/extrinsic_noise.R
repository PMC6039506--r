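#' Extrinsic-noise law on the total sequestrant copy number
#'
#' Specifies the cell-to-cell (realization-to-realization) variability of
#' the total sequestrant `S_T`, modeled as a static discrete law on
#' nonnegative integers.
#'
#' @param family `"gaussian"` (discretised, truncated at `S_T >= 0` and
#'   renormalized), `"uniform"` (equal weights on an integer interval) or
#'   `"point"` (no extrinsic noise).
#' @param mean mean `<S_T>` (gaussian/point), nonnegative.
#' @param sigma standard deviation of the underlying Gaussian, nonnegative.
#' @param lo,hi integer bounds of the uniform law, `0 <= lo <= hi`.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(family = c("gaussian", "uniform", "point"),
                       mean = NULL, sigma = NULL, lo = NULL, hi = NULL) {
  family <- match.arg(family)
  spec <- switch(family,
    gaussian = {
      if (is.null(mean) || length(mean) != 1L || !is.finite(mean) || mean < 0)
        stop("gaussian noise requires a nonnegative 'mean'")
      if (is.null(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
        stop("gaussian noise requires a nonnegative 'sigma'")
      list(mean = as.numeric(mean), sigma = as.numeric(sigma))
    },
    point = {
      if (is.null(mean) || length(mean) != 1L || !is.finite(mean) || mean < 0)
        stop("point noise requires a nonnegative 'mean'")
      list(mean = as.numeric(mean))
    },
    uniform = {
      lo <- check_count(lo, "lo")
      hi <- check_count(hi, "hi")
      if (hi < lo) stop("'hi' must be >= 'lo'")
      list(lo = lo, hi = hi)
    })
  structure(c(list(family = family), spec), class = "noise_spec")
}

#' Discretise an extrinsic-noise law onto integer sequestrant counts
#'
#' Gaussian noise is discretised by evaluating the Gaussian kernel
#' `exp(-(s - mean)^2 / (2 sigma^2))` on integers `s >= 0`, truncating the
#' upper tail at `ceiling(mean + 10 sigma)` and where the kernel falls below
#' `1e-16` of its maximum, and renormalizing. A zero-sigma Gaussian and the
#' point family both give a unit mass at `round(mean)`.
#'
#' @param spec a [noise_spec()].
#' @return a [discrete_dist()] over integer `S_T` values.
#' @export
discretise_noise <- function(spec) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$family == "uniform") {
    n <- spec$hi - spec$lo + 1L
    return(discrete_dist(spec$lo, rep(1 / n, n)))
  }
  if (spec$family == "point" || spec$sigma == 0)
    return(discrete_dist(round(spec$mean), 1))
  s <- 0:ceiling(spec$mean + 10 * spec$sigma)
  k <- exp(-(s - spec$mean)^2 / (2 * spec$sigma^2))
  keep <- which(k >= 1e-16 * max(k))
  if (length(keep) == 0L) stop("empty noise support")
  s <- s[min(keep):max(keep)]
  k <- k[min(keep):max(keep)]
  discrete_dist(s[1], k / sum(k))
}

#' Superpose conditional steady states over an extrinsic-noise law
#'
#' Law of total probability: `P(T) = sum_S P(T | S_T = S) P(S_T = S)`, where
#' the conditional distributions are the exact intrinsic-noise steady states
#' at fixed sequestrant total and the weights come from the discretised
#' noise law.
#'
#' @param solve function mapping an integer `S_T` to a [discrete_dist()].
#' @param noise a [discrete_dist()] over `S_T` (see [discretise_noise()]),
#'   or a [noise_spec()].
#' @return the mixed [discrete_dist()].
#' @export
mix_over_sequestrant <- function(solve, noise) {
  if (inherits(noise, "noise_spec")) noise <- discretise_noise(noise)
  stopifnot(inherits(noise, "discrete_dist"))
  svals <- dist_support(noise)
  conds <- vector("list", length(svals))
  for (i in seq_along(svals)) {
    if (noise$probs[i] == 0) next
    d <- tryCatch(solve(svals[i]), error = function(e)
      stop("conditional solver failed at S_T = ", svals[i], ": ",
           conditionMessage(e)))
    if (!inherits(d, "discrete_dist"))
      stop("conditional solver must return a discrete_dist (S_T = ",
           svals[i], ")")
    conds[[i]] <- d
  }
  used <- !vapply(conds, is.null, logical(1))
  lo <- min(vapply(conds[used], function(d) d$offset, integer(1)))
  hi <- max(vapply(conds[used], function(d)
    d$offset + length(d$probs) - 1L, integer(1)))
  out <- numeric(hi - lo + 1L)
  for (i in which(used)) {
    d <- conds[[i]]
    idx <- (d$offset - lo + 1L):(d$offset - lo + length(d$probs))
    out[idx] <- out[idx] + noise$probs[i] * d$probs
  }
  discrete_dist(lo, out / sum(out))
}

#' Count strict local maxima of a discrete distribution
#'
#' A mode is an index whose probability strictly exceeds both neighbours
#' (values outside the support count as 0). Consecutive values equal within
#' the relative tolerance form a plateau, which counts as a single mode when
#' flanked by strictly smaller values.
#'
#' @param dist a [discrete_dist()] or a bare numeric probability vector.
#' @param rel_tol relative tolerance used to declare two values tied.
#' @return integer number of modes (`>= 1` for any proper distribution).
#' @export
count_modes <- function(dist, rel_tol = 1e-12) {
  p <- if (inherits(dist, "discrete_dist")) dist$probs else as.numeric(dist)
  stopifnot(all(p >= 0))
  # run-length encode with tolerant equality, then compare run values
  vals <- p[1]
  for (x in p[-1]) {
    last <- vals[length(vals)]
    if (abs(x - last) > rel_tol * max(x, last)) vals <- c(vals, x)
  }
  vals <- c(0, vals, 0)
  n <- 0L
  for (i in 2:(length(vals) - 1L)) {
    if (vals[i] > vals[i - 1] && vals[i] > vals[i + 1]) n <- n + 1L
  }
  n
}

#' Scan the bimodality region over total target and noise level
#'
#' For each node of a `(T_T, sigma)` grid, builds the extrinsic-noise
#' mixture of the exact conditional steady state (Gaussian noise with mean
#' `mean_ST`, standard deviation `sigma`), counts the modes of the chosen
#' marginal, and extracts the region with two distinct peaks. Default grid
#' steps are 1 along `T_T` and 0.25 along `sigma`.
#'
#' @param model which conditional steady state to scan: the single-target
#'   free-target marginal, or the active-enzyme / inhibited-complex marginal
#'   of the quasi-equilibrium competitive-inhibition network.
#' @param T_T integer vector of total target (enzyme) copy numbers.
#' @param sigma numeric vector of extrinsic-noise standard deviations.
#' @param mean_ST mean of the Gaussian noise on the sequestrant total.
#' @param K_d dissociation constant.
#' @param a activation ratio (inhibition models only).
#' @param rel_tol tie tolerance passed to [count_modes()].
#' @return An object of class `"bimodality_scan"`: the grid axes, the
#'   mode-count matrix (`length(T_T)` rows by `length(sigma)` columns), the
#'   logical bimodal-region matrix, its node count `area`, and a data frame
#'   of region-edge nodes (`boundary`).
#' @export
bimodality_scan <- function(model = c("single", "inhibition_active",
                                      "inhibition_complex"),
                            T_T, sigma, mean_ST, K_d, a = NULL,
                            rel_tol = 1e-12) {
  model <- match.arg(model)
  if (length(T_T) == 0L || length(sigma) == 0L)
    stop("empty scan ranges")
  T_T <- as.integer(T_T)
  if (model != "single" && is.null(a))
    stop("inhibition scans require the activation ratio 'a'")
  max_s <- ceiling(mean_ST + 10 * max(sigma))
  # precompute the noise weight vectors over 0..max_s once per sigma
  wmat <- matrix(0, length(sigma), max_s + 1L)
  for (j in seq_along(sigma)) {
    nd <- discretise_noise(noise_spec("gaussian", mean = mean_ST,
                                      sigma = sigma[j]))
    sv <- dist_support(nd)
    wmat[j, sv + 1L] <- nd$probs
  }
  modes <- matrix(NA_integer_, length(T_T), length(sigma))
  for (i in seq_along(T_T)) {
    tt <- T_T[i]
    ncol_m <- if (model == "inhibition_complex") min(tt, max_s) + 1L else tt + 1L
    cond <- matrix(0, max_s + 1L, ncol_m)
    for (s in 0:max_s) {
      d <- switch(model,
        single = steady_state_distribution(seq_params(tt, s, K_d)),
        inhibition_active = joint_marginal(
          inhibition_joint(inhibition_params(tt, s, K_d, a)), 1),
        inhibition_complex = joint_marginal(
          inhibition_joint(inhibition_params(tt, s, K_d, a)), 2))
      idx <- (d$offset + 1L):(d$offset + length(d$probs))
      cond[s + 1L, idx] <- d$probs
    }
    mixed <- wmat %*% cond
    modes[i, ] <- apply(mixed, 1, count_modes, rel_tol = rel_tol)
  }
  bimodal <- modes == 2L
  boundary <- scan_boundary(T_T, sigma, bimodal)
  structure(list(model = model, T_T = T_T, sigma = sigma,
                 mean_ST = mean_ST, K_d = K_d, a = a,
                 modes = modes, bimodal = bimodal,
                 area = sum(bimodal), boundary = boundary),
            class = "bimodality_scan")
}

# Region-edge nodes: bimodal nodes with at least one non-bimodal
# 4-neighbour (or sitting on the grid border).
scan_boundary <- function(T_T, sigma, bimodal) {
  idx <- which(bimodal, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(T_T = integer(0), sigma = numeric(0)))
  nr <- nrow(bimodal); nc <- ncol(bimodal)
  edge <- apply(idx, 1, function(ij) {
    i <- ij[1]; j <- ij[2]
    i == 1L || i == nr || j == 1L || j == nc ||
      !bimodal[i - 1L, j] || !bimodal[i + 1L, j] ||
      !bimodal[i, j - 1L] || !bimodal[i, j + 1L]
  })
  data.frame(T_T = T_T[idx[edge, 1]], sigma = sigma[idx[edge, 2]])
}

#' @export
print.bimodality_scan <- function(x, ...) {
  cat("Bimodality scan (", x$model, "): ", length(x$T_T), " x ",
      length(x$sigma), " grid, bimodal nodes: ", x$area, "\n", sep = "")
  invisible(x)
}
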