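#' Support of the free-target copy number
#'
#' The number of free target molecules ranges from
#' `max(0, T_T - S_T)` (all sequestrant bound) up to `T_T` (none bound).
#'
#' @param params a [seq_params()].
#' @return integer vector `c(T_min, T_max)`.
#' @export
support_range <- function(params) {
  stopifnot(inherits(params, "seq_params"))
  c(max(0L, params$T_T - params$S_T), params$T_T)
}

#' Deterministic steady-state free target
#'
#' Closed-form fixed point of the mass-action rate equation in molecule
#' numbers:
#' `T = ( T_T - S_T - K_d + sqrt((T_T - S_T - K_d)^2 + 4 K_d T_T) ) / 2`.
#' This is the threshold-shaped curve of free target vs total target that
#' molecular titration produces: repressed below `T_T ~ S_T`, linear above.
#'
#' @param params a [seq_params()].
#' @return numeric in `[0, T_T]`.
#' @export
deterministic_free_target <- function(params) {
  stopifnot(inherits(params, "seq_params"))
  b <- params$T_T - params$S_T - params$K_d
  tt <- (b + sqrt(b^2 + 4 * params$K_d * params$T_T)) / 2
  min(max(tt, 0), params$T_T)
}

#' Exact steady-state distribution of the free target
#'
#' Detailed balance of the reversible binding reaction gives the equilibrium
#' law
#' `P(T) = K_d^T * choose(T_T, T) / (S_T - (T_T - T))! / N`
#' on the support from [support_range()]. Weights are accumulated as
#' log-gamma sums and exponentiated after a max shift, so totals up to at
#' least `1e4` molecules stay finite.
#'
#' @param params a [seq_params()].
#' @return a [discrete_dist()] over the free target count.
#' @export
steady_state_distribution <- function(params) {
  stopifnot(inherits(params, "seq_params"))
  sup <- support_range(params)
  tv <- sup[1]:sup[2]
  logw <- tv * log(params$K_d) +
    lchoose(params$T_T, tv) -
    lgamma(params$S_T - (params$T_T - tv) + 1)
  dist_from_logw(sup[1], logw)
}

# Terminating confluent hypergeometric series 1F1(a, b; x) for a a
# nonpositive integer: sum of exactly (-a + 1) terms, Kahan-compensated.
# For the steady-state means a <= 0, b >= 1 and x = -K_d < 0, in which case
# every term is positive and the sum cannot cancel; an overflow guard
# reports when terms exceed the double range.
hyp1f1_terminating <- function(a, b, x) {
  stopifnot(a <= 0, a == round(a))
  n <- -a
  term <- 1
  s <- 1
  comp <- 0
  max_abs <- 1
  if (n > 0) {
    for (k in 0:(n - 1)) {
      term <- term * (a + k) / (b + k) * x / (k + 1)
      max_abs <- max(max_abs, abs(term))
      y <- term - comp
      t2 <- s + y
      comp <- (t2 - s) - y
      s <- t2
    }
  }
  list(value = s, max_abs_term = max_abs,
       cancelled = abs(s) < 1e-6 * max_abs)
}

#' Exact mean free target via terminating hypergeometric sums
#'
#' The mean of the free-target steady state has a closed form as a ratio of
#' confluent hypergeometric functions `1F1` whose first arguments are
#' nonpositive integers, so each is a finite polynomial in `K_d` evaluated
#' by compensated summation:
#' \describe{
#'   \item{`T_T <= S_T`}{`<T> = K_d * T_T / (1 - T_T + S_T) *
#'     1F1(1 - T_T, 2 - T_T + S_T; -K_d) / 1F1(-T_T, 1 - T_T + S_T; -K_d)`}
#'   \item{`T_T > S_T`}{`<T> = (T_T - S_T) *
#'     1F1(-S_T, T_T - S_T; -K_d) / 1F1(-S_T, 1 + T_T - S_T; -K_d)`}
#' }
#' If the series evaluation degrades (overflow of intermediate terms or
#' loss of precision), the mean of [steady_state_distribution()] is
#' returned with a warning.
#'
#' @param params a [seq_params()].
#' @return numeric mean free-target copy number.
#' @export
analytic_mean <- function(params) {
  stopifnot(inherits(params, "seq_params"))
  T_T <- params$T_T; S_T <- params$S_T; K <- params$K_d
  if (T_T == 0) return(0)
  if (S_T == 0) return(as.numeric(T_T))
  if (T_T <= S_T) {
    num <- hyp1f1_terminating(1 - T_T, 2 - T_T + S_T, -K)
    den <- hyp1f1_terminating(-T_T, 1 - T_T + S_T, -K)
    pref <- K * T_T / (1 - T_T + S_T)
  } else {
    num <- hyp1f1_terminating(-S_T, T_T - S_T, -K)
    den <- hyp1f1_terminating(-S_T, 1 + T_T - S_T, -K)
    pref <- T_T - S_T
  }
  bad <- num$cancelled || den$cancelled ||
    max(num$max_abs_term, den$max_abs_term) > 1e290 || den$value == 0
  if (bad) {
    warning("hypergeometric evaluation lost precision; ",
            "falling back to the distribution mean")
    return(dist_mean(steady_state_distribution(params)))
  }
  pref * num$value / den$value
}

#' Logarithmic gain (effective Hill coefficient) of the mean response
#'
#' Local slope of `log <T>` against `log T_T` at integer total-target
#' values, computed from the exact mean by central finite differences.
#' Values above 1 near the equimolar point are the signature of
#' ultrasensitivity in titration systems.
#'
#' @param T_T vector of total target copy numbers (integers `>= 1`).
#' @param S_T total sequestrant copy number.
#' @param K_d dissociation constant.
#' @return numeric vector of the same length as `T_T`.
#' @export
log_gain <- function(T_T, S_T, K_d) {
  vapply(T_T, function(tt) {
    lo <- max(1L, tt - 1L)
    hi <- tt + 1L
    m_lo <- analytic_mean(seq_params(lo, S_T, K_d))
    m_hi <- analytic_mean(seq_params(hi, S_T, K_d))
    (log(m_hi) - log(m_lo)) / (log(hi) - log(lo))
  }, numeric(1))
}
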