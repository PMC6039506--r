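check_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x != round(x))
    stop("'", name, "' must be a single nonnegative integer")
  as.integer(x)
}

check_pos <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop("'", name, "' must be a single positive number")
  as.numeric(x)
}

check_rates <- function(K_d, k_plus, k_minus) {
  if (is.null(k_plus) != is.null(k_minus))
    stop("'k_plus' and 'k_minus' must be given together")
  if (!is.null(k_plus)) {
    k_plus <- check_pos(k_plus, "k_plus")
    k_minus <- check_pos(k_minus, "k_minus")
    if (abs(K_d - k_minus / k_plus) > 1e-12 * K_d)
      stop("'K_d' must equal k_minus/k_plus (relative tolerance 1e-12)")
  }
  list(k_plus = k_plus, k_minus = k_minus)
}

#' Parameters of the single-target sequestration network
#'
#' One target species `T` reversibly binds one sequestrant `S` into a
#' complex; both total copy numbers are conserved. The steady state depends
#' on the kinetic rates only through the dissociation constant
#' `K_d = k_minus / k_plus` (in molecule-number units); the individual rates
#' are optional and only used by the stochastic-simulation oracle.
#'
#' @param T_T total target copy number (nonnegative integer).
#' @param S_T total sequestrant copy number (nonnegative integer).
#' @param K_d dissociation constant, positive.
#' @param k_plus,k_minus optional binding/unbinding rates; when both are
#'   given, `k_minus / k_plus` must equal `K_d` to relative `1e-12`.
#' @return An object of class `"seq_params"`.
#' @export
seq_params <- function(T_T, S_T, K_d, k_plus = NULL, k_minus = NULL) {
  T_T <- check_count(T_T, "T_T")
  S_T <- check_count(S_T, "S_T")
  K_d <- check_pos(K_d, "K_d")
  r <- check_rates(K_d, k_plus, k_minus)
  structure(list(T_T = T_T, S_T = S_T, K_d = K_d,
                 k_plus = r$k_plus, k_minus = r$k_minus),
            class = "seq_params")
}

#' Parameters of the two-target competition network
#'
#' Two target species compete for the same sequestrant pool; all three
#' total copy numbers are conserved.
#'
#' @param T_1T,T_2T total copy numbers of the two targets.
#' @param S_T total sequestrant copy number.
#' @param K1_d,K2_d per-target dissociation constants (positive).
#' @param rates optional named list with `k_plus1`, `k_minus1`, `k_plus2`,
#'   `k_minus2` for the simulation oracle; each pair must be consistent with
#'   its dissociation constant.
#' @return An object of class `"two_target_params"`.
#' @export
two_target_params <- function(T_1T, T_2T, S_T, K1_d, K2_d, rates = NULL) {
  T_1T <- check_count(T_1T, "T_1T")
  T_2T <- check_count(T_2T, "T_2T")
  S_T <- check_count(S_T, "S_T")
  K1_d <- check_pos(K1_d, "K1_d")
  K2_d <- check_pos(K2_d, "K2_d")
  if (!is.null(rates)) {
    check_rates(K1_d, rates$k_plus1, rates$k_minus1)
    check_rates(K2_d, rates$k_plus2, rates$k_minus2)
  }
  structure(list(T_1T = T_1T, T_2T = T_2T, S_T = S_T,
                 K1_d = K1_d, K2_d = K2_d, rates = rates),
            class = "two_target_params")
}

#' Parameters of the competitive-inhibition network (quasi-equilibrium)
#'
#' A free enzyme can reversibly bind an inhibitor (the sequestrant) into an
#' inactive complex, or reversibly bind substrate (held at constant
#' concentration `c_s`) to form the active enzyme. In the quasi-equilibrium
#' limit the slow catalytic step is excluded and the steady state depends on
#' the rates only through `K_d = k_minus / k_plus` and the activation ratio
#' `a = c_s * k_f / k_r`.
#'
#' @param T_T total enzyme copy number.
#' @param S_T total inhibitor copy number.
#' @param K_d inhibitor dissociation constant, positive.
#' @param a activation ratio `c_s * k_f / k_r`, positive.
#' @param rates optional named list with raw rates (`k_plus`, `k_minus`,
#'   `k_f_cs`, `k_r`, and optionally `k_cat`) for the simulation oracle;
#'   must be consistent with `K_d` and `a` to relative `1e-12`.
#' @return An object of class `"inhibition_params"`.
#' @export
inhibition_params <- function(T_T, S_T, K_d, a, rates = NULL) {
  T_T <- check_count(T_T, "T_T")
  S_T <- check_count(S_T, "S_T")
  K_d <- check_pos(K_d, "K_d")
  a <- check_pos(a, "a")
  if (!is.null(rates)) {
    check_rates(K_d, rates$k_plus, rates$k_minus)
    if (!is.null(rates$k_f_cs)) {
      kf <- check_pos(rates$k_f_cs, "k_f_cs")
      kr <- check_pos(rates$k_r, "k_r")
      if (abs(a - kf / kr) > 1e-12 * a)
        stop("'a' must equal k_f_cs/k_r (relative tolerance 1e-12)")
    }
  }
  structure(list(T_T = T_T, S_T = S_T, K_d = K_d, a = a, rates = rates),
            class = "inhibition_params")
}

#' Parameters for two enzyme species inhibited by a shared inhibitor
#'
#' @param T_1T,T_2T total copy numbers of the two enzymes.
#' @param S_T total inhibitor copy number (shared pool).
#' @param K1_d,K2_d per-enzyme inhibitor dissociation constants.
#' @param a1,a2 per-enzyme activation ratios `c_s * k_f_i / k_r_i`.
#' @param rates optional raw-rate list for the simulation oracle.
#' @return An object of class `"two_enzyme_params"`.
#' @export
two_enzyme_params <- function(T_1T, T_2T, S_T, K1_d, K2_d, a1, a2,
                              rates = NULL) {
  structure(list(T_1T = check_count(T_1T, "T_1T"),
                 T_2T = check_count(T_2T, "T_2T"),
                 S_T = check_count(S_T, "S_T"),
                 K1_d = check_pos(K1_d, "K1_d"),
                 K2_d = check_pos(K2_d, "K2_d"),
                 a1 = check_pos(a1, "a1"),
                 a2 = check_pos(a2, "a2"),
                 rates = rates),
            class = "two_enzyme_params")
}
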