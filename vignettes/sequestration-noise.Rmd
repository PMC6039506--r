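---
title: "Exact steady states of sequestration networks under extrinsic noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact steady states of sequestration networks under extrinsic noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqnoise)
```

## The models

Molecular titration couples a *target* species `T` to a *sequestrant* `S`
that binds it into an inactive complex. seqnoise treats three closed,
reversible mass-action networks in which every total copy number is
conserved:

1. **Single target.** `T + S <-> TS` with binding rate `k+` and unbinding
   rate `k-`, totals `T_T = T + TS` and `S_T = S + TS`. One free variable
   remains (the free target count `T`).
2. **Two competing targets.** `T1 + S <-> T1S`, `T2 + S <-> T2S` with a
   shared sequestrant pool; two free variables `(T1, T2)`.
3. **Competitive enzyme inhibition.** A free enzyme `TF` can bind an
   inhibitor (`TF + S <-> TS`) or bind substrate held at fixed
   concentration `c_s` to become active (`TF <-> TA`, forward rate
   `c_s k_f`, backward `k_r`). In the *quasi-equilibrium* limit the slow
   catalytic step is dropped and the remaining network is reversible; two
   free variables `(TA, C = TS)` remain, and the two-enzyme variant adds a
   second enzyme species sharing the inhibitor.

Because each network is reversible with conserved totals, the stationary
law of its chemical master equation satisfies detailed balance: there is no
probability flux across any reaction edge. Applying the edge balance
recursively gives closed product forms. For the single target,

```
P(T) = K_d^T * choose(T_T, T) / (S_T - (T_T - T))!  / N
```

on `T in [max(0, T_T - S_T), T_T]`, where `K_d = k-/k+` in molecule-number
units. The two-target law is the grand-canonical form for an ideal mixture,

```
P(T1, T2) ~ K1_d^T1 K2_d^T2 choose(T_1T, T1) choose(T_2T, T2)
            / (S_T + T1 + T2 - T_1T - T_2T)!
```

over the feasible region (implied free sequestrant nonnegative), and the
inhibition law is

```
P(TA, C) ~ a^TA (1/K_d)^C * T_T! / ((T_T - TA - C)! TA! C!) / (S_T - C)!
```

with the activation ratio `a = c_s k_f / k_r`. The steady states depend on
the kinetic constants only through `K_d` (and `a`); individual rates matter
only for the stochastic-simulation oracle. The inhibition product forms are
derived in-package from the edge-balance conditions and validated two ways:
the test suite asserts the binding and activation balance ratios edge by
edge, and compares every closed form against the brute-force null space of
the enumerated master-equation generator (`me_steady_state()`), with
agreement required to `1e-10`.

The mean free target also has a closed form as a ratio of confluent
hypergeometric functions `1F1` whose first arguments are nonpositive
integers. Each is therefore a terminating polynomial in `K_d`; with
`x = -K_d < 0` every term of the terminating series is positive, so the
sums cannot suffer sign cancellation. `analytic_mean()` evaluates them by
compensated (Kahan) summation and falls back to the summed distribution
mean (with a warning) only if intermediate terms approach the double
overflow limit.

## Key parameters

* `T_T`, `S_T`, `T_1T`, `T_2T` — total copy numbers (molecules). The
  titration threshold sits near equimolarity (`T_T ~ S_T`, or
  `T_1T + T_2T ~ S_T` with two targets).
* `K_d` — dissociation constant in molecule units. Small `K_d` (strong
  affinity) means a sharp threshold; the package's worked examples use
  `K_d` in 0.02–5, the range over which the threshold goes from nearly
  discontinuous to gentle.
* `a = c_s k_f / k_r` — dimensionless activation ratio; `a/(1+a)` is the
  active fraction of uninhibited enzyme (`a = 1.25` gives 5/9). Examples
  use `a = 1.25`.
* Extrinsic noise — a static law on `S_T`: Gaussian with mean `<S_T>` and
  standard deviation `sigma`, uniform on an integer interval, or a point
  mass.

## Extrinsic noise and bimodality

Extrinsic (cell-to-cell) variability of the sequestrant total is modeled as
a static mixture: `P(T) = sum_S P(T | S_T = S) P(S_T = S)`
(`mix_over_sequestrant()`, `mixed_joint()`). The Gaussian law is
discretised on integers `s >= 0` — truncation plus renormalization, not
resampling; the two differ negligibly when `<S_T> >= 3 sigma` — and cut off
above `ceiling(mean + 10 sigma)` and wherever the kernel falls below
`1e-16` of its maximum, which bounds the truncation error far below every
tolerance used in the tests. Whether the support should include `s = 0` is
a genuinely open convention; seqnoise includes it.

Near the threshold the mean response is ultrasensitive (logarithmic gain
above 1, `log_gain()`), so a noise law broad enough to straddle the
threshold splits the mixture into a narrow repressed peak near `T = 0` plus
a broad unrepressed peak — bimodality from a monostable deterministic
system. A flat (uniform) noise law concentrates only the repressed
contribution and cannot raise a comparable unrepressed peak, which the test
suite checks over a grid of spanning intervals.

`count_modes()` counts strict local maxima with a relative tie tolerance of
`1e-12` and no prominence threshold: the tolerance exists only to absorb
floating-point ties, and a flat plateau flanked by smaller values counts
once. Since no published prominence rule exists for "two distinct peaks",
region boundaries from `bimodality_scan()` can shift by about one grid step
under a different peak-detection convention; the tolerance is exposed as an
argument. Scans default to steps of 1 along `T_T` and 0.25 along `sigma`.

## Correlations and information

Competition for one sequestrant correlates two targets negatively
(`pearson()` on the exact joint): below threshold both are nearly free and
`rho ~ 0`; past it the constraint on bound sequestrant drives `rho` toward
its lower bound of -1 (reaching -0.999 at `K_d = 1e-6` deep in
saturation). Extrinsic noise on the shared pool pushes both targets the
same way and adds a positive component that can null or flip the sign, with
the maximum positive correlation near the equimolar line
`T_1T + T_2T ~ <S_T>`; `correlation_maximum_locus()` traces that maximum
(argmax ties broken toward the smaller `T_1T` for reproducibility,
`rho` reported as `NA` when a marginal is degenerate since the coefficient
divides by its standard deviation).

`mutual_information()` computes `I` in bits (a `nats` switch exists) with
zero cells contributing exactly 0 before any logarithm. `I` is nonnegative
and bounded by the log of the smaller marginal support. The Gaussian
baseline `-1/2 log2(1 - rho^2)` (`gaussian_equivalent_mi()`) lies below the
exact `I` through the threshold region, showing dependence beyond linear
correlation; deep in saturation the joint becomes strongly peaked and
non-Gaussian and the ordering inverts (at `S_T = 60`, `T_2T = 20`,
`K = 0.1` the crossover sits near `T_1T ~ 84`), so the bound is asserted on
the pre-saturation range. With strongly unequal affinities the information
shows an interior maximum where the cheaper target starts being in excess
while the correlation merely plateaus.

For the two-enzyme system, sweeps use `two_enzyme_active_joint()`, which
obtains the `(T_1A, T_2A)` marginal by summing the shared-inhibitor
coupling over `(C_1, C_2)` with two matrix products. This is algebraically
identical to projecting the dense four-axis table of `two_enzyme_joint()`
(tested to `1e-12`) and avoids materializing it; the dense path carries a
state-count guard (default `5e7` cells). The added activation reaction
dilutes the coupling: the correlation acquires an interior minimum at the
threshold instead of a plateau, and is weaker in magnitude than the
two-target model wherever the latter's correlation is material.

## Oracles and numerical choices

* **Master-equation oracle.** `enumerate_states()` lists every state
  compatible with the conservation laws in lexicographic order;
  `me_steady_state()` assembles the sparse generator and solves for its
  null vector with one balance row replaced by normalization. Independent
  of every closed form it validates.
* **Gillespie oracle.** Direct-method SSA in compiled code, seeded through
  R's RNG (the seed is mandatory — no silent entropy). Time units are set
  by `k- = 1`; defaults of burn-in 50 and sampling interval 5 give
  effectively independent samples for these fast-relaxing reversible
  networks, and a stationarity test (doubling the burn-in) guards the
  choice. Samples keep the conservation laws exactly in integer
  arithmetic. A slow catalytic step at `k_cat = 1e-3 k_r` leaves sampled
  histograms within total variation 0.02 of the quasi-equilibrium law,
  which is how the package treats the general (non-quasi-equilibrium)
  inhibition case: numerically, via the oracle, rather than through a
  separate closed form.
* **Log-space weights.** All factorials and binomials go through
  `lgamma`/`lchoose`, normalized by max-shifted exponentiation, so copy
  numbers up to at least `1e4` stay finite. Probabilities in the far tail
  of very wide supports can still underflow to exact zeros, which is
  harmless for every statistic computed here.
* **Degenerate inputs.** `T_T = 0` or `S_T = 0` give forced point masses
  rather than errors; they are used as boundary cases throughout the
  tests. Constructors renormalize probability vectors only when their sum
  is measurably off 1 (`> 1e-14`), so TSV serialization at 17 significant
  digits round-trips bit-exactly.

## Scale of the validation runs

The checks shipped with the package run at desk scale, chosen to exercise
every regime: oracle equivalence on state spaces up to a few thousand
states; mean consistency up to totals of 200 and the deterministic-limit
comparison at totals of 500–1000; bimodality scans on `T_T = 1..60`,
`sigma = 0.25..13` by 0.25 with `<S_T> = 30`; correlation and information
sweeps over `T_1T` up to 100 at `S_T = 60`; SSA comparisons at `1e5`
samples per network. Anything larger is a matter of runtime, not method —
the closed forms are exact at any scale the log-space arithmetic covers.

## What the tests do and do not show

All inputs are generated by the package itself (analytic limits, enumerated
state spaces, seeded simulations); there is no external data. The static
extrinsic-noise mixture is a good approximation of a sequestrant that
fluctuates slowly compared with binding — the regime relevant to, e.g.,
microRNA-mediated repression — but it does not model synthesis and
degradation of either species, time-correlated noise, multiple complex
stoichiometries, or more than two competing targets. Passing tests
establish the exactness of the steady-state laws and the qualitative
phenomenology (threshold, noise-induced bimodality, sign reversal of
correlations); they do not calibrate any specific biological system.
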