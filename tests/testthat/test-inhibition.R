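test_that("without inhibitor the active enzyme is binomial in a/(1+a)", {
  m <- inhibition_marginals(inhibition_params(2, 0, 1, 1.25))$active
  expect_equal(m$probs, c(16, 40, 25) / 81, tolerance = 1e-14)
  m <- inhibition_marginals(inhibition_params(7, 0, 1, 0.5))$active
  expect_equal(m$probs, dbinom(0:7, 7, 0.5 / 1.5), tolerance = 1e-12)
})

test_that("switching activation off recovers the pure sequestration law", {
  pars <- inhibition_params(12, 8, 0.5, 1e-10)
  cm <- joint_marginal(inhibition_joint(pars), 2)
  # complex count C maps to T_T - T of the single-target model
  d <- steady_state_distribution(seq_params(12, 8, 0.5))
  expect_equal(embed_dist(cm, 13), rev(embed_dist(d, 13)), tolerance = 1e-8)
})

test_that("inhibition product form matches the master-equation oracle", {
  for (K in c(0.1, 1, 5)) {
    for (a in c(0.5, 1.25)) {
      for (tot in list(c(4, 3), c(8, 6), c(12, 5))) {
        pars <- inhibition_params(tot[1], tot[2], K, a)
        j <- inhibition_joint(pars)
        sol <- me_steady_state(net_inhib(K, a), tot)
        oj <- me_project(sol, c("TA", "TS"))
        expect_lt(max(abs(embed_joint(oj, nrow(j$p), ncol(j$p)) - j$p)), 1e-10)
        expect_lt(seqnoise:::inhibition_db_residual(pars, j), 1e-10)
      }
    }
  }
})

test_that("marginal supports respect the conservation laws exactly", {
  pars <- inhibition_params(6, 4, 0.5, 1.25)
  j <- inhibition_joint(pars)
  for (ta in 0:6) for (cc in 0:4) {
    if (ta + cc > 6) expect_identical(j$p[ta + 1, cc + 1], 0)
  }
  expect_identical(ncol(j$p), 5L)  # C <= S_T
})

test_that("extrinsic noise makes both enzyme marginals bimodal", {
  pars <- inhibition_params(40, 30, 0.04, 1.25)
  noisy <- inhibition_marginals(pars, gnoise(30, 8))
  expect_identical(count_modes(noisy$active), 2L)
  expect_identical(count_modes(noisy$complex), 2L)
  pure <- inhibition_marginals(pars)
  expect_identical(count_modes(pure$active), 1L)
  expect_identical(count_modes(pure$complex), 1L)
  # point noise is the pure case
  pt <- inhibition_marginals(pars, gnoise(30, 0))
  expect_equal(pt$active$probs, pure$active$probs, tolerance = 1e-14)
})

test_that("two-enzyme joint reduces, symmetrizes and matches the oracle", {
  # an absent second enzyme reduces to the one-enzyme law
  tj <- two_enzyme_joint(two_enzyme_params(5, 0, 4, 0.5, 1, 1.25, 1))
  j1 <- inhibition_joint(inhibition_params(5, 4, 0.5, 1.25))
  expect_equal(apply(tj$p4, c(1, 2), sum), j1$p, tolerance = 1e-13)
  # label swap symmetry of the active projection
  ja <- two_enzyme_joint(two_enzyme_params(4, 3, 3, 0.2, 1, 0.5, 2))$active
  jb <- two_enzyme_joint(two_enzyme_params(3, 4, 3, 1, 0.2, 2, 0.5))$active
  expect_equal(ja$p, t(jb$p), tolerance = 1e-13)
  # enumerated-generator oracle
  tep <- two_enzyme_params(3, 3, 2, 0.5, 0.5, 1.25, 1.25)
  tj <- two_enzyme_joint(tep)
  sol <- me_steady_state(net_two_enz(0.5, 0.5, 1.25, 1.25), c(3, 3, 2))
  oj <- me_project(sol, c("T1A", "T2A"))
  expect_lt(max(abs(embed_joint(oj, 4, 4) - tj$active$p)), 1e-10)
  # the marginalized fast projection is the same distribution
  expect_lt(max(abs(two_enzyme_active_joint(tep)$p - tj$active$p)), 1e-12)
  # state-count guard
  expect_error(two_enzyme_joint(tep, max_states = 10), "max_states")
})

test_that("active-enzyme correlations dip at threshold and flip under noise", {
  sw0 <- two_enzyme_correlation_sweep(seq(2, 50, 2), 20, 30,
                                      0.04, 0.04, 1.25, 1.25)
  expect_true(all(sw0$rho <= 1e-9))
  imin <- which.min(sw0$rho)
  expect_gt(imin, 1)
  expect_lt(imin, nrow(sw0))  # interior minimum, not a plateau
  expect_gt(sw0$rho[nrow(sw0)], min(sw0$rho) + 0.05)
  sw12 <- two_enzyme_correlation_sweep(seq(2, 50, 2), 20, 0,
                                       0.04, 0.04, 1.25, 1.25,
                                       noise = gnoise(30, 12))
  expect_gt(max(sw12$rho), 0)
  # the added activation stochasticity weakens the coupling relative to the
  # minimal model wherever the minimal-model correlation is material
  swm <- correlation_sweep(seq(2, 50, 2), 20, 30, 0.04, 0.04)
  material <- abs(swm$rho) > 0.05
  expect_true(all(abs(sw0$rho[material]) <= abs(swm$rho[material])))
  expect_gt(min(sw0$rho), min(swm$rho))
  expect_lt(mean(abs(sw0$rho)), mean(abs(swm$rho)))
})

test_that("slow catalysis leaves the quasi-equilibrium law intact", {
  # SSA of the full network with k_cat = 1e-3 * k_r against the analytic law
  s <- gillespie_sample(net_inhib(0.5, 1.25, k_cat = 1e-3), c(6, 4),
                        ssa_config(seed = 7, n_samples = 1e5))
  ji <- inhibition_joint(inhibition_params(6, 4, 0.5, 1.25))
  emp <- seqnoise:::sample_joint(s, c("TA", "TS"), 0L, 0L, 7L, 5L)
  expect_lt(tv_dist(as.vector(emp$p), as.vector(ji$p)), 0.02)
})
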