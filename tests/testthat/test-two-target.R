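test_that("feasible region reproduces the conservation-law bounds", {
  fr <- feasible_region(two_target_params(20, 20, 60, 1, 1))
  expect_identical(fr$S[1], 20L)
  expect_identical(fr$T1[1], 0L)
  expect_identical(fr$T2[1], 0L)
  fr <- feasible_region(two_target_params(100, 20, 60, 1, 1))
  expect_identical(fr$T1, c(40L, 100L))
  expect_true(fr$feasible(40, 20))
  expect_false(fr$feasible(39, 20))
  fr <- feasible_region(two_target_params(0, 5, 3, 1, 1))
  expect_identical(fr$T1, c(0L, 0L))
})

test_that("joint distribution reduces, transposes and matches the generator", {
  # T_2T = 0 collapses to the single-target law
  j <- joint_distribution(two_target_params(12, 0, 8, 0.5, 1))
  expect_identical(ncol(j$p), 1L)
  d1 <- steady_state_distribution(seq_params(12, 8, 0.5))
  expect_equal(j$p[dist_support(d1) + 1, 1], d1$probs, tolerance = 1e-13)
  # relabeling symmetry
  ja <- joint_distribution(two_target_params(5, 3, 4, 0.2, 2))
  jb <- joint_distribution(two_target_params(3, 5, 4, 2, 0.2))
  expect_equal(ja$p, t(jb$p), tolerance = 1e-14)
  # full master-equation oracle on small state spaces
  for (K in c(0.1, 1, 5)) {
    for (tot in list(c(3, 2, 3), c(5, 4, 6), c(12, 7, 9))) {
      pars <- two_target_params(tot[1], tot[2], tot[3], K, 2 * K)
      j <- joint_distribution(pars)
      sol <- me_steady_state(net_two(K, 2 * K), tot)
      oj <- me_project(sol, c("T1", "T2"))
      expect_lt(max(abs(embed_joint(oj, nrow(j$p), ncol(j$p)) - j$p)), 1e-10)
    }
  }
})

test_that("detailed balance holds on every feasible edge of the joint", {
  pars <- two_target_params(8, 6, 7, 0.3, 1.5)
  j <- joint_distribution(pars)
  worst <- 0
  for (t1 in 0:pars$T_1T) {
    for (t2 in 0:pars$T_2T) {
      s <- pars$S_T - (pars$T_1T - t1) - (pars$T_2T - t2)
      if (s < 0 || j$p[t1 + 1, t2 + 1] <= 0) next
      if (t1 < pars$T_1T) {
        lhs <- pars$K1_d * (pars$T_1T - t1) * j$p[t1 + 1, t2 + 1]
        rhs <- (t1 + 1) * (s + 1) * j$p[t1 + 2, t2 + 1]
        worst <- max(worst, abs(lhs - rhs) / max(lhs, rhs))
      }
      if (t2 < pars$T_2T) {
        lhs <- pars$K2_d * (pars$T_2T - t2) * j$p[t1 + 1, t2 + 1]
        rhs <- (t2 + 1) * (s + 1) * j$p[t1 + 1, t2 + 2]
        worst <- max(worst, abs(lhs - rhs) / max(lhs, rhs))
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("moments and correlation behave on degenerate and product joints", {
  pm <- joint_dist(3L, 5L, matrix(1, 1, 1))
  mo <- joint_moments(pm)
  expect_equal(mo$mean, c(3, 5))
  expect_equal(mo$var, c(0, 0))
  expect_equal(mo$cov, 0)
  expect_true(is.na(pearson(pm)))
  # outer product of two marginals has zero covariance
  p1 <- c(0.2, 0.5, 0.3)
  p2 <- c(0.6, 0.4)
  mo <- joint_moments(joint_dist(0L, 0L, outer(p1, p2)))
  expect_lt(abs(mo$cov), 1e-14)
  expect_equal(pearson(joint_dist(0L, 0L, diag(c(0.5, 0.5)))), 1)
  expect_equal(pearson(joint_dist(0L, 0L, matrix(c(0, 0.5, 0.5, 0), 2))), -1)
})

test_that("the mean of target 1 switches at the equimolarity threshold", {
  m <- vapply(1:60, function(t1t) joint_moments(joint_distribution(
    two_target_params(t1t, 20, 60, 0.1, 0.1)))$mean[1], numeric(1))
  d2 <- diff(diff(m))
  expect_lt(abs((which.max(d2) + 1L) - 40L), 3)
})

test_that("competition correlates the targets negatively, saturating at -1", {
  sw <- correlation_sweep(seq(2, 100, 7), 20, 60, 0.1, 0.1)
  expect_true(all(sw$rho <= 1e-9))
  expect_true(all(diff(sw$rho) <= 1e-9))
  rho_sat <- pearson(joint_distribution(
    two_target_params(100, 20, 60, 1e-6, 1e-6)))
  expect_lt(rho_sat, -0.999)
  expect_gte(rho_sat, -1)
})

test_that("extrinsic noise mixes the joint linearly and can flip the sign", {
  pars <- two_target_params(45, 20, 60, 0.1, 0.1)
  # point noise reproduces the fixed-sequestrant joint
  jm <- mixed_joint(pars, gnoise(60, 0))
  expect_equal(jm$p, joint_distribution(pars)$p, tolerance = 1e-14)
  # convex combination of two point laws
  two_pt <- discrete_dist(50L, c(0.3, rep(0, 19), 0.7))
  jm <- mixed_joint(pars, two_pt)
  p50 <- joint_distribution(two_target_params(45, 20, 50, 0.1, 0.1))$p
  p70 <- joint_distribution(two_target_params(45, 20, 70, 0.1, 0.1))$p
  expect_equal(jm$p, 0.3 * p50 + 0.7 * p70, tolerance = 1e-13)
  # strong sequestrant noise induces positive correlation near threshold
  expect_gt(pearson(mixed_joint(pars, gnoise(60, 12))), 0)
  expect_lt(pearson(joint_distribution(pars)), 0)
})

test_that("the correlation-maximum locus tracks the equimolar line", {
  loc <- correlation_maximum_locus(c(10L, 20L), seq(30L, 70L, 1L),
                                   0.1, 0.1, gnoise(60, 4))
  expect_true(all(abs(loc$T_1T_star + loc$T_2T - 60) <= 2))
  expect_true(all(loc$rho_max > 0))
})
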