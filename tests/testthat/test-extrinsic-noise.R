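test_that("noise laws discretise as stated", {
  d <- discretise_noise(gnoise(30, 0))
  expect_identical(dist_support(d), 30L)
  d <- discretise_noise(noise_spec("uniform", lo = 0, hi = 3))
  expect_equal(d$probs, rep(0.25, 4))
  # Gaussian weights proportional to the kernel, unit total mass
  d <- discretise_noise(gnoise(30, 8))
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
  s <- dist_support(d)
  kern <- function(x) exp(-(x - 30)^2 / (2 * 64))
  expect_equal(d$probs[s == 10] / d$probs[s == 30], kern(10) / kern(30),
               tolerance = 1e-12)
  expect_lt(abs(dist_mean(d) - 30), 0.5)
  expect_error(noise_spec("gaussian", mean = 30, sigma = -1), "sigma")
  expect_error(noise_spec("uniform", lo = 5, hi = 2), "hi")
})

test_that("mixing over the sequestrant obeys the law of total probability", {
  solve1 <- function(s) steady_state_distribution(seq_params(40, s, 0.1))
  # point noise recovers the pure intrinsic case exactly
  mx <- mix_over_sequestrant(solve1, gnoise(30, 0))
  ref <- solve1(30)
  expect_identical(mx$offset, ref$offset)
  expect_equal(mx$probs, ref$probs, tolerance = 1e-14)
  # two-component noise is the elementwise convex combination
  half <- discrete_dist(20L, c(0.5, rep(0, 14), 0.5))  # half at 20, half at 35
  mx <- mix_over_sequestrant(solve1, half)
  d20 <- embed_dist(solve1(20), 41)
  d35 <- embed_dist(solve1(35), 41)
  expect_equal(embed_dist(mx, 41), 0.5 * d20 + 0.5 * d35, tolerance = 1e-14)
  # normalization and total expectation across noise levels
  for (sg in c(2, 8, 13)) {
    nd <- discretise_noise(gnoise(30, sg))
    mx <- mix_over_sequestrant(solve1, nd)
    expect_equal(sum(mx$probs), 1, tolerance = 1e-10)
    mean_by_parts <- sum(nd$probs * vapply(dist_support(nd), function(s)
      dist_mean(solve1(s)), numeric(1)))
    expect_equal(dist_mean(mx), mean_by_parts, tolerance = 1e-10)
  }
  expect_error(mix_over_sequestrant(function(s) stop("boom"),
                                    gnoise(5, 1)), "S_T = ")
})

test_that("mode counting handles boundaries, plateaus and ties", {
  expect_identical(count_modes(c(0.5, 0.3, 0.2)), 1L)
  expect_identical(count_modes(c(0.1, 0.4, 0.1, 0.3, 0.1)), 2L)
  # plateau flanked by smaller values counts once
  expect_identical(count_modes(c(0.2, 0.3, 0.3, 0.2)), 1L)
  # near-tie within tolerance is a plateau, outside it is two peaks
  p <- c(0.1, 0.3, 0.2, 0.3 * (1 + 1e-13), 0.1)
  expect_identical(count_modes(p / sum(p)), 2L)
  expect_identical(count_modes(c(1)), 1L)
})

test_that("pure intrinsic single-target distributions are unimodal", {
  for (K in c(0.1, 1, 5)) {
    for (T_T in c(10L, 30L, 40L)) {
      d <- steady_state_distribution(seq_params(T_T, 30L, K))
      expect_identical(count_modes(d), 1L)
    }
  }
})

test_that("noise level modulates bimodality of the mixed distribution", {
  solve1 <- function(s) steady_state_distribution(seq_params(40, s, 0.1))
  modes <- vapply(c(0, 5, 8, 13), function(sg)
    count_modes(mix_over_sequestrant(solve1, gnoise(30, sg))), integer(1))
  expect_identical(modes[1], 1L)
  expect_identical(modes[3], 2L)  # the bimodal window
  # mixed mean grows smoothly with noise at the threshold
  means <- vapply(c(0, 5, 8, 13), function(sg)
    dist_mean(mix_over_sequestrant(solve1, gnoise(30, sg))), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("flat (uniform) noise cannot raise an unrepressed peak", {
  for (T_T in c(35L, 40L, 45L)) {
    for (hi in c(50L, 60L)) {
      mx <- mix_over_sequestrant(
        function(s) steady_state_distribution(seq_params(T_T, s, 0.1)),
        noise_spec("uniform", lo = 10, hi = hi))
      p <- mx$probs
      n <- length(p)
      peaks <- which(p > c(0, p[-n]) & p > c(p[-1], 0))
      if (length(peaks) > 1L) {
        # any high-count peak must not exceed the repressed peak
        expect_lte(max(p[peaks[-1]]), p[peaks[1]])
      } else {
        succeed()
      }
    }
  }
})

test_that("bimodality scan flags the threshold region and rejects bad input", {
  sc <- bimodality_scan("single", T_T = 35:45, sigma = c(0, 8),
                        mean_ST = 30, K_d = 0.1)
  expect_true(all(sc$modes[, 1] == 1L))        # no extrinsic noise: unimodal
  expect_identical(sc$modes[sc$T_T == 40, 2], 2L)
  expect_identical(sc$area, sum(sc$modes == 2L))
  expect_true(all(sc$boundary$T_T %in% sc$T_T))
  expect_error(bimodality_scan("single", T_T = integer(0), sigma = 1,
                               mean_ST = 30, K_d = 0.1), "empty")
})
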