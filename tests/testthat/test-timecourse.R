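test_that("time-course invariants are enforced", {
  expect_error(time_course("x", 1, c(0, 15), c(1, 2)), "3 samples")
  expect_error(time_course("x", 1, c(5, 15, 30), c(1, 2, 1)), "must be 0")
  expect_error(time_course("x", 1, c(0, 15, 15), c(1, 2, 1)), "increasing")
  expect_error(time_course("x", 1, c(0, 15, 30), c(1, -2, 1)), ">= 0")
})

test_that("period detection interpolates the baseline return", {
  tc <- time_course("x", 1, c(0, 15, 30, 45, 60), c(1, 2, 1.5, 0.9, 1))
  p <- detect_period(tc)
  expect_equal(p$tau, 42.5)   # between (30, 1.5) and (45, 0.9)
  expect_false(p$truncated)

  rising <- time_course("x", 1, paper_grid, c(1, 1.2, 1.5, 2, 2.5, 3, 3.5))
  pr <- detect_period(rising)
  expect_equal(pr$tau, 180)
  expect_true(pr$truncated)

  flat <- time_course("nc", 1, paper_grid, rep(1, 7))
  pf <- detect_period(flat)
  expect_equal(pf$tau, 180)
  expect_true(pf$truncated)

  # early sub-baseline dip before the maximum is ignored
  dip <- time_course("x", 1, c(0, 10, 20, 40, 60), c(1, 0.8, 3, 0.5, 1))
  expect_equal(detect_period(dip)$tau, 20 + 20 * 2 / 2.5)
})

test_that("mean fold integrates the curve with sub-baseline subtraction", {
  flat <- time_course("nc", 1, paper_grid, rep(1, 7))
  expect_equal(integrate_ratio(flat, 100), 1)

  tri <- time_course("x", 1, c(0, 30, 60), c(1, 3, 1))
  expect_equal(integrate_ratio(tri, 60), 2)   # triangle of height 2

  tc <- time_course("x", 1, c(0, 15, 30, 45, 60), c(1, 2, 1.5, 0.9, 1))
  # closed-form piecewise-linear oracle over the detected window
  expect_equal(integrate_ratio(tc, 42.5),
               piecewise_linear_mean(tc$times, tc$ratios, 42.5),
               tolerance = 1e-9)
  expect_error(integrate_ratio(tc, 100), "outside")
})

test_that("flat baseline estimates a rate of exactly zero", {
  flat <- time_course("Negative control", 1, paper_grid, rep(1, 7))
  est <- estimate_rate(flat)
  expect_identical(est$kld_rate_per_h, 0)
  expect_equal(est$mean_fold, 1)
  expect_match(est$flags, "period_truncated")
})

test_that("estimator recovers calibrated pulse rates on fine grids", {
  for (r in c(1.5, 3)) for (tau in c(45, 60)) {
    f <- pulse_profile(tau, r)
    tt <- seq(0, tau, by = 2.5)
    tc <- time_course("x", 1, tt, f(tt))
    est <- estimate_rate(tc)
    expect_equal(est$tau_min, tau, tolerance = 1e-9)
    expect_lt(abs(est$kld_rate_per_h - r) / r, 0.01)
    expect_equal(est$kld_rate_per_h, quadrature_rate(f, tau),
                 tolerance = 1e-4)
  }
})

test_that("scaling a truncated curve shifts the rate by log(c)/tau", {
  rising <- time_course("x", 1, paper_grid, c(1, 1.2, 1.5, 2, 2.5, 3, 3.5))
  base <- estimate_rate(rising)
  for (c0 in c(1.5, 2)) {
    scaled <- time_course("x", 1, paper_grid, c0 * rising$ratios)
    est <- estimate_rate(scaled)
    expect_equal(est$tau_min, base$tau_min)
    expect_equal(est$kld_rate_per_h - base$kld_rate_per_h,
                 log(c0) / (base$tau_min / 60), tolerance = 1e-10)
  }
})

test_that("below-baseline windows give flagged negative rates, not clamps", {
  # deep dip before the late peak: the detected window [0, tau] then
  # holds more sub-baseline than excess area
  tc <- time_course("x", 1, c(0, 15, 30, 45, 60), c(1, 0.2, 0.2, 1.3, 0.9))
  est <- estimate_rate(tc)
  expect_lt(est$kld_rate_per_h, 0)
  expect_match(est$flags, "below_baseline")
})

test_that("grid refinement converges to the analytic rate", {
  # pulse not commensurate with the grid, sampled over a longer window
  r <- 3; tau <- 50
  f <- pulse_profile(tau, r)
  # nested halvings, so the detected baseline crossing can only move
  # toward the true period as the grid refines
  errs <- vapply(7.5 / 2^(0:6), function(h) {
    tt <- seq(0, 60, by = h)
    abs(estimate_rate(time_course("x", 1, tt, f(tt)))$kld_rate_per_h - r)
  }, numeric(1))
  # monotone up to the O(h^2) quadrature wiggle at unchanged crossings
  expect_true(all(diff(errs) <= 2e-3))
  expect_lt(errs[length(errs)], 0.01)
  expect_lt(errs[length(errs)], errs[1] / 10)
})

test_that("batch estimation is ordered, complete, and strict", {
  g <- generate_timecourses(generator_config(noise_sigma = 0.05, seed = 2))
  est <- batch_estimate(g$timecourses)
  expect_equal(nrow(est), 6 * 4)
  expect_equal(est$molecule, sort(est$molecule))
  expect_error(batch_estimate(list()), "empty")
  bad <- g$timecourses
  bad$ratio[bad$molecule == "p38" & bad$replicate == 2][3] <- -1
  expect_error(batch_estimate(bad), "p38/2")

  # estimates depend only on the baseline-normalized ratio: any overall
  # scale in the raw signal cancels in raw/raw(0)
  raw_scale <- 7.3
  renorm <- g$timecourses
  renorm$ratio <- ave(renorm$ratio * raw_scale,
                      renorm$molecule, renorm$replicate,
                      FUN = function(x) x / x[1])
  expect_equal(batch_estimate(renorm), est, tolerance = 1e-12)
})

test_that("time courses survive the CSV round trip", {
  g <- generate_timecourses(generator_config(seed = 5))
  path <- tempfile(fileext = ".csv")
  write_timecourses(g$timecourses, path)
  back <- read_timecourses(path)
  expect_equal(back$ratio, g$timecourses$ratio, tolerance = 1e-12)
  expect_equal(batch_estimate(back), batch_estimate(g$timecourses),
               tolerance = 1e-12)
})
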