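test_that("traffic equations solve tandem and isolated networks", {
  tandem <- tandem_cascade_spec(3, 0.5, 1)
  expect_equal(unname(solve_traffic(tandem)), c(0.5, 0.5, 0.5))

  # side-fed chain; expected value frozen from fixed-point iteration of
  # the balance equations (see helper traffic_fixed_point)
  fed <- tandem_cascade_spec(3, c(0.5, 0.2, 0), 1)
  expect_equal(unname(solve_traffic(fed)), c(0.5, 0.7, 0.7))
  expect_equal(unname(solve_traffic(fed)), traffic_fixed_point(fed),
               tolerance = 1e-12)

  iso <- cascade_spec(c("a", "b"), c(0.3, 0.4), c(1, 1))
  expect_equal(unname(solve_traffic(iso)), c(0.3, 0.4))
})

test_that("traffic solutions satisfy the balance residual on random networks", {
  for (seed in 1:8) {
    n <- sample(2:20, 1)
    spec <- random_open_spec(n, seed)
    lam <- solve_traffic(spec)
    resid <- lam - (spec$lambda_o + as.numeric(t(spec$routing) %*% lam))
    expect_lt(max(abs(resid)), 1e-10)
  }
})

test_that("non-open or malformed routing is rejected", {
  expect_error(cascade_spec("a", 1, 1, matrix(1, 1, 1)), "not open")
  expect_error(cascade_spec(c("a", "b"), c(1, 0), c(1, 1),
                            matrix(c(0, 1, 1, 0), 2, 2)), "not open")
  expect_error(cascade_spec(c("a", "b"), c(0, 0), c(1, 1)), "external")
  expect_error(cascade_spec("a", 1, 0), "positive")
  expect_error(cascade_spec(c("a", "b"), c(1, 0), c(1, 1),
                            matrix(c(0.7, 0.7, 0, 0), 2, 2, byrow = TRUE)),
               "row sums")
})

test_that("utilizations follow lambda/mu and flag instability", {
  r <- utilizations(1, 4)
  expect_equal(as.numeric(r), 0.25)
  expect_true(attr(r, "stable"))
  expect_warning(ru <- utilizations(1, 1), "unstable")
  expect_false(attr(ru, "stable"))
  expect_equal(as.numeric(utilizations(0, 2)), 0)
  expect_error(utilizations(1, 0), "positive")
})

test_that("product-form probabilities multiply geometric marginals", {
  expect_equal(stationary_probability(c(0.5, 0.5), c(1, 1)), 0.0625)
  expect_equal(stationary_probability(c(0.5, 0.5), c(0, 0)), 0.25)
  expect_error(stationary_probability(c(1, 0.5), c(0, 0)), "unstable")

  # normalization by truncated enumeration, and exact truncated mass
  rho <- c(0.5, 0.5)
  states <- expand.grid(a1 = 0:50, a2 = 0:50)
  total <- sum(mapply(function(a1, a2)
    stationary_probability(rho, c(a1, a2)), states$a1, states$a2))
  expect_equal(total, prod(1 - rho^51), tolerance = 1e-12)

  # marginal of node i is geometric
  rho <- c(0.3, 0.6)
  marg <- vapply(0:10, function(a1)
    sum(vapply(0:200, function(a2)
      stationary_probability(rho, c(a1, a2)), numeric(1))), numeric(1))
  expect_equal(marg, rho[1]^(0:10) * (1 - rho[1]), tolerance = 1e-10)
})

test_that("mean queue lengths match the geometric closed form and its mean", {
  expect_equal(mean_queue_lengths(0.5)$L, 1)
  expect_equal(mean_queue_lengths(0.25)$L, 1 / 3)
  # L_i equals the mean of the geometric occupancy law
  for (rho in c(0.1, 0.37, 0.8)) {
    direct <- sum((0:2000) * rho^(0:2000) * (1 - rho))
    expect_equal(mean_queue_lengths(rho)$L_i, direct, tolerance = 1e-10)
  }
  # light-traffic approximation gap is bounded by max rho/(1-rho)
  rho <- c(0.01, 0.01)
  ql <- mean_queue_lengths(rho)
  expect_equal(ql$L_light_traffic, 0.02)
  gap <- abs(ql$L - ql$L_light_traffic) / ql$L_light_traffic
  expect_lte(gap, max(rho / (1 - rho)) + 1e-15)
})

test_that("light-traffic per-state approximation bound holds", {
  rho <- 0.05
  for (a in 0:6) {
    p_exact <- rho^a * (1 - rho)
    expect_lte(abs(p_exact - rho^a), rho^a * rho + 1e-15)
  }
})

test_that("Poisson arrival counts normalize and match closed forms", {
  expect_equal(arrival_count_pmf(2, 1, 0), exp(-2))
  expect_equal(arrival_count_pmf(2, 1, 2), 2 * exp(-2))
  expect_equal(sum(arrival_count_pmf(2, 1, 0:100)), 1, tolerance = 1e-12)
  expect_error(arrival_count_pmf(-1, 1, 0), "non-negative")
})

test_that("total duration sums occupancy dwell times", {
  expect_equal(total_duration(c(1, 1), c(1, 1)), 2)
  expect_equal(total_duration(c(2, 0), c(0.5, 0)), 4)
  expect_equal(total_duration(c(0, 0), c(1, 1)), 0)
  expect_error(total_duration(c(1, 1), c(1, 0)), "undefined")
})

test_that("steady state assembles rates, occupancies and dwell times", {
  spec <- cascade_spec(c("a", "b"), c(0.2, 0.1), c(1, 0.8),
                       matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE))
  ss <- steady_state(spec)
  expect_equal(unname(ss$lambda), c(0.2, 0.2))
  expect_equal(unname(ss$rho), c(0.2, 0.25))
  expect_equal(ss$L, sum(ss$rho / (1 - ss$rho)))
  expect_equal(ss$a, ss$L)
  expect_equal(unname(ss$tau_o), c(5, 10))
  unstable <- cascade_spec("a", 2, 1)
  expect_error(steady_state(unstable), "unstable")
})

test_that("cascade specs round-trip through YAML", {
  spec <- random_open_spec(4, seed = 11)
  path <- tempfile(fileext = ".yaml")
  write_cascade_spec(spec, path)
  back <- read_cascade_spec(path)
  expect_equal(back$labels, spec$labels)
  expect_equal(back$lambda_o, spec$lambda_o, tolerance = 1e-6)
  expect_equal(back$mu, spec$mu, tolerance = 1e-6)
  expect_equal(back$routing, spec$routing, tolerance = 1e-6)
})
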