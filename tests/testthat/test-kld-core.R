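test_that("divergence matches direct term-by-term summation", {
  expect_equal(kld(c(0.2, 0.3), c(0.2, 0.3))$divergence, 0)
  # frozen from the summation oracle: .4*log(.4/.2) + .1*log(.1/.3)
  expect_equal(kld(c(0.4, 0.1), c(0.2, 0.3))$divergence,
               0.4 * log(2) + 0.1 * log(1 / 3))
  expect_equal(kld(c(0.4, 0.1), c(0.2, 0.3))$divergence, 0.1673976,
               tolerance = 1e-6)
  # zero-term convention and the 0.5*log(2) case
  expect_equal(kld(c(0.5, 0), c(0.25, 0.25))$divergence, 0.5 * log(2))
  # absolutely-continuous failure reported as infinite
  expect_equal(kld(c(0.5, 0.1), c(0.25, 0))$divergence, Inf)
})

test_that("divergence is non-negative for equal-mass states, zero iff equal", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    rho <- runif(n, 0.01, 0.5)
    w <- runif(n); rho_t <- w / sum(w) * sum(rho)   # same total mass
    expect_gte(kld(rho_t, rho)$divergence, -1e-12)
  }
  rho <- c(0.1, 0.2, 0.3)
  expect_equal(kld(rho, rho)$divergence, 0)
})

test_that("state log-probability: exact log-factorials vs Stirling form", {
  r <- log_state_probability(c(1, 1), c(0.3, 0.3))
  expect_equal(r$exact, log(2 * 0.09))
  # all mass in one node with matching rho: approximation exactly 0,
  # exact reduces to a*log(rho) -- the degenerate Stirling gap
  r2 <- log_state_probability(c(5, 0), c(1, 0.3), a = 5)
  expect_equal(r2$stirling, 0)
  expect_equal(r2$exact, 5 * log(1))
  # large-a regime: per-customer gap below 1% for the two-node state
  r3 <- log_state_probability(c(300, 700), c(0.3, 0.7))
  expect_lt(r3$per_customer_gap, 0.01)
  expect_error(log_state_probability(c(1, 1), c(0.3, 0.3), a = 3),
               "sum")
})

test_that("Stirling gap per customer shrinks as the state grows", {
  rho <- c(0.2, 0.1, 0.05)
  gaps <- vapply(c(30, 300, 3000), function(a) {
    counts <- round(a * c(0.5, 0.3, 0.2))
    log_state_probability(counts, rho, sum(counts))$per_customer_gap
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("optimal fold ratios follow exp(-gamma * tau_o)", {
  expect_equal(optimal_ratio(-2, 0.5), exp(1))
  expect_equal(optimal_ratio(0, c(0.5, 3)), c(1, 1))
  lr <- log(optimal_ratio(-1, c(0.5, 1)))
  expect_equal(lr, c(0.5, 1))
})

test_that("the constrained extremum conserves the divergence rate", {
  # symmetric case: identical nodes share the fold change
  opt <- maximize_kld(c(0.1, 0.1), c(2, 2), tau = 1)
  expect_equal(opt$rho_t[1], opt$rho_t[2])

  set.seed(7)
  for (i in 1:6) {
    n <- sample(2:5, 1)
    rho <- runif(n, 0.01, 0.3)
    tau_o <- runif(n, 0.5, 20)
    tau <- runif(1, 1.2, 3) * sum(rho * tau_o)
    opt <- maximize_kld(rho, tau_o, tau)
    # stationarity: lambda_o * log fold is node-independent
    expect_lt(opt$stationarity_residual, 1e-6)
    # budget met and D = -gamma * tau
    expect_equal(opt$budget, tau, tolerance = 1e-10)
    expect_lt(abs(opt$divergence + opt$gamma * tau), 1e-8)
    # agreement with the independent brute-force system solver
    oracle <- penalty_stationarity_oracle(rho, tau_o, tau)
    expect_equal(opt$rho_t, oracle$rho_t, tolerance = 1e-6)
    expect_equal(opt$gamma, oracle$gamma, tolerance = 1e-6)
  }
  expect_error(maximize_kld(c(0.1), c(1), tau = -1), "budget")
})

test_that("the literal-derivative variant satisfies its own condition", {
  rho <- c(0.05, 0.1, 0.02); tau_o <- c(4, 9, 13); tau <- 2
  lit <- maximize_kld(rho, tau_o, tau, constant = "literal")
  expect_equal(log(lit$rho_t / rho), -1 - lit$gamma * tau_o,
               tolerance = 1e-10)
  expect_equal(lit$budget, tau, tolerance = 1e-10)
  # the literal state is the true interior critical point of D on the
  # budget set: a penalty-method minimizer of D lands on it
  expect_equal(lit$rho_t, penalty_min_divergence(rho, tau_o, tau),
               tolerance = 1e-4)
  # equal dwell times: both conventions give the same state
  rho2 <- c(0.1, 0.2); tau_o2 <- c(3, 3)
  a <- maximize_kld(rho2, tau_o2, 2)
  b <- maximize_kld(rho2, tau_o2, 2, constant = "literal")
  expect_equal(a$rho_t, b$rho_t, tolerance = 1e-10)
})

test_that("entropy changes reduce to log fold ratios, potentials cancel", {
  expect_equal(entropy_change(1), 0)
  expect_equal(entropy_change(exp(1)), 1)
  expect_error(entropy_change(0), "positive")
  # chemical-potential route: any reference potential cancels
  rho <- 0.2; rho_t <- 0.35
  for (mu0 in c(-3, 0, 17)) {
    ds <- (chemical_potential(rho_t, mu0, kT = 2.5) -
             chemical_potential(rho, mu0, kT = 2.5)) / 2.5
    expect_equal(ds, entropy_change(rho_t / rho))
  }
})

test_that("total entropy change equals the divergence identically", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    rho <- runif(n, 0.01, 0.6)
    rho_t <- runif(n, 0, 0.8)
    expect_equal(total_entropy_change(rho_t, rho),
                 kld(rho_t, rho)$divergence, tolerance = 1e-12)
  }
  rho <- c(0.1, 0.4)
  expect_equal(total_entropy_change(rho, rho), 0)
  # at the extremum: Delta S = -gamma * tau
  opt <- maximize_kld(c(0.1, 0.05), c(2, 5), tau = 1)
  expect_equal(total_entropy_change(opt$rho_t, c(0.1, 0.05)),
               -opt$gamma * opt$tau, tolerance = 1e-10)
})
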