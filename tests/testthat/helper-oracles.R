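# Independent oracles and fixture builders used across the suite.

paper_grid <- c(0, 15, 30, 45, 60, 120, 180)

# random open, stable network with external arrivals at every node
random_open_spec <- function(n, seed) {
  set.seed(seed)
  lambda_o <- runif(n, 0.05, 0.5)
  routing <- matrix(runif(n * n, 0, 1), n, n)
  routing <- routing / rowSums(routing) * runif(n, 0.2, 0.8)
  # service rates chosen so every utilization is comfortably below 1
  lambda <- solve(diag(n) - t(routing), lambda_o)
  mu <- lambda / runif(n, 0.1, 0.8)
  cascade_spec(paste0("n", seq_len(n)), lambda_o, mu, routing)
}

# fixed-point iteration of the traffic balance, independent of solve()
traffic_fixed_point <- function(spec, iters = 10000) {
  lam <- unname(spec$lambda_o)
  for (i in seq_len(iters))
    lam <- unname(spec$lambda_o) + as.numeric(t(spec$routing) %*% lam)
  lam
}

# Brute-force solver for the conserved-rate stationarity system
#   lambda_oi * log(x_i / rho_i) + gamma = 0  (all i),
#   sum(x_i * tau_oi) = tau,
# treated as a penalized least-squares problem over (log x, gamma) and
# polished by finite-difference Newton. Shares nothing with the
# package's one-dimensional root-finder.
penalty_stationarity_oracle <- function(rho, tau_o, tau) {
  n <- length(rho)
  resids <- function(z) {
    x <- exp(z[1:n]); g <- z[n + 1]
    c((z[1:n] - log(rho)) / tau_o + g, sum(x * tau_o) - tau)
  }
  obj <- function(z) sum(resids(z)^2)
  z <- c(log(rho), 0)
  z <- optim(z, obj, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-16))$par
  for (it in 1:30) {                     # generic FD-Newton on the system
    f0 <- resids(z)
    if (max(abs(f0)) < 1e-12) break
    jac <- matrix(0, n + 1, n + 1)
    h <- 1e-7
    for (j in seq_len(n + 1)) {
      dz <- z; dz[j] <- dz[j] + h
      jac[, j] <- (resids(dz) - f0) / h
    }
    step <- tryCatch(solve(jac, f0), error = function(e) rep(0, n + 1))
    z <- z - step
  }
  list(rho_t = exp(z[1:n]), gamma = z[n + 1])
}

# Generic *minimizer* of the divergence on the budget set -- the interior
# critical point of D itself (the literal-derivative state). The budget
# is eliminated exactly (last coordinate solved from the constraint) and
# the reduced problem handed to a quasi-Newton optimizer.
penalty_min_divergence <- function(rho, tau_o, tau) {
  n <- length(rho)
  expand <- function(lx) {
    x_free <- exp(lx)
    x_last <- (tau - sum(x_free * tau_o[-n])) / tau_o[n]
    c(x_free, x_last)
  }
  obj <- function(lx) {
    x <- expand(lx)
    if (x[n] <= 0) return(1e10 + sum(lx^2))
    sum(x * log(x / rho))
  }
  lx0 <- log(rho * tau / sum(rho * tau_o))[-n]
  fit <- optim(lx0, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
  expand(fit$par)
}

# fine-grid trapezoid estimate of the divergence rate of a continuous
# fold-ratio curve over [0, t_end] (minutes), rate in nats/h
quadrature_rate <- function(f, t_end, n = 20001) {
  tt <- seq(0, t_end, length.out = n)
  rr <- f(tt)
  mean_fold <- sum(diff(tt) * (head(rr, -1) + tail(rr, -1)) / 2) / t_end
  log(mean_fold) / (t_end / 60)
}

# analytic piecewise-linear integral of a sampled curve on [0, tau]
piecewise_linear_mean <- function(times, ratios, tau) {
  f <- approxfun(times, ratios)
  integrate(f, 0, tau, subdivisions = 10000, rel.tol = 1e-12)$value / tau
}

expect_snapshot_equalish <- function(x, y, tol = 1e-10) {
  expect_true(max(abs(x - y)) < tol)
}
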