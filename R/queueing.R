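#' Solve the traffic equations of an open Jackson network
#'
#' Computes the effective arrival rate at each node from the balance
#' \deqn{\lambda_i = \lambda_{oi} + \sum_j \lambda_j r_{j \to i},}
#' the traffic equation of the network. Openness (routing spectral
#' radius below 1) guarantees the linear system has a unique solution.
#'
#' @param spec a [cascade_spec()].
#' @return named numeric vector of effective arrival rates
#'   \eqn{\lambda_i}.
#' @examples
#' spec <- tandem_cascade_spec(3, lambda_in = c(0.5, 0.2, 0), mu = 1)
#' solve_traffic(spec)  # 0.5, 0.7, 0.7
#' @export
solve_traffic <- function(spec) {
  stopifnot(inherits(spec, "cascade_spec"))
  n <- length(spec$labels)
  a <- diag(n) - t(spec$routing)
  lambda <- tryCatch(solve(a, unname(spec$lambda_o)),
                     error = function(e) stop("network not open: ",
                                              conditionMessage(e)))
  stats::setNames(as.numeric(lambda), spec$labels)
}

#' Node utilizations
#'
#' \eqn{\rho_i = \lambda_i / \mu_i}, the dimensionless ratio of effective
#' arrival rate to service rate. A single-server node is stable only when
#' \eqn{\rho_i < 1}; utilizations at or above \eqn{1 - 10^{-12}} trigger a
#' warning and are flagged via the `"stable"` attribute.
#'
#' @param lambda numeric vector of effective arrival rates.
#' @param mu numeric vector of service rates (positive).
#' @return numeric vector of utilizations with a logical `"stable"`
#'   attribute.
#' @export
utilizations <- function(lambda, mu) {
  if (any(mu <= 0)) stop("service rates must be positive")
  if (any(lambda < 0)) stop("arrival rates must be non-negative")
  rho <- lambda / mu
  stable <- all(rho < 1 - 1e-12)
  if (!stable)
    warning("unstable network: some utilization >= 1; queue lengths diverge")
  attr(rho, "stable") <- stable
  rho
}

.check_stable <- function(rho) {
  if (any(rho < 0)) stop("utilizations must be non-negative")
  if (any(rho >= 1 - 1e-12))
    stop("unstable utilization (rho >= 1); stationary distribution undefined")
  invisible(rho)
}

#' Product-form stationary probability of a network state
#'
#' Jackson's theorem: the stationary occupancy distribution of an open
#' network factorizes into per-node geometric marginals,
#' \deqn{p(a) = \prod_i \rho_i^{a_i} (1 - \rho_i).}
#'
#' @param rho utilization vector, all below 1.
#' @param state non-negative integer occupancy vector \eqn{a_i}.
#' @param log if `TRUE`, return the log probability.
#' @return the stationary probability of `state`.
#' @examples
#' stationary_probability(c(0.5, 0.5), c(1, 1))  # 0.0625
#' @export
stationary_probability <- function(rho, state, log = FALSE) {
  .check_stable(rho)
  if (length(state) != length(rho)) stop("state and rho lengths differ")
  if (any(state < 0) || any(state != round(state)))
    stop("occupancies must be non-negative integers")
  lp <- sum(state * base::log(rho) + log1p(-rho))
  if (log) lp else exp(lp)
}

#' Mean queue lengths and Little's-law total
#'
#' For a stable single-server node the stationary mean number in system
#' is \eqn{L_i = \rho_i / (1 - \rho_i)}; the network total is
#' \eqn{L = \sum_i L_i}. In the light-traffic regime
#' \eqn{\lambda_i/\mu_i \ll 1} this is approximated by \eqn{\sum_i
#' \rho_i}, which is also returned.
#'
#' @param rho utilization vector, all below 1.
#' @return list with `L_i` (per-node means), `L` (total) and
#'   `L_light_traffic` (the \eqn{\sum \rho_i} approximation).
#' @export
mean_queue_lengths <- function(rho) {
  .check_stable(rho)
  l <- rho / (1 - rho)
  list(L_i = l, L = sum(l), L_light_traffic = sum(rho))
}

#' Poisson arrival-count probability
#'
#' Probability that a Poisson stream of rate `lambda` delivers exactly
#' `k` customers in time `t`. Thin wrapper over [stats::dpois()] kept as
#' the package's named primitive for the arrival model.
#'
#' @param lambda arrival rate (non-negative).
#' @param t elapsed time (non-negative).
#' @param k non-negative integer count (vectorized).
#' @return numeric probability vector.
#' @export
arrival_count_pmf <- function(lambda, t, k) {
  if (lambda < 0 || t < 0) stop("rate and time must be non-negative")
  if (any(k < 0) || any(k != round(k)))
    stop("counts must be non-negative integers")
  stats::dpois(k, lambda * t)
}

#' Total signal duration implied by an occupancy vector
#'
#' The duration budget \eqn{\tau = \sum_i a_i \tau_{oi} = \sum_i a_i /
#' \lambda_{oi}}, where \eqn{\tau_{oi} = 1/\lambda_{oi}} is the mediator
#' dwell time attributable to one customer at node \eqn{i}. Nodes with
#' zero occupancy contribute nothing regardless of their external rate.
#'
#' @param a occupancy vector (non-negative).
#' @param lambda_o external arrival rates; must be positive wherever
#'   `a > 0`.
#' @return the total duration \eqn{\tau}.
#' @export
total_duration <- function(a, lambda_o) {
  if (length(a) != length(lambda_o)) stop("length mismatch")
  if (any(a < 0)) stop("occupancies must be non-negative")
  active <- a > 0
  if (any(lambda_o[active] <= 0))
    stop("zero external arrival rate at an occupied node: duration undefined")
  sum(a[active] / lambda_o[active])
}

#' Steady state of an open Jackson network
#'
#' Solves the traffic equations, checks stability, and assembles the
#' pre-stimulus steady state: effective arrival rates, utilizations,
#' mean queue lengths (exact and light-traffic), the total customer
#' number, and per-node durations \eqn{\tau_{oi} = 1/\lambda_{oi}}
#' (infinite where the node receives no external arrivals).
#'
#' @param spec a [cascade_spec()].
#' @return an object of class `jqn_steady_state`: list with `lambda`,
#'   `rho`, `L_i`, `L`, `a` (total customers, equal to `L`),
#'   `a_light_traffic` (\eqn{\sum \rho_i}), and `tau_o`.
#' @export
steady_state <- function(spec) {
  stopifnot(inherits(spec, "cascade_spec"))
  lambda <- solve_traffic(spec)
  rho <- lambda / spec$mu
  if (any(rho >= 1 - 1e-12))
    stop("unstable network: utilization >= 1 at ",
         paste(spec$labels[rho >= 1 - 1e-12], collapse = ", "))
  ql <- mean_queue_lengths(rho)
  tau_o <- ifelse(spec$lambda_o > 0, 1 / spec$lambda_o, Inf)
  structure(list(spec = spec, lambda = lambda, rho = rho,
                 L_i = ql$L_i, L = ql$L, a = ql$L,
                 a_light_traffic = ql$L_light_traffic,
                 tau_o = stats::setNames(tau_o, spec$labels)),
            class = "jqn_steady_state")
}

#' @export
print.jqn_steady_state <- function(x, ...) {
  cat("Jackson-network steady state (total customers L =",
      format(x$L, digits = 4), ")\n")
  print(data.frame(node = x$spec$labels, lambda = unname(x$lambda),
                   rho = unname(x$rho), L_i = unname(x$L_i),
                   tau_o = unname(x$tau_o), row.names = NULL), ...)
  invisible(x)
}
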