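#' Kullback-Leibler divergence of a signalling state
#'
#' The information gain of the stimulated network state
#' \eqn{\{\rho_i(t)\}} over the pre-stimulus steady state
#' \eqn{\{\rho_i\}},
#' \deqn{D(\rho(t) \| \rho) = \sum_i \rho_i(t)\,
#'   \log\frac{\rho_i(t)}{\rho_i},}
#' in nats (natural logarithm throughout; the thermodynamic mapping to
#' entropy in units of \eqn{k_B} forces the natural base). A term with
#' \eqn{\rho_i(t) = 0} contributes 0 by the continuity convention
#' \eqn{0\log 0 = 0}; \eqn{\rho_i = 0} with \eqn{\rho_i(t) > 0} makes
#' the divergence infinite. Note the utilization vectors need not be
#' normalized; \eqn{D \ge 0} is guaranteed only when both share the same
#' total mass.
#'
#' @param rho_t non-negative signalling-state utilizations
#'   \eqn{\rho_i(t)}.
#' @param rho positive steady-state utilizations \eqn{\rho_i}.
#' @param tau optional total signal duration; when supplied, the rate
#'   fields of the result are populated with \eqn{-\gamma = D/\tau}.
#' @return object of class `kld_result`: list with `divergence` (nats),
#'   `per_node` contributions, and (when `tau` is given) `gamma` and
#'   `kld_rate`.
#' @examples
#' kld(c(0.4, 0.1), c(0.2, 0.3))$divergence  # ~0.1674
#' @export
kld <- function(rho_t, rho, tau = NULL) {
  if (length(rho_t) != length(rho)) stop("length mismatch")
  if (any(rho_t < 0) || any(rho < 0)) stop("utilizations must be >= 0")
  per <- ifelse(rho_t > 0, rho_t * log(rho_t / rho), 0)
  d <- sum(per)
  res <- list(divergence = d, per_node = per,
              gamma = if (!is.null(tau)) -d / tau else NA_real_,
              kld_rate = if (!is.null(tau)) d / tau else NA_real_,
              tau = if (!is.null(tau)) tau else NA_real_)
  class(res) <- "kld_result"
  res
}

#' @export
print.kld_result <- function(x, ...) {
  cat("KLD D =", format(x$divergence, digits = 6), "nats")
  if (!is.na(x$kld_rate))
    cat("; rate -gamma = D/tau =", format(x$kld_rate, digits = 6))
  cat("\n")
  invisible(x)
}

#' Exact and Stirling log-probability of a repeated-signalling state
#'
#' When the complete transduction event repeats \eqn{a} times in total
#' and \eqn{a_i(t)} times at node \eqn{i}, the probability of the state
#' is the multinomial weight times the product-form factor,
#' \eqn{\frac{a!}{\prod_i a_i(t)!} \prod_i \rho_i^{a_i(t)}}. Its
#' logarithm is computed exactly via log-gamma functions and compared
#' with the Stirling-approximation form \eqn{-a\,D(f \| \rho)} where
#' \eqn{f_i = a_i(t)/a} are the occupancy fractions. The absolute gap is
#' the Stirling error of the multinomial coefficient, which grows like
#' \eqn{\tfrac{n-1}{2}\log a} while both terms grow like \eqn{a}, so the
#' per-customer gap vanishes as \eqn{a \to \infty}.
#'
#' @param counts non-negative integer occupancy counts \eqn{a_i(t)}.
#' @param rho positive steady-state utilizations.
#' @param a total repetition number; must equal `sum(counts)`.
#' @return list with `exact`, `stirling` (\eqn{-aD}), `gap` and
#'   `per_customer_gap` (`gap / a`).
#' @export
log_state_probability <- function(counts, rho, a = sum(counts)) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(counts) != length(rho)) stop("length mismatch")
  if (any(rho <= 0)) stop("steady-state utilizations must be positive")
  if (sum(counts) != a) stop("counts must sum to `a`")
  exact <- lgamma(a + 1) - sum(lgamma(counts + 1)) + sum(counts * log(rho))
  f <- counts / a
  stirling <- -a * sum(ifelse(f > 0, f * log(f / rho), 0))
  gap <- abs(exact - stirling)
  list(exact = exact, stirling = stirling, gap = gap,
       per_customer_gap = gap / a)
}

#' Fold change implied by the conserved divergence rate
#'
#' At the budget-constrained extremum the per-node log fold change is
#' proportional to the node's dwell time,
#' \eqn{\log(\rho_i(t)/\rho_i) = -\gamma\,\tau_{oi}}; this returns the
#' fold ratio \eqn{e^{-\gamma\tau_{oi}}}.
#'
#' @param gamma signed rate parameter (the divergence rate is
#'   \eqn{-\gamma}).
#' @param tau_o per-node duration(s) \eqn{\tau_{oi} > 0}.
#' @return fold ratio(s) \eqn{\rho_i(t)/\rho_i}.
#' @export
optimal_ratio <- function(gamma, tau_o) {
  if (any(tau_o <= 0)) stop("durations must be positive")
  exp(-gamma * tau_o)
}

#' Budget-constrained extremum of the Kullback-Leibler divergence
#'
#' Finds the signalling state \eqn{\{\rho_i(t)\}} that makes the
#' divergence \eqn{D(\rho(t)\|\rho)} stationary under the
#' signal-duration budget \eqn{\sum_i \rho_i(t)\,\tau_{oi} = \tau}
#' (Lagrangian \eqn{F = D + \gamma \sum_i \rho_i(t)\tau_{oi}}). The
#' stationarity condition makes \eqn{\lambda_{oi}\log(\rho_i(t)/\rho_i)}
#' the same at every node; its negated common value is the multiplier
#' \eqn{\gamma}, giving \eqn{\rho_i(t) = \rho_i e^{-\gamma\tau_{oi}}}
#' and the conservation identity \eqn{-\gamma = D/\tau} exactly. The
#' solution is computed by one-dimensional root finding in \eqn{\gamma}
#' on the strictly monotone budget function, followed by Newton
#' polishing to machine precision.
#'
#' With `constant = "absorbed"` (the default) the additive constant from
#' differentiating \eqn{x\log x} is absorbed into \eqn{\gamma}, so the
#' returned state satisfies \eqn{\log(\rho_i(t)/\rho_i) =
#' -\gamma\tau_{oi}}. With `constant = "literal"` the raw stationarity
#' condition \eqn{\log(\rho_i(t)/\rho_i) = -1 - \gamma\tau_{oi}} is
#' solved instead; the two parameterizations coincide when all
#' \eqn{\tau_{oi}} are equal and otherwise describe slightly different
#' states (the literal one is the calculus stationary point of the
#' Lagrangian term by term).
#'
#' @param rho positive steady-state utilizations.
#' @param tau_o positive per-node durations \eqn{\tau_{oi} =
#'   1/\lambda_{oi}}.
#' @param tau positive total duration budget.
#' @param constant `"absorbed"` or `"literal"`; see Details.
#' @return list with `rho_t` (the extremal state), `gamma`,
#'   `divergence`, `kld_rate` (\eqn{-\gamma}), `budget` (achieved
#'   \eqn{\sum \rho_i(t)\tau_{oi}}), and `stationarity_residual`
#'   \eqn{\max_i |\lambda_{oi}\log(\rho_i(t)/\rho_i) + \gamma|}.
#' @examples
#' rho <- c(0.02, 0.03); tau_o <- c(10, 20)
#' opt <- maximize_kld(rho, tau_o, tau = 2)
#' opt$divergence / opt$tau  # equals -opt$gamma
#' @export
maximize_kld <- function(rho, tau_o, tau,
                         constant = c("absorbed", "literal")) {
  constant <- match.arg(constant)
  if (any(rho <= 0)) stop("steady-state utilizations must be positive")
  if (any(tau_o <= 0)) stop("per-node durations must be positive")
  if (length(rho) != length(tau_o)) stop("length mismatch")
  if (!is.finite(tau) || tau <= 0) stop("infeasible budget: need tau > 0")
  off <- if (constant == "literal") -1 else 0
  budget <- function(g) sum(rho * exp(off - g * tau_o) * tau_o)
  # bracket the root of budget(g) = tau: budget is strictly decreasing
  lo <- -1; hi <- 1
  while (budget(lo) < tau) lo <- lo * 2
  while (budget(hi) > tau) hi <- hi * 2
  g <- stats::uniroot(function(g) budget(g) - tau, c(lo, hi),
                      tol = .Machine$double.eps^0.75)$root
  for (i in 1:5) {                      # Newton polish
    num <- budget(g) - tau
    den <- -sum(rho * exp(off - g * tau_o) * tau_o^2)
    step <- num / den
    if (!is.finite(step) || step == 0) break
    g <- g - step
  }
  rho_t <- rho * exp(off - g * tau_o)
  achieved <- sum(rho_t * tau_o)
  if (abs(achieved - tau) > 1e-8 * max(1, tau))
    stop("budget root-finding failed to converge (residual ",
         format(achieved - tau), ")")
  d <- kld(rho_t, rho)$divergence
  lam_o <- 1 / tau_o
  resid <- if (constant == "absorbed")
    max(abs(lam_o * log(rho_t / rho) + g))
  else                                   # literal: log ratio = -1 - g*tau_o
    max(abs(lam_o * (log(rho_t / rho) + 1) + g))
  list(rho_t = rho_t, gamma = g, divergence = d,
       kld_rate = -g, tau = tau, budget = achieved,
       stationarity_residual = resid, constant = constant)
}

#' Chemical potential of a node state
#'
#' \eqn{\mu_i = \mu_{i0} + k_B T \log\rho_i}: the reference potential
#' plus the thermal energy times the log occupancy. Only differences of
#' potentials are physically identified here, so `mu0` cancels from all
#' entropy changes.
#'
#' @param rho positive utilization(s).
#' @param mu0 reference potential(s); default 0.
#' @param kT thermal energy \eqn{k_B T > 0}; default 1.
#' @return chemical potential(s), same units as `mu0` and `kT`.
#' @export
chemical_potential <- function(rho, mu0 = 0, kT = 1) {
  if (any(rho <= 0)) stop("utilizations must be positive")
  if (kT <= 0) stop("thermal energy must be positive")
  mu0 + kT * log(rho)
}

#' Per-node entropy change of signalling
#'
#' The dimensionless (units of \eqn{k_B}) entropy change between the
#' pre-signal and signalling states,
#' \eqn{\Delta s_i = (\mu_i - \mu_i^{st})/k_BT =
#' \log(\rho_i(t)/\rho_i)}; the reference potential cancels.
#'
#' @param ratio positive fold ratio(s) \eqn{\rho_i(t)/\rho_i}.
#' @return entropy change(s) in units of \eqn{k_B}.
#' @export
entropy_change <- function(ratio) {
  if (any(ratio <= 0)) stop("fold ratios must be positive")
  log(ratio)
}

#' Total thermodynamic entropy change of signalling
#'
#' \eqn{\Delta S = \sum_i \rho_i(t)\,\Delta s_i}, which is numerically
#' identical to the Kullback-Leibler divergence
#' \eqn{D(\rho(t)\|\rho)}; at the budget-constrained extremum it also
#' equals \eqn{-\gamma\tau}.
#'
#' @inheritParams kld
#' @return total entropy change in units of \eqn{k_B} (nats).
#' @export
total_entropy_change <- function(rho_t, rho) {
  if (length(rho_t) != length(rho)) stop("length mismatch")
  if (any(rho_t < 0) || any(rho <= 0))
    stop("need rho_t >= 0 and rho > 0")
  pos <- rho_t > 0
  sum(rho_t[pos] * entropy_change(rho_t[pos] / rho[pos]))
}
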