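#' Simulate an open Jackson network
#'
#' Discrete-event simulation of the network described by `spec`: Poisson
#' external arrivals at rate \eqn{\lambda_{oi}}, exponential
#' first-come-first-served service at rate \eqn{\mu_i} on a single
#' server per node, and probabilistic routing on service completion.
#' Statistics (time-averaged occupancy, throughput, mean sojourn, and
#' the time-weighted occupancy distribution per node) are accumulated on
#' `[burn_in, horizon]`. Trajectories are deterministic given `seed`;
#' the per-node random streams are derived independently from the master
#' seed so that adding a node does not perturb the others.
#'
#' @param spec a [cascade_spec()]; must be stable (all \eqn{\rho_i < 1}).
#' @param horizon total simulated time (model time units).
#' @param burn_in initial time span discarded from all statistics;
#'   default 10\% of the horizon.
#' @param seed integer master seed.
#' @param max_events optional cap on the number of processed events.
#' @param keep_log if `TRUE`, retain the full event log (grows with the
#'   event count; intended for short runs).
#' @return an object of class `jqn_trajectory`: list with `summary` (a
#'   data frame of per-node time-averaged occupancy, throughput, mean
#'   sojourn, completion counts and Little's-law residuals), `occ_time`
#'   (per-node time spent at each occupancy count), `departures`,
#'   `observed_time`, `n_events`, and optionally `events`.
#' @examples
#' spec <- tandem_cascade_spec(1, lambda_in = 0.5, mu = 1)
#' traj <- simulate_jqn(spec, horizon = 2e4, seed = 1)
#' traj$summary$time_avg_occupancy  # close to rho/(1-rho) = 1
#' @export
simulate_jqn <- function(spec, horizon, burn_in = 0.1 * horizon, seed = 1,
                         max_events = Inf, keep_log = FALSE) {
  stopifnot(inherits(spec, "cascade_spec"))
  if (horizon < 0 || burn_in < 0 || burn_in > horizon)
    stop("need horizon > burn_in >= 0")
  rho <- utilizations(solve_traffic(spec), spec$mu)
  if (!attr(rho, "stable"))
    stop("refusing to simulate an unstable network (some rho >= 1)")
  raw <- .jqn_des(unname(spec$lambda_o), unname(spec$mu),
                  unname(spec$routing), horizon, burn_in,
                  as.numeric(seed) %% 2^31, as.numeric(max_events), keep_log)
  lw <- raw$throughput * raw$mean_sojourn
  summary <- data.frame(
    node = spec$labels,
    time_avg_occupancy = raw$time_avg_occupancy,
    throughput = raw$throughput,
    mean_sojourn = raw$mean_sojourn,
    completions = raw$completions,
    littles_residual = ifelse(raw$time_avg_occupancy > 0,
                              abs(raw$time_avg_occupancy - lw) /
                                raw$time_avg_occupancy, NA_real_),
    row.names = NULL)
  occ_time <- raw$occ_time
  names(occ_time) <- spec$labels
  structure(list(spec = spec, horizon = horizon, burn_in = burn_in,
                 seed = seed, summary = summary, occ_time = occ_time,
                 departures = raw$departures,
                 observed_time = raw$observed_time,
                 end_time = raw$end_time, n_events = raw$n_events,
                 events = raw$events),
            class = "jqn_trajectory")
}

#' @export
print.jqn_trajectory <- function(x, ...) {
  cat("JQN trajectory:", format(x$n_events, big.mark = ","),
      "events over", format(x$end_time), "time units (burn-in",
      format(x$burn_in), ")\n")
  print(x$summary, ...)
  invisible(x)
}

#' Time-weighted empirical occupancy distribution at a node
#'
#' The fraction of post-burn-in time the node spent at each occupancy
#' count; under the product-form stationary law this converges to the
#' geometric distribution \eqn{\rho_i^{a}(1-\rho_i)}.
#'
#' @param traj a [simulate_jqn()] trajectory.
#' @param node node index or label.
#' @return named numeric vector: probabilities for counts `0, 1, ...`,
#'   summing to 1.
#' @export
empirical_occupancy_pmf <- function(traj, node) {
  stopifnot(inherits(traj, "jqn_trajectory"))
  w <- traj$occ_time[[node]]
  if (is.null(w) || sum(w) <= 0)
    stop("empty trajectory: no observed time past burn-in")
  stats::setNames(w / sum(w), seq_along(w) - 1L)
}

#' Empirical Little's-law summary
#'
#' Per node, returns the time-averaged number in system \eqn{\hat L},
#' the throughput \eqn{\hat\lambda} (completions per unit observed
#' time), the mean sojourn \eqn{\hat W}, and the relative residual
#' \eqn{|\hat L - \hat\lambda \hat W| / \hat L}. On a window whose
#' endpoints find the system empty, Little's law is an identity and the
#' residual vanishes to rounding error; pass such a `window` (requires a
#' trajectory simulated with `keep_log = TRUE`) to verify this.
#'
#' @param traj a [simulate_jqn()] trajectory.
#' @param window optional numeric `c(t0, t1)`; statistics are then
#'   recomputed exactly on the window from the event log, and an error
#'   is raised if customers are present at either endpoint.
#' @param min_completions minimum completed customers required per node.
#' @return data frame with columns `node`, `L_hat`, `lambda_hat`,
#'   `W_hat`, `completions`, `littles_residual`.
#' @export
empirical_little <- function(traj, window = NULL, min_completions = 100) {
  stopifnot(inherits(traj, "jqn_trajectory"))
  if (is.null(window)) {
    s <- traj$summary
    if (any(s$completions < min_completions))
      stop("too few completed customers per node (minimum ",
           paste(s$completions, collapse = ", "), " observed; need ",
           min_completions, ")")
    return(s[, c("node", "time_avg_occupancy", "throughput", "mean_sojourn",
                 "completions", "littles_residual")])
  }
  ev <- traj$events
  if (is.null(ev)) stop("window statistics need keep_log = TRUE")
  n <- length(traj$spec$labels)
  t0 <- window[1]; t1 <- window[2]
  occ <- .occupancy_steps(ev, n)
  occ_at <- function(tt) {
    idx <- findInterval(tt, occ$time)
    if (idx == 0) rep(0L, n) else occ$counts[idx, , drop = TRUE]
  }
  if (sum(occ_at(t0)) != 0 || sum(occ_at(t1)) != 0)
    stop("window endpoints must find the system empty")
  inside <- ev$time > t0 & ev$time <= t1
  # per-visit sojourns via FCFS reconstruction (all visits lie inside)
  entry <- vector("list", n)
  soj_sum <- numeric(n); comp <- numeric(n); tint <- numeric(n)
  evs <- ev[inside, , drop = FALSE]
  for (r in seq_len(nrow(evs))) {
    tt <- evs$time[r]; nd <- evs$node[r]; kd <- evs$kind[r]
    if (kd == 1) {                       # external arrival
      entry[[nd]] <- c(entry[[nd]], tt)
    } else {                             # completion at nd
      soj_sum[nd] <- soj_sum[nd] + (tt - entry[[nd]][1])
      entry[[nd]] <- entry[[nd]][-1]
      comp[nd] <- comp[nd] + 1
      if (kd == 2) {
        dd <- evs$dest[r]
        entry[[dd]] <- c(entry[[dd]], tt)
      }
    }
  }
  # time-integral of occupancy over the window
  for (i in seq_len(n)) {
    ts <- c(t0, occ$time[occ$time > t0 & occ$time <= t1], t1)
    cs <- vapply(ts[-length(ts)],
                 function(tt) occ_at(tt)[i], numeric(1))
    tint[i] <- sum(cs * diff(ts))
  }
  l_hat <- tint / (t1 - t0)
  lam_hat <- comp / (t1 - t0)
  w_hat <- ifelse(comp > 0, soj_sum / comp, NA_real_)
  data.frame(node = traj$spec$labels, time_avg_occupancy = l_hat,
             throughput = lam_hat, mean_sojourn = w_hat,
             completions = comp,
             littles_residual = ifelse(l_hat > 0,
                                       abs(l_hat - lam_hat * w_hat) / l_hat,
                                       0),
             row.names = NULL)
}

# step-function occupancy from an event log: times plus the occupancy
# matrix holding counts valid from each event time (inclusive) onward
.occupancy_steps <- function(ev, n) {
  m <- nrow(ev)
  delta <- matrix(0L, m, n)
  arr <- ev$kind == 1
  delta[cbind(which(arr), ev$node[arr])] <- 1L
  cmp <- ev$kind %in% c(2, 3)
  delta[cbind(which(cmp), ev$node[cmp])] <- delta[cbind(which(cmp),
                                                        ev$node[cmp])] - 1L
  trf <- ev$kind == 2
  delta[cbind(which(trf), ev$dest[trf])] <-
    delta[cbind(which(trf), ev$dest[trf])] + 1L
  counts <- apply(delta, 2, cumsum)
  if (m == 1) counts <- matrix(counts, 1, n)
  list(time = ev$time, counts = counts)
}

#' Joint time-weighted occupancy distribution of two nodes
#'
#' Reconstructs, from the event log, the fraction of time the pair of
#' nodes spent in each joint occupancy state on `[burn_in, end]`. Used
#' to check the across-node independence implied by the product-form
#' stationary distribution.
#'
#' @param traj a [simulate_jqn()] trajectory with `keep_log = TRUE`.
#' @param nodes integer vector of two node indices.
#' @return matrix of joint probabilities; rows index the first node's
#'   count (from 0), columns the second node's.
#' @export
joint_occupancy_pmf <- function(traj, nodes = c(1L, 2L)) {
  stopifnot(inherits(traj, "jqn_trajectory"), length(nodes) == 2)
  ev <- traj$events
  if (is.null(ev)) stop("joint pmf needs keep_log = TRUE")
  n <- length(traj$spec$labels)
  occ <- .occupancy_steps(ev, n)
  t0 <- traj$burn_in; t1 <- traj$end_time
  keep <- occ$time <= t1
  # state valid on [time_k, time_{k+1}); prepend the initial empty state
  c1 <- c(0L, occ$counts[keep, nodes[1]])
  c2 <- c(0L, occ$counts[keep, nodes[2]])
  starts <- c(0, occ$time[keep])
  ends <- c(occ$time[keep], t1)
  w <- pmax(pmin(ends, t1) - pmax(starts, t0), 0)
  tab <- tapply(w, list(factor(c1, levels = 0:max(c1)),
                        factor(c2, levels = 0:max(c2))), sum, default = 0)
  tab / sum(tab)
}
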