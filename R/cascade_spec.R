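#' Define an open Jackson network for a signalling cascade
#'
#' A `cascade_spec` describes an open Jackson queueing network (JQN) in
#' which the signal mediator (inorganic phosphate carried between kinases)
#' is the customer and each signalling molecule is a single-server
#' first-come-first-served node. External mediator arrivals at node
#' \eqn{i} follow a Poisson process with rate \eqn{\lambda_{oi}}; service
#' (phosphotransfer to the next molecule) is exponential with rate
#' \eqn{\mu_i}; on service completion the customer moves to node \eqn{j}
#' with probability \code{routing[i, j]} or leaves the network with the
#' residual probability \eqn{1 - \sum_j r_{i \to j}}.
#'
#' The network must be open: the routing matrix must have spectral radius
#' below 1 so that every customer eventually leaves. At least one external
#' arrival rate must be positive.
#'
#' @param labels character vector of molecule names, one per node.
#' @param lambda_o numeric vector of external arrival rates (events per
#'   unit time), one per node; all non-negative, at least one positive.
#' @param mu numeric vector of service rates (events per unit time), all
#'   positive.
#' @param routing numeric matrix; `routing[i, j]` is the probability that
#'   a customer finishing service at node `i` proceeds to node `j`.
#'   Defaults to the zero matrix (isolated queues). Row sums must not
#'   exceed 1.
#' @return an object of class `cascade_spec`.
#' @seealso [solve_traffic()], [steady_state()], [simulate_jqn()],
#'   [tandem_cascade_spec()]
#' @examples
#' spec <- tandem_cascade_spec(3, lambda_in = 0.5, mu = 1)
#' solve_traffic(spec)
#' @export
cascade_spec <- function(labels, lambda_o, mu, routing = NULL) {
  n <- length(labels)
  stopifnot(is.character(labels), n >= 1, !anyDuplicated(labels))
  lambda_o <- as.numeric(lambda_o)
  mu <- as.numeric(mu)
  if (length(lambda_o) != n || length(mu) != n)
    stop("`labels`, `lambda_o` and `mu` must have the same length")
  if (anyNA(lambda_o) || any(lambda_o < 0))
    stop("external arrival rates must be non-negative")
  if (!any(lambda_o > 0))
    stop("an open network needs at least one positive external arrival rate")
  if (anyNA(mu) || any(mu <= 0))
    stop("service rates must be positive")
  if (is.null(routing)) routing <- matrix(0, n, n)
  routing <- as.matrix(routing)
  if (!all(dim(routing) == c(n, n)))
    stop("`routing` must be an n x n matrix")
  if (anyNA(routing) || any(routing < 0) || any(routing > 1))
    stop("routing probabilities must lie in [0, 1]")
  if (any(rowSums(routing) > 1 + 1e-12))
    stop("routing row sums must not exceed 1")
  sr <- spectral_radius(routing)
  if (sr >= 1 - 1e-12)
    stop("network not open: routing spectral radius ", format(sr), " >= 1")
  dimnames(routing) <- list(labels, labels)
  structure(
    list(labels = labels, lambda_o = stats::setNames(lambda_o, labels),
         mu = stats::setNames(mu, labels), routing = routing),
    class = "cascade_spec")
}

spectral_radius <- function(m) {
  if (all(m == 0)) return(0)
  max(Mod(eigen(m, only.values = TRUE)$values))
}

#' @export
print.cascade_spec <- function(x, ...) {
  n <- length(x$labels)
  cat("Open Jackson network:", n, if (n == 1) "node\n" else "nodes\n")
  df <- data.frame(node = x$labels, lambda_o = unname(x$lambda_o),
                   mu = unname(x$mu),
                   p_leave = 1 - rowSums(x$routing), row.names = NULL)
  print(df, ...)
  invisible(x)
}

#' Convenience constructor for a one-directional cascade
#'
#' Builds a tandem chain in which node \eqn{i} routes to node \eqn{i+1}
#' with probability `forward` and the last node always leaves the
#' network; external arrivals can feed the head of the chain only or
#' every node.
#'
#' @param n number of nodes.
#' @param lambda_in external arrival rate(s): a scalar feeding node 1
#'   only, or a length-`n` vector.
#' @param mu service rate(s), scalar or length `n`.
#' @param forward probability of proceeding to the next node (last node
#'   always departs).
#' @param labels optional node names; default `node1 ... nodeN`.
#' @return a [cascade_spec()].
#' @export
tandem_cascade_spec <- function(n, lambda_in, mu, forward = 1,
                                labels = paste0("node", seq_len(n))) {
  lambda_o <- if (length(lambda_in) == 1L) c(lambda_in, rep(0, n - 1L))
              else as.numeric(lambda_in)
  mu <- rep_len(as.numeric(mu), n)
  routing <- matrix(0, n, n)
  if (n > 1) routing[cbind(seq_len(n - 1L), seq(2L, n))] <- forward
  cascade_spec(labels, lambda_o, mu, routing)
}

#' Read or write a cascade specification as YAML
#'
#' The on-disk form is a mapping with keys `labels`, `lambda_o`, `mu` and
#' `routing` (a list of rows).
#'
#' @param path file path.
#' @return `read_cascade_spec()` returns a [cascade_spec()];
#'   `write_cascade_spec()` returns `path` invisibly.
#' @export
read_cascade_spec <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("labels", "lambda_o", "mu", "routing"))
    if (is.null(y[[k]])) stop("cascade YAML is missing field `", k, "`")
  routing <- do.call(rbind, lapply(y$routing, as.numeric))
  cascade_spec(as.character(y$labels), as.numeric(y$lambda_o),
               as.numeric(y$mu), routing)
}

#' @rdname read_cascade_spec
#' @param spec a [cascade_spec()].
#' @export
write_cascade_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cascade_spec"))
  y <- list(labels = spec$labels,
            lambda_o = unname(spec$lambda_o),
            mu = unname(spec$mu),
            routing = lapply(seq_along(spec$labels),
                             function(i) unname(spec$routing[i, ])))
  yaml::write_yaml(y, path)
  invisible(path)
}
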