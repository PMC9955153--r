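#' Construct a fold-phosphorylation time course
#'
#' One molecule-by-replicate curve of the fold-phosphorylation ratio
#' \eqn{a_i(t)/a_i} (phospho signal relative to the unstimulated
#' baseline) over the sampling grid. Times are in minutes, strictly
#' increasing and starting at 0, where the ratio is 1 by normalization.
#'
#' @param molecule molecule label.
#' @param replicate replicate identifier.
#' @param times sample times in minutes; at least 3, strictly
#'   increasing, first equal to 0.
#' @param ratios fold ratios, non-negative, same length as `times`.
#' @return object of class `time_course`.
#' @export
time_course <- function(molecule, replicate, times, ratios) {
  times <- as.numeric(times); ratios <- as.numeric(ratios)
  if (length(times) < 3) stop("need at least 3 samples")
  if (length(times) != length(ratios)) stop("times/ratios length mismatch")
  if (times[1] != 0) stop("first sample time must be 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (anyNA(ratios) || any(ratios < 0)) stop("ratios must be >= 0")
  structure(list(molecule = as.character(molecule),
                 replicate = as.character(replicate),
                 times = times, ratios = ratios),
            class = "time_course")
}

#' Detect the phosphorylation period of a time course
#'
#' The phosphorylation period \eqn{\tau_i} is read off the curve as the
#' first time after its global maximum at which the linearly
#' interpolated fold ratio crosses the baseline 1.0 from above. Sub-
#' baseline dips before the maximum are ignored. If the curve never
#' returns to baseline after its maximum -- or never rises above
#' baseline at all -- the period is truncated at the last sample time
#' and flagged.
#'
#' @param tc a [time_course()].
#' @return list with `tau` (minutes) and logical `truncated`.
#' @examples
#' tc <- time_course("x", 1, c(0, 15, 30, 45, 60), c(1, 2, 1.5, 0.9, 1))
#' detect_period(tc)$tau  # 42.5
#' @export
detect_period <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  tt <- tc$times; rr <- tc$ratios
  peak <- which.max(rr)
  if (rr[peak] <= 1 || peak == length(tt)) # flat curve or max at last sample
    return(list(tau = tt[length(tt)], truncated = TRUE))
  for (k in peak:(length(tt) - 1L)) {
    if (rr[k] > 1 && rr[k + 1] <= 1) {
      tau <- tt[k] + (tt[k + 1] - tt[k]) * (rr[k] - 1) / (rr[k] - rr[k + 1])
      return(list(tau = tau, truncated = FALSE))
    }
  }
  list(tau = tt[length(tt)], truncated = TRUE)
}

# piecewise-linear interpolation of the ratio curve at time tau
.interp_ratio <- function(tc, tau) {
  stats::approx(tc$times, tc$ratios, xout = tau, rule = 1)$y
}

#' Mean fold ratio over the phosphorylation period
#'
#' Trapezoidal integral of the fold-ratio curve over \eqn{[0, \tau_i]}
#' (appending the interpolated point at \eqn{\tau_i}), divided by
#' \eqn{\tau_i}. This is the ratio \eqn{\int_0^{\tau_i} \rho_i(t)\,dt /
#' \int_0^{\tau_i} \rho_i\,dt}, the denominator being the baseline
#' (ratio 1) integrated over the same window; stretches below baseline
#' subtract from the excess area.
#'
#' @param tc a [time_course()].
#' @param tau integration endpoint in minutes, within the sampled range.
#' @return the mean fold ratio (dimensionless).
#' @export
integrate_ratio <- function(tc, tau) {
  stopifnot(inherits(tc, "time_course"))
  if (tau <= 0 || tau > tc$times[length(tc$times)])
    stop("integration endpoint outside the sampled range")
  keep <- tc$times < tau
  tt <- c(tc$times[keep], tau)
  rr <- c(tc$ratios[keep], .interp_ratio(tc, tau))
  area <- sum(diff(tt) * (utils::head(rr, -1) + utils::tail(rr, -1)) / 2)
  area / tau
}

#' Estimate the KLD rate of one fold-phosphorylation time course
#'
#' Composes period detection and trapezoidal integration into the
#' divergence-rate estimator
#' \deqn{-\gamma = \frac{1}{\tau_i}\,\log\frac{\int_0^{\tau_i}
#'   a_i(t)\,dt}{\int_0^{\tau_i} a_i\,dt}
#'   = \frac{\log(\mathrm{mean\ fold})}{\tau_i},}
#' with \eqn{\tau_i} converted from minutes to hours so rates are in
#' nats per hour. A mean fold below 1 gives a negative rate, which is
#' reported (flag `below_baseline`) rather than clamped; a period
#' truncated at the last sample is flagged `period_truncated`.
#'
#' @param tc a [time_course()].
#' @return data frame row with `molecule`, `replicate`, `tau_min`,
#'   `mean_fold`, `kld_rate_per_h`, `flags` (semicolon-separated, empty
#'   if none).
#' @examples
#' grid <- c(0, 15, 30, 45, 60, 120, 180)
#' flat <- time_course("nc", 1, grid, rep(1, 7))
#' estimate_rate(flat)$kld_rate_per_h  # exactly 0
#' @export
estimate_rate <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  per <- detect_period(tc)
  mean_fold <- integrate_ratio(tc, per$tau)
  rate <- log(mean_fold) / (per$tau / 60)
  flags <- c(if (per$truncated) "period_truncated",
             if (mean_fold < 1) "below_baseline")
  data.frame(molecule = tc$molecule, replicate = tc$replicate,
             tau_min = per$tau, mean_fold = mean_fold,
             kld_rate_per_h = rate,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Estimate KLD rates for a batch of time courses
#'
#' @param tcs either a list of [time_course()] objects or a long-format
#'   data frame with columns `molecule`, `replicate`, `time_min`,
#'   `ratio` (one row per sample).
#' @return data frame of [estimate_rate()] rows, ordered by
#'   `(molecule, replicate)`. Malformed curves abort with a message
#'   naming every invalid `(molecule, replicate)` pair.
#' @export
batch_estimate <- function(tcs) {
  if (is.data.frame(tcs)) tcs <- as_time_courses(tcs)
  if (!length(tcs)) stop("empty input: no time courses")
  bad <- character(0); rows <- vector("list", length(tcs))
  for (k in seq_along(tcs)) {
    rows[[k]] <- tryCatch(estimate_rate(tcs[[k]]), error = function(e) {
      bad <<- c(bad, paste0(tcs[[k]]$molecule, "/", tcs[[k]]$replicate,
                            " (", conditionMessage(e), ")"))
      NULL
    })
  }
  if (length(bad))
    stop("invalid time courses: ", paste(bad, collapse = "; "))
  out <- do.call(rbind, rows)
  out[order(out$molecule, out$replicate), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Split a long-format table into time-course objects
#'
#' @param df data frame with columns `molecule`, `replicate`,
#'   `time_min`, `ratio`.
#' @return list of [time_course()] objects, one per
#'   `(molecule, replicate)` group. Groups that violate the
#'   time-course invariants are collected and reported in a single
#'   error.
#' @export
as_time_courses <- function(df) {
  need <- c("molecule", "replicate", "time_min", "ratio")
  if (!all(need %in% names(df)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (!nrow(df)) stop("empty input: no time courses")
  key <- interaction(df$molecule, df$replicate, drop = TRUE, sep = "\r")
  groups <- split(df, key)
  bad <- character(0)
  out <- lapply(groups, function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    tryCatch(time_course(g$molecule[1], g$replicate[1], g$time_min,
                         g$ratio),
             error = function(e) {
               bad <<- c(bad, paste0(g$molecule[1], "/", g$replicate[1],
                                     " (", conditionMessage(e), ")"))
               NULL
             })
  })
  if (length(bad))
    stop("invalid time courses: ", paste(bad, collapse = "; "))
  unname(out)
}

#' Read or write fold-phosphorylation time courses as CSV
#'
#' The schema is one row per sample: `molecule,replicate,time_min,ratio`.
#'
#' @param path CSV file path.
#' @return `read_timecourses()` returns the validated long-format data
#'   frame; `write_timecourses()` returns `path` invisibly.
#' @export
read_timecourses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  invisible(as_time_courses(df))          # validation pass
  df
}

#' @rdname read_timecourses
#' @param df long-format time-course data frame.
#' @export
write_timecourses <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
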