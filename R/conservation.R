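#' Per-molecule replicate summary of KLD rates
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of
#' the per-replicate divergence rates of each molecule. With a single
#' replicate the SD is undefined and flagged, not silently zero.
#'
#' @param rates data frame with columns `molecule` and
#'   `kld_rate_per_h` (the output of [batch_estimate()]), or a numeric
#'   vector of rates for one molecule (then `molecule` names it).
#' @param molecule label used when `rates` is a bare numeric vector.
#' @return data frame with columns `molecule`, `n`, `mean`, `sd`,
#'   `sd_defined`.
#' @export
summarize_rates <- function(rates, molecule = "molecule") {
  if (is.numeric(rates))
    rates <- data.frame(molecule = molecule, kld_rate_per_h = rates)
  stopifnot(all(c("molecule", "kld_rate_per_h") %in% names(rates)))
  groups <- split(rates$kld_rate_per_h, rates$molecule)
  out <- data.frame(
    molecule = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(x) if (length(x) >= 2) stats::sd(x)
                else NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out$sd_defined <- !is.na(out$sd)
  out
}

#' Absolute difference of two mean rates
#'
#' @param mean_a,mean_b group means.
#' @param digits rounding used for report display; the unrounded value
#'   is returned in the `full` attribute.
#' @return \eqn{\Delta\mu = |mean_a - mean_b|}, rounded to `digits`.
#' @export
pairwise_delta <- function(mean_a, mean_b, digits = 2) {
  full <- abs(mean_a - mean_b)
  out <- round(full, digits)
  attr(out, "full") <- full
  out
}

#' Cohen's d for two equal-size replicate groups
#'
#' Standardized mean difference with the equal-n pooled standard
#' deviation, \deqn{d = \frac{|\mu_a - \mu_b|}{\sqrt{(s_a^2 +
#' s_b^2)/2}}.} When both SDs are zero, identical means give
#' \eqn{d = 0} and distinct means an infinite effect size (reported as
#' `Inf`); means are compared at the 2-decimal reporting precision in
#' that degenerate case.
#'
#' @param mean_a,sd_a,mean_b,sd_b group means and sample SDs.
#' @return the (non-negative) effect size.
#' @examples
#' cohens_d(3.27, 0.76, 3.43, 0.70)  # ~0.22
#' @export
cohens_d <- function(mean_a, sd_a, mean_b, sd_b) {
  if (anyNA(c(mean_a, sd_a, mean_b, sd_b)))
    stop("undefined inputs: each group needs n >= 2 for a sample SD")
  if (any(c(sd_a, sd_b) < 0)) stop("standard deviations must be >= 0")
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  delta <- abs(mean_a - mean_b)
  if (pooled == 0)
    return(if (round(delta, 2) == 0) 0 else Inf)
  delta / pooled
}

#' Rate-conservation report across cascade pairs
#'
#' Compares the requested molecule pairs: mean difference
#' \eqn{\Delta\mu}, Cohen's d, and a similarity call at `threshold`
#' (default the d <= 0.5 convention). The cascade-wide `conserved` flag
#' is `TRUE` when every requested pair is similar. Display values are
#' rounded to 2 decimals and the similarity call uses the rounded d, so
#' reported and decided values agree; full-precision columns are kept
#' alongside. Pairs are user-supplied; a negative control should not be
#' among them.
#'
#' @param summaries output of [summarize_rates()].
#' @param pairs list of 2-element character vectors, or a 2-column
#'   matrix/data frame of molecule labels.
#' @param threshold similarity threshold on Cohen's d.
#' @return object of class `conservation_report`: list with `pairs` (a
#'   data frame: `molecule_a`, `molecule_b`, `delta_mu`, `cohens_d`,
#'   rounded display columns, `similar`), `conserved` (logical, `NA`
#'   when no pairs were requested), and `threshold`.
#' @export
conservation_report <- function(summaries, pairs, threshold = 0.5) {
  stopifnot(is.data.frame(summaries),
            all(c("molecule", "mean", "sd") %in% names(summaries)))
  if (is.matrix(pairs) || is.data.frame(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i)
      as.character(unlist(pairs[i, 1:2])))
  unknown <- setdiff(unique(unlist(pairs)), summaries$molecule)
  if (length(unknown))
    stop("unknown molecule(s): ", paste(unknown, collapse = ", "))
  rows <- lapply(pairs, function(p) {
    a <- summaries[summaries$molecule == p[1], ]
    b <- summaries[summaries$molecule == p[2], ]
    dm <- pairwise_delta(a$mean, b$mean)
    d <- cohens_d(a$mean, a$sd, b$mean, b$sd)
    data.frame(molecule_a = p[1], molecule_b = p[2],
               delta_mu = attr(dm, "full"), cohens_d = d,
               delta_mu_2dp = as.numeric(dm), cohens_d_2dp = round(d, 2),
               similar = round(d, 2) <= threshold,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_a = character(0), molecule_b = character(0),
               delta_mu = numeric(0), cohens_d = numeric(0),
               delta_mu_2dp = numeric(0), cohens_d_2dp = numeric(0),
               similar = logical(0))
  structure(list(pairs = tab,
                 conserved = if (nrow(tab)) all(tab$similar) else NA,
                 threshold = threshold),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("KLD-rate conservation report (similarity: Cohen's d <=",
      x$threshold, ")\n")
  if (nrow(x$pairs)) {
    print(x$pairs[, c("molecule_a", "molecule_b", "delta_mu_2dp",
                      "cohens_d_2dp", "similar")], ...)
    cat("conserved across all pairs:", x$conserved, "\n")
  } else cat("no pairs requested; conserved flag undefined\n")
  invisible(x)
}

#' Screen all molecule pairs for candidate cascade links
#'
#' Exhaustive pairwise comparison: every unordered pair with Cohen's
#' d at or below the threshold is returned, sorted by increasing d.
#' Similar divergence rates are a *hypothesis-generating* signal that
#' two molecules may sit in one cascade; no biological claim is made
#' and no multiplicity control is applied.
#'
#' @inheritParams conservation_report
#' @return data frame of qualifying pairs (columns as in
#'   [conservation_report()]), with attribute
#'   `"exploratory"` set to `TRUE`.
#' @export
candidate_cascade_screen <- function(summaries, threshold = 0.5) {
  stopifnot(is.data.frame(summaries))
  mols <- summaries$molecule
  if (length(mols) < 2) stop("screening needs at least 2 molecules")
  idx <- utils::combn(mols, 2, simplify = FALSE)
  rep <- conservation_report(summaries, idx, threshold)
  out <- rep$pairs[rep$pairs$similar, , drop = FALSE]
  out <- out[order(out$cohens_d), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exploratory") <- TRUE
  out
}

#' Reference replicate statistics of the motivating MAPK experiment
#'
#' Published per-molecule replicate summaries (mean and sample SD of
#' the KLD rate, n = 4 antibody-array replicates) from the
#' EGF-stimulated A431 experiment on the stress-MAPK cascade that
#' motivates this package, including its flat negative control. The
#' four published cascade comparisons are returned by
#' [mapk_reference_pairs()]. Units of the published rates are not
#' stated with the data; only unit-free comparisons (mean differences
#' in the published unit, Cohen's d) should be built on them.
#'
#' @return `mapk_reference_summary()`: data frame with columns
#'   `molecule`, `n`, `mean`, `sd`; `mapk_reference_pairs()`: 2-column
#'   data frame of compared molecule labels.
#' @export
mapk_reference_summary <- function() {
  data.frame(
    molecule = c("ASK1", "MKK4", "p38", "MKK3", "ATF2",
                 "Negative control"),
    n = 4L,
    mean = c(3.27, 3.43, 3.07, 3.19, 3.03, 0.00),
    sd = c(0.76, 0.70, 0.73, 0.20, 0.50, 0.00),
    stringsAsFactors = FALSE)
}

#' @rdname mapk_reference_summary
#' @export
mapk_reference_pairs <- function() {
  data.frame(molecule_a = c("ASK1", "MKK4", "MKK3", "p38"),
             molecule_b = c("MKK4", "p38", "p38", "ATF2"),
             stringsAsFactors = FALSE)
}
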