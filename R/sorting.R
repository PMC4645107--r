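# Fluence-proxy sorting of SFX pattern metadata: the on-crystal fluence of a
# snapshot is not measured directly, but the number of Bragg peaks, their
# average integrated intensity, and the upstream pulse-energy monitor are all
# positively correlated with it. Patterns are scored by the mean of the
# empirical percentile ranks of the three proxies and the top-scoring
# fraction is selected ("best" subset).

.PATTERN_FIELDS <- c("id", "pulse_energy_reading", "n_peaks", "mean_peak_intensity",
                     "max_resolution")

.check_patterns <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    .stopf("records must be a nonempty data.frame")
  }
  missing_cols <- setdiff(.PATTERN_FIELDS, names(records))
  if (length(missing_cols)) {
    .stopf("pattern records lack columns: %s", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.PATTERN_FIELDS, "id")) {
    bad <- which(!is.finite(records[[col]]))
    if (length(bad)) {
      .stopf("record '%s': field %s is missing or non-finite", records$id[bad[1]], col)
    }
  }
  if (any(records$n_peaks < 0)) .stopf("n_peaks must be >= 0")
  if (any(records$max_resolution <= 0)) .stopf("max_resolution must be > 0")
  if (any(records$mean_peak_intensity < 0)) .stopf("mean_peak_intensity must be >= 0")
  if (anyDuplicated(records$id)) .stopf("pattern ids must be unique")
  invisible(records)
}

#' Score diffraction patterns by fluence proxies
#'
#' For each of `n_peaks`, `mean_peak_intensity` and `pulse_energy_reading`,
#' the empirical percentile rank (midranks for ties, scaled to `(0, 1]`) is
#' computed; a pattern's score is the mean of the three. Scores are invariant
#' under any monotone rescaling of a single proxy and under record
#' permutation.
#'
#' @param records data.frame with columns `id`, `pulse_energy_reading`,
#'   `n_peaks`, `mean_peak_intensity`, `max_resolution` (see
#'   [generate_stream()]).
#' @return Named numeric vector of scores in `(0, 1]`, one per record.
#' @export
score_patterns <- function(records) {
  .check_patterns(records)
  n <- nrow(records)
  pr <- function(x) rank(x, ties.method = "average") / n
  score <- (pr(records$n_peaks) + pr(records$mean_peak_intensity) +
              pr(records$pulse_energy_reading)) / 3
  stats::setNames(score, records$id)
}

#' Select the highest-scoring fraction of patterns
#'
#' Deterministic: patterns are ordered by decreasing score with ties broken
#' by `id`, and the top `max(1, floor(n * fraction))` are kept. Selection is
#' monotone in `fraction`.
#'
#' @param records Pattern records (see [score_patterns()]).
#' @param fraction Fraction to retain, in (0, 1].
#' @return Object of class `selection_result`: `selected` (ids), `scores`,
#'   `fraction`, `score_definition`, and per-variable minima over the
#'   selected set (`thresholds`).
#' @export
select_best <- function(records, fraction = 0.33) {
  .check_patterns(records)
  if (!.is_number(fraction) || fraction <= 0 || fraction > 1) {
    .stopf("fraction must be in (0, 1]")
  }
  k <- max(1L, floor(nrow(records) * fraction))
  score <- score_patterns(records)
  ord <- order(-score, records$id)
  sel <- ord[seq_len(k)]
  thresholds <- vapply(c("n_peaks", "mean_peak_intensity", "pulse_energy_reading"),
                       function(col) min(records[[col]][sel]), numeric(1))
  structure(list(selected = records$id[sel], scores = score, fraction = fraction,
                 score_definition = "mean of percentile midranks of (n_peaks, mean_peak_intensity, pulse_energy_reading)",
                 thresholds = thresholds, n_input = nrow(records)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d / %d patterns (fraction %.3g)\n",
              length(x$selected), x$n_input, x$fraction))
  cat("  score:", x$score_definition, "\n")
  invisible(x)
}

#' Binned summaries of a pattern stream
#'
#' Tabular stand-ins for the usual diagnostic plots: a 2-D histogram of mean
#' peak intensity against pulse energy, a 2-D histogram of peak count
#' against best resolution, the marginal histograms of all four variables,
#' and the median peak count per resolution bin.
#'
#' @param records Pattern records.
#' @param n_bins Bins per axis.
#' @return List of tables/data.frames, class `stream_summary`.
#' @export
stream_summaries <- function(records, n_bins = 20) {
  .check_patterns(records)
  cutter <- function(x) cut(x, breaks = n_bins, include.lowest = TRUE)
  intensity_vs_energy <- table(intensity = cutter(records$mean_peak_intensity),
                               pulse_energy = cutter(records$pulse_energy_reading))
  res_bins <- cutter(records$max_resolution)
  peaks_vs_resolution <- table(n_peaks = cutter(records$n_peaks),
                               resolution = res_bins)
  marginals <- lapply(setdiff(.PATTERN_FIELDS, "id"), function(col) {
    tab <- table(cutter(records[[col]]))
    data.frame(bin = names(tab), count = as.integer(tab))
  })
  names(marginals) <- setdiff(.PATTERN_FIELDS, "id")
  med_peaks <- tapply(records$n_peaks, res_bins, median)
  structure(list(intensity_vs_energy = intensity_vs_energy,
                 peaks_vs_resolution = peaks_vs_resolution,
                 marginals = marginals,
                 median_peaks_by_resolution = data.frame(
                   resolution_bin = names(med_peaks),
                   median_n_peaks = as.numeric(med_peaks))),
            class = "stream_summary")
}
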