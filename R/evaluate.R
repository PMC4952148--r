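#' Paired reference/estimate series
#'
#' Aligned reference (e.g. invasive co-oximetry, iSvO2) and estimate
#' (noninvasive, nSvO2) saturation values in percent.
#'
#' @param reference Reference values (length >= 2).
#' @param estimate Estimated values, same length.
#' @param labels Optional level/repeat identifiers.
#' @return A `paired_series` object.
#' @export
paired_series <- function(reference, estimate, labels = NULL) {
  if (length(reference) != length(estimate)) {
    stop_invalid_input("reference and estimate must have equal lengths")
  }
  if (length(reference) < 2L) {
    stop_invalid_input("paired series need at least 2 pairs")
  }
  if (!is.null(labels) && length(labels) != length(reference)) {
    stop_invalid_input("labels must match the series length")
  }
  structure(list(reference = as.numeric(reference),
                 estimate = as.numeric(estimate), labels = labels),
            class = "paired_series")
}

as_pairs <- function(pairs, estimate = NULL, min_n = 1L) {
  if (inherits(pairs, "paired_series")) {
    ref <- pairs$reference; est <- pairs$estimate
  } else {
    ref <- as.numeric(pairs); est <- as.numeric(estimate)
    if (is.null(estimate) || length(ref) != length(est)) {
      stop_invalid_input("supply a paired_series or two equal-length vectors")
    }
  }
  if (length(ref) < min_n) {
    stop_insufficient_data(sprintf("need at least %d pairs", min_n))
  }
  list(reference = ref, estimate = est)
}

#' Root mean square error of paired measurements
#'
#' `sqrt(mean((estimate - reference)^2))`.
#'
#' @param pairs A [paired_series()], or a reference vector.
#' @param estimate Estimate vector when `pairs` is a vector.
#' @return The RMSE.
#' @export
rmse <- function(pairs, estimate = NULL) {
  p <- as_pairs(pairs, estimate, min_n = 1L)
  sqrt(mean((p$estimate - p$reference)^2))
}

#' Pearson correlation of paired measurements
#'
#' Standard product-moment correlation between the two series. Constant
#' series have no defined correlation and raise a classed error.
#'
#' @inheritParams rmse
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(pairs, estimate = NULL) {
  p <- as_pairs(pairs, estimate, min_n = 2L)
  if (stats::sd(p$reference) == 0 || stats::sd(p$estimate) == 0) {
    stop_venoxim("correlation is undefined for a constant series",
                 "venoxim_undefined_correlation")
  }
  stats::cor(p$reference, p$estimate)
}

#' Difference (agreement) analysis of paired measurements
#'
#' Per-pair differences `estimate - reference` with band-membership flags
#' and a Bland-Altman-style summary. All points are retained; no outlier
#' exclusion of any kind.
#'
#' @inheritParams rmse
#' @param band Agreement half-band in the same units (default 10, i.e. the
#'   band from -10 to +10).
#' @return A list with `differences` (data.frame: `reference`, `estimate`,
#'   `mean` of the pair, `difference`, `within_band`) and `summary`
#'   (`mean_difference`, `sd_difference`, `loa_lower`/`loa_upper`
#'   (mean +/- 1.96 sd), `fraction_within`, `band`, `n`).
#' @export
difference_analysis <- function(pairs, estimate = NULL, band = 10) {
  p <- as_pairs(pairs, estimate, min_n = 1L)
  d <- p$estimate - p$reference
  within <- abs(d) <= band
  sdd <- if (length(d) > 1L) stats::sd(d) else 0
  list(differences = data.frame(reference = p$reference,
                                estimate = p$estimate,
                                mean = (p$reference + p$estimate) / 2,
                                difference = d,
                                within_band = within),
       summary = list(mean_difference = mean(d),
                      sd_difference = sdd,
                      loa_lower = mean(d) - 1.96 * sdd,
                      loa_upper = mean(d) + 1.96 * sdd,
                      fraction_within = mean(within),
                      band = band, n = length(d)))
}

#' Compare noninvasive and reference oxygen consumption
#'
#' Oxygen consumption is the arteriovenous difference SaO2 - SvO2. The
#' noninvasive side comes from an `oximetry_result` (SpO2 standing in for
#' SaO2); the reference side from aligned reference saturations.
#'
#' @param noninvasive An `oximetry_result` from [run_pipeline()], or a
#'   data.frame with columns `spo2` and `svo2`.
#' @param reference A data.frame with columns `sao2` and `svo2`, aligned
#'   row-for-row with the noninvasive windows.
#' @return A list with `table` (per-window consumptions and their
#'   difference) and `summary` (`rmse`, `mean_difference`, `n`).
#' @export
consumption_comparison <- function(noninvasive, reference) {
  if (!all(c("spo2", "svo2") %in% names(noninvasive))) {
    stop_invalid_input("noninvasive input needs columns spo2 and svo2")
  }
  if (!all(c("sao2", "svo2") %in% names(reference))) {
    stop_invalid_input("reference input needs columns sao2 and svo2")
  }
  if (nrow(noninvasive) != nrow(reference)) {
    stop_venoxim("noninvasive and reference tables are not aligned",
                 "venoxim_alignment_error")
  }
  est <- noninvasive$spo2 - noninvasive$svo2
  ref <- reference$sao2 - reference$svo2
  tab <- data.frame(window = seq_len(nrow(noninvasive)),
                    consumption_est = est,
                    consumption_ref = ref,
                    difference = est - ref)
  keep <- stats::complete.cases(tab)
  list(table = tab,
       summary = list(rmse = sqrt(mean(tab$difference[keep]^2)),
                      mean_difference = mean(tab$difference[keep]),
                      n = sum(keep)))
}
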