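#' Summarize a control cohort's false-positive MAFs
#'
#' Median, quartiles (weighted-average quantile convention, R type 7)
#' and maximum of the MAFs observed in known-negative samples.
#'
#' @param control_mafs Numeric vector of control MAFs, percent.
#' @return List: `median`, `q25`, `q75`, `max`, `n`.
#' @export
summarize_controls <- function(control_mafs) {
  if (length(control_mafs) == 0 || any(is.na(control_mafs))) {
    stop("control MAFs must be non-empty and complete")
  }
  q <- quantile(control_mafs, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q25 = q[1], q75 = q[3],
       max = max(control_mafs), n = length(control_mafs))
}

#' Determine the false-positive MAF cutoff at full specificity
#'
#' ROC-style cutoff at the maximal-sensitivity operating point
#' constrained to 100 percent specificity on the controls: the
#' threshold is the midpoint between the largest control MAF and the
#' smallest case MAF exceeding it. When no case exceeds the control
#' maximum (or no cases are supplied), the cutoff falls back to
#' `control_max + delta`.
#'
#' @param control_mafs MAFs of known-negative samples, percent.
#' @param case_mafs Optional case MAFs, percent.
#' @param delta Fallback offset above the control maximum, percentage
#'   points (default 0.05).
#' @return A list of class `calibration_result`: control summary,
#'   `cutoff`, `achieved_specificity` (1 by construction),
#'   `achieved_sensitivity` (fraction of cases above the cutoff, NA
#'   without cases), `delta`, `n_controls`, `n_cases`.
#' @export
determine_cutoff <- function(control_mafs, case_mafs = NULL, delta = 0.05) {
  s <- summarize_controls(control_mafs)
  above <- case_mafs[case_mafs > s$max]
  cutoff <- if (length(above) > 0) (s$max + min(above)) / 2
            else s$max + delta
  structure(list(
    control_median = s$median, control_iqr = c(s$q25, s$q75),
    control_max = s$max, cutoff = cutoff,
    achieved_specificity = mean(control_mafs < cutoff),
    achieved_sensitivity = if (length(case_mafs)) mean(case_mafs > cutoff)
                           else NA_real_,
    delta = delta, n_controls = s$n, n_cases = length(case_mafs)),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n",
      sprintf("  controls (n=%d): median %.3f [%.3f-%.3f] %%, max %.3f %%\n",
              x$n_controls, x$control_median,
              x$control_iqr[1], x$control_iqr[2], x$control_max),
      sprintf("  cutoff %.3f %% (specificity %.3f", x$cutoff,
              x$achieved_specificity),
      if (!is.na(x$achieved_sensitivity))
        sprintf(", sensitivity %.3f", x$achieved_sensitivity) else "",
      ")\n", sep = "")
  invisible(x)
}

#' Subtract the cutoff from raw MAFs and call samples
#'
#' The calibrated cutoff is subtracted from each sample's raw MAF
#' (clipped at zero); a sample is called mutation-positive when the
#' corrected MAF is positive.
#'
#' @param results A `sample_result` data.frame (from
#'   [quantify_well()]), or any data.frame with a `raw_maf` column;
#'   alternatively a bare numeric vector of raw MAFs.
#' @param cutoff Cutoff in percent.
#' @return Same shape as `results`, with `corrected_maf` and `call`
#'   filled in (for a numeric input, a data.frame with the three
#'   columns).
#' @export
apply_cutoff <- function(results, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff >= 0)
  if (is.numeric(results)) {
    results <- data.frame(raw_maf = results)
  }
  stopifnot("raw_maf" %in% names(results))
  results$corrected_maf <- pmax(0, results$raw_maf - cutoff)
  results$call <- results$corrected_maf > 0
  results
}

#' Replicate variability as SD percent of the mean
#'
#' @param replicate_mafs >= 2 replicate MAF measurements of one
#'   sample, percent, with positive mean.
#' @return `100 * sd / mean` (sample SD, n-1 denominator).
#' @export
replicate_cv <- function(replicate_mafs) {
  if (length(replicate_mafs) < 2) {
    stop("replicate CV needs >= 2 replicates")
  }
  m <- mean(replicate_mafs)
  if (m <= 0) stop("replicate CV undefined for non-positive mean MAF")
  100 * sd(replicate_mafs) / m
}

#' Compare replicate variability between two groups
#'
#' Two-sided Mann–Whitney U comparison of per-sample replicate CVs,
#' typically false-positive (control) versus true-mutation (case)
#' wells: purely stochastic false-positive signal varies relatively
#' more across replicates than a genuine mutant template population.
#'
#' @param control_cvs,case_cvs Per-sample CVs (percent of mean).
#' @return A `stat_result` (see [mann_whitney()]) with group
#'   median/IQR summaries attached.
#' @export
compare_replicate_variability <- function(control_cvs, case_cvs) {
  if (!length(control_cvs) || !length(case_cvs)) {
    stop("both CV groups must be non-empty")
  }
  res <- mann_whitney(control_cvs, case_cvs)
  res$effect <- list(
    control = quantile(control_cvs, c(0.25, 0.5, 0.75), names = FALSE),
    case = quantile(case_cvs, c(0.25, 0.5, 0.75), names = FALSE))
  res
}
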