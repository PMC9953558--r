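new_stat_result <- function(name, statistic, p_value, effect = NULL,
                            n = NULL, note = NULL) {
  structure(list(name = name, statistic = statistic, p_value = p_value,
                 effect = effect, n = n, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$name, ": statistic = ",
      format(x$statistic), ", p = ", format(x$p_value), "\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Tie-aware ROC curve and AUC
#'
#' `AUC = [#(case > control) + 0.5 * #(case = control)] /
#' (n_case * n_control)` — the Mann–Whitney U normalization, computed
#' via average ranks. ROC points are returned at every distinct score
#' (rule: positive iff score >= threshold).
#'
#' @param case_scores,control_scores Numeric score vectors (higher =
#'   more case-like); here, corrected MAFs.
#' @return List of class `roc_result`: `auc`, `points` (data.frame
#'   `threshold`, `sensitivity`, `specificity`), `n_cases`,
#'   `n_controls`.
#' @export
roc_auc <- function(case_scores, control_scores) {
  n1 <- length(case_scores); n0 <- length(control_scores)
  if (n1 == 0 || n0 == 0) stop("both score vectors must be non-empty")
  r <- rank(c(case_scores, control_scores))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  thresholds <- sort(unique(c(case_scores, control_scores)),
                     decreasing = TRUE)
  points <- data.frame(
    threshold = c(Inf, thresholds),
    sensitivity = vapply(c(Inf, thresholds),
                         function(t) mean(case_scores >= t), numeric(1)),
    specificity = vapply(c(Inf, thresholds),
                         function(t) mean(control_scores < t), numeric(1)))
  structure(list(auc = u / (n1 * n0), u = u, points = points,
                 n_cases = n1, n_controls = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d cases vs %d controls)\n",
              x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' Sensitivity and specificity of binary calls
#'
#' @param calls Logical vector of positive calls.
#' @param is_case Logical vector: TRUE for cases, FALSE for controls.
#' @return List: `sensitivity`, `specificity` (percent), `n_cases`,
#'   `n_controls`, `n_detected`.
#' @export
sensitivity_specificity <- function(calls, is_case) {
  stopifnot(length(calls) == length(is_case),
            is.logical(calls), is.logical(is_case))
  if (!any(is_case) || all(is_case)) {
    stop("need at least one case and one control")
  }
  list(sensitivity = 100 * mean(calls[is_case]),
       specificity = 100 * mean(!calls[!is_case]),
       n_cases = sum(is_case), n_controls = sum(!is_case),
       n_detected = sum(calls & is_case))
}

#' Combine per-marker calls into a panel call
#'
#' Panel positivity is the logical OR across markers; the
#' intersection (samples positive for every marker) is reported for
#' overlap analyses.
#'
#' @param calls Logical matrix or data.frame, rows = samples,
#'   columns = markers (row order defines the sample set; all markers
#'   must cover the same samples, i.e. no NAs).
#' @return List: `combined` (logical vector), `n_union`,
#'   `n_intersection`, `per_marker` (named positive counts).
#' @export
combine_panel <- function(calls) {
  calls <- as.matrix(calls)
  if (any(is.na(calls))) {
    stop("mismatched sample sets: every marker must call every sample")
  }
  mode(calls) <- "logical"
  list(combined = apply(calls, 1, any),
       n_union = sum(apply(calls, 1, any)),
       n_intersection = sum(apply(calls, 1, all)),
       per_marker = colSums(calls))
}

#' Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped and ties get average ranks; the
#' p-value is exact for <= 25 informative (non-zero, untied) pairs
#' and otherwise uses the tie-corrected normal approximation. All
#' pairs equal is a degenerate case and is flagged rather than tested.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A `stat_result` (statistic = V, the positive-rank sum).
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(new_stat_result("Wilcoxon signed-rank", NA_real_, NA_real_,
                           n = length(x),
                           note = "degenerate: all paired differences zero"))
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact,
                                     correct = !exact))
  new_stat_result("Wilcoxon signed-rank", unname(ht$statistic), ht$p.value,
                  effect = list(x = quantile(x, c(.25, .5, .75), names = FALSE),
                                y = quantile(y, c(.25, .5, .75), names = FALSE)),
                  n = length(x))
}

#' Mann–Whitney U test for unpaired data
#'
#' U is tie-aware (half credit for ties, so `U = AUC * n1 * n2`);
#' the p-value is exact for small untied samples (min group size
#' <= 8) and tie-corrected normal otherwise. Completely tied data
#' yield p = 1.
#'
#' @param x,y Numeric vectors.
#' @return A `stat_result` (statistic = U of `x` versus `y`).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(new_stat_result("Mann-Whitney U", u, 1,
                           n = c(length(x), length(y)),
                           note = "all observations tied"))
  }
  exact <- min(length(x), length(y)) <= 8 && !any(duplicated(c(x, y)))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  new_stat_result("Mann-Whitney U", u, ht$p.value,
                  effect = list(x = quantile(x, c(.25, .5, .75), names = FALSE),
                                y = quantile(y, c(.25, .5, .75), names = FALSE)),
                  n = c(length(x), length(y)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, p-value by the
#' t-approximation (ties allowed).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `stat_result` (statistic = r_s).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("spearman needs two equal-length vectors of length >= 3")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("correlation undefined for a constant vector")
  }
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  new_stat_result("Spearman rank correlation", unname(ht$estimate),
                  ht$p.value, n = length(x))
}

#' Fisher's exact test on a 2x2 table
#'
#' @param table A 2x2 matrix of non-negative counts with positive
#'   margins.
#' @return A `stat_result` (statistic = odds ratio estimate).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("fisher_exact requires positive margins")
  }
  ht <- fisher.test(table)
  new_stat_result("Fisher exact", unname(ht$estimate), ht$p.value,
                  n = sum(table))
}

#' Coefficient of determination of a spike-in linearity experiment
#'
#' R-squared of the ordinary least-squares fit of observed on
#' expected MAF; linearity, not identity, is assessed.
#'
#' @param expected,observed MAFs, percent, length >= 3.
#' @return R-squared in [0, 1].
#' @export
linearity_r2 <- function(expected, observed) {
  if (length(expected) != length(observed) || length(expected) < 3) {
    stop("linearity needs >= 3 paired points")
  }
  if (length(unique(expected)) == 1L) {
    stop("expected MAFs must vary")
  }
  fit <- lm(observed ~ expected)
  # R2 from the fit's residuals directly; summary.lm warns on an
  # exact fit, which is a legitimate input here
  1 - sum(residuals(fit)^2) / sum((observed - mean(observed))^2)
}

#' Cohort-level diagnostic evaluation
#'
#' Assembles the full diagnostic report from calibrated per-sample
#' results: per-marker sensitivity/specificity/AUC (scores are
#' corrected MAFs, so calibrated controls sit at exactly zero),
#' the OR-combined panel (scored as the per-sample maximum corrected
#' MAF), marker overlap counts, and the paired MAF comparison on
#' dual-positive samples.
#'
#' @param results Data.frame with columns `sample_id`, `group`,
#'   `assay`, `corrected_maf`, `call` (long format, one row per
#'   sample x marker, as produced by [quantify_well()] +
#'   [apply_cutoff()]).
#' @param case_group Group label identifying cases (default "UBC");
#'   all other groups are controls.
#' @return A list of class `diagnostic_report`: `markers` (data.frame
#'   with n_cases, n_controls, n_detected, sensitivity, specificity,
#'   auc), `combined` (same fields), `overlap` (both/either/neither
#'   counts among cases), `paired_maf` (a `stat_result` or NULL).
#' @export
evaluate_cohort <- function(results, case_group = "UBC") {
  needed <- c("sample_id", "group", "assay", "corrected_maf", "call")
  stopifnot(all(needed %in% names(results)))
  if (any(is.na(results$corrected_maf))) {
    stop("results must be calibrated (corrected_maf filled) first")
  }
  markers <- unique(results$assay)
  samples <- unique(results[, c("sample_id", "group")])
  is_case <- samples$group == case_group

  score <- function(marker) {
    m <- results[results$assay == marker, ]
    m$corrected_maf[match(samples$sample_id, m$sample_id)]
  }
  scores <- vapply(markers, score, numeric(nrow(samples)))  # samples x markers
  calls_mat <- scores > 0

  marker_row <- function(sc, calls) {
    ss <- sensitivity_specificity(calls, is_case)
    roc <- roc_auc(sc[is_case], sc[!is_case])
    data.frame(n_cases = ss$n_cases, n_controls = ss$n_controls,
               n_detected = ss$n_detected,
               sensitivity = ss$sensitivity, specificity = ss$specificity,
               auc = roc$auc)
  }
  per_marker <- do.call(rbind, lapply(markers, function(mk)
    cbind(marker = mk, marker_row(scores[, mk], calls_mat[, mk]))))

  panel <- combine_panel(calls_mat)
  combined_score <- apply(scores, 1, max)
  combined <- cbind(marker = "combined",
                    marker_row(combined_score, panel$combined))

  case_calls <- calls_mat[is_case, , drop = FALSE]
  overlap <- list(all_markers = sum(apply(case_calls, 1, all)),
                  any_marker = sum(apply(case_calls, 1, any)),
                  none = sum(!apply(case_calls, 1, any)))

  paired <- NULL
  if (length(markers) == 2) {
    dual <- is_case & apply(calls_mat, 1, all)
    if (sum(dual) >= 2) {
      paired <- paired_wilcoxon(scores[dual, 1], scores[dual, 2])
    }
  }
  structure(list(markers = per_marker, combined = combined,
                 overlap = overlap, paired_maf = paired,
                 case_group = case_group),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("<diagnostic_report> cases = ", x$case_group, "\n", sep = "")
  print(rbind(x$markers, x$combined), row.names = FALSE, digits = 3)
  cat(sprintf("  case overlap: all markers %d, any %d, none %d\n",
              x$overlap$all_markers, x$overlap$any_marker, x$overlap$none))
  if (!is.null(x$paired_maf)) {
    cat(sprintf("  paired MAF (dual-positive): V = %s, p = %.3f\n",
                format(x$paired_maf$statistic), x$paired_maf$p_value))
  }
  invisible(x)
}
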