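#' Automatic per-channel positivity threshold
#'
#' Robust quadrant threshold placed `k` spreads above the centre of
#' the negative (lower) mode. The lower mode is located in two
#' stages: the lower half of the amplitudes gives a provisional
#' centre and spread (median/MAD) that are guaranteed to sit inside
#' the negative cluster even when most droplets are positive; the
#' droplets within ten provisional spreads of that centre are then
#' taken as the negative cluster, whose median and MAD set the final
#' threshold. The default `k = 6` is conservative against rain for
#' this assay geometry.
#'
#' @param amplitudes Numeric vector of one channel's amplitudes
#'   (>= 100 droplets).
#' @param k Number of lower-mode spreads above the centre (default 6).
#' @return Threshold value.
#' @export
auto_threshold <- function(amplitudes, k = 6) {
  if (length(amplitudes) < 100) {
    stop("auto thresholding needs >= 100 droplets")
  }
  lower <- amplitudes[amplitudes <= median(amplitudes)]
  c0 <- median(lower)
  s0 <- mad(lower)
  if (s0 == 0) {
    stop("degenerate amplitude distribution: zero spread in lower mode")
  }
  neg <- amplitudes[amplitudes < c0 + 10 * s0]
  centre <- median(neg)
  spread <- mad(neg)
  if (spread == 0) {
    stop("degenerate amplitude distribution: zero spread in lower mode")
  }
  centre + k * spread
}

#' Classify droplets into the four duplex quadrants
#'
#' A droplet is positive on a channel iff its amplitude exceeds that
#' channel's threshold; the pair of positivities yields the label:
#' `empty`, `wt_only` (HEX only), `mut_only` (FAM only) or `double`.
#'
#' @param droplets A `droplet_set` (or any list with an `amplitudes`
#'   data.frame holding `fam` and `hex` columns).
#' @param thresholds `"auto"` (default) or a named numeric vector
#'   `c(fam = ..., hex = ...)`.
#' @param k Auto-threshold multiplier, see [auto_threshold()].
#' @return A list of class `droplet_classification`: `labels`
#'   (factor), `counts` (named integer), `thresholds`.
#' @export
classify_droplets <- function(droplets, thresholds = "auto", k = 6) {
  amp <- droplets$amplitudes
  stopifnot(is.data.frame(amp), all(c("fam", "hex") %in% names(amp)))
  if (identical(thresholds, "auto")) {
    thresholds <- c(fam = auto_threshold(amp$fam, k),
                    hex = auto_threshold(amp$hex, k))
  }
  stopifnot(all(c("fam", "hex") %in% names(thresholds)))
  fam_pos <- amp$fam > thresholds[["fam"]]
  hex_pos <- amp$hex > thresholds[["hex"]]
  labels <- factor(
    ifelse(fam_pos & hex_pos, "double",
           ifelse(fam_pos, "mut_only",
                  ifelse(hex_pos, "wt_only", "empty"))),
    levels = c("empty", "wt_only", "mut_only", "double"))
  structure(list(labels = labels,
                 counts = c(table(labels)),
                 thresholds = thresholds),
            class = "droplet_classification")
}

#' Poisson inversion of a droplet positive count to a concentration
#'
#' With `p = n_positive / n_total` the mean occupancy is
#' `lambda = -ln(1 - p)` copies per droplet, and the concentration in
#' copies per microliter of reaction is `lambda / droplet volume
#' (uL)`. The 95 percent interval propagates the binomial standard
#' error of `p` through the log transform (delta method), which is
#' adequate at the ~20000-droplet scale.
#'
#' @param n_positive,n_total Positive and total droplet counts.
#' @param droplet_volume_nl Droplet volume, nL (default 0.85).
#' @return A list of class `concentration_estimate`: `lambda`,
#'   `concentration` (copies/uL), `ci_low`, `ci_high`, `n_positive`,
#'   `n_total`.
#' @export
poisson_concentration <- function(n_positive, n_total,
                                  droplet_volume_nl = 0.85) {
  stopifnot(n_total > 0, n_positive >= 0, n_positive <= n_total,
            droplet_volume_nl > 0)
  if (n_positive == n_total) {
    stop("saturated well: every droplet positive, lambda is unbounded")
  }
  p <- n_positive / n_total
  lambda <- -log(1 - p)
  vol_ul <- droplet_volume_nl * 1e-3
  se_lambda <- sqrt(p / ((1 - p) * n_total))
  z <- qnorm(0.975)
  structure(list(
    lambda = lambda,
    concentration = lambda / vol_ul,
    ci_low = max(0, lambda - z * se_lambda) / vol_ul,
    ci_high = (lambda + z * se_lambda) / vol_ul,
    n_positive = as.integer(n_positive), n_total = as.integer(n_total)),
    class = "concentration_estimate")
}

#' Mutant allele fraction from channel concentrations
#'
#' `MAF = 100 * C_mut / (C_wt + C_mut)` percent, where the `C` are
#' concentrations in copies per microliter of reaction.
#'
#' @param c_wt,c_mut Wild-type / mutant concentrations (copies/uL).
#' @return MAF in percent, in [0, 100].
#' @export
compute_maf <- function(c_wt, c_mut) {
  stopifnot(c_wt >= 0, c_mut >= 0)
  if (c_wt + c_mut == 0) {
    stop("undefined MAF: no template detected on either channel")
  }
  100 * c_mut / (c_wt + c_mut)
}

#' Quantify one well to wild-type/mutant concentrations and raw MAF
#'
#' Standard duplex bookkeeping: double-positive droplets count toward
#' both channels' positive totals (wild-type positives = wt_only +
#' double, mutant positives = mut_only + double). A screening assay
#' cannot attribute FAM positives to a specific mutant genotype, so a
#' single pooled mutant concentration is reported.
#'
#' @param droplets A `droplet_set`.
#' @param assay Assay name (character) or an `assay_definition`; only
#'   used to label the result.
#' @param thresholds Passed to [classify_droplets()].
#' @param droplet_volume_nl Droplet volume, nL.
#' @param group Optional group label carried into the result.
#' @param k Auto-threshold multiplier.
#' @return A one-row data.frame (`sample_result`): sample_id, group,
#'   assay, n_droplets, n_wt_pos, n_mut_pos, c_wt, c_mut, raw_maf;
#'   corrected_maf and call are NA until calibration.
#' @export
quantify_well <- function(droplets, assay = "assay", thresholds = "auto",
                          droplet_volume_nl = 0.85, group = NA_character_,
                          k = 6) {
  assay_name <- if (inherits(assay, "assay_definition")) assay$name
                else as.character(assay)
  cl <- classify_droplets(droplets, thresholds, k = k)
  n <- length(cl$labels)
  n_wt <- cl$counts[["wt_only"]] + cl$counts[["double"]]
  n_mut <- cl$counts[["mut_only"]] + cl$counts[["double"]]
  c_wt <- if (n_wt > 0)
    poisson_concentration(n_wt, n, droplet_volume_nl)$concentration else 0
  c_mut <- if (n_mut > 0)
    poisson_concentration(n_mut, n, droplet_volume_nl)$concentration else 0
  data.frame(
    sample_id = droplets$sample_id %||% NA_character_,
    group = group, assay = assay_name,
    n_droplets = n, n_wt_pos = n_wt, n_mut_pos = n_mut,
    c_wt = c_wt, c_mut = c_mut,
    raw_maf = compute_maf(c_wt, c_mut),
    corrected_maf = NA_real_, call = NA,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
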