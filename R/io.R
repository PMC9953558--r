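# Polynomial rolling hash of a serialized object; used to stamp
# outputs so a report can be traced to the configuration that
# produced it (provenance only, not cryptographic)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 1000000007
  sprintf("%08x", h)
}

#' Write / read a droplet amplitude table as CSV
#'
#' One row per droplet with columns `sample_id`, `well_id`,
#' `fam_amplitude`, `hex_amplitude` (QuantaSoft-export style; column
#' names are configurable on read for instrument exports).
#'
#' @param droplets A `droplet_set`.
#' @param path CSV file path.
#' @param fam_col,hex_col Amplitude column names on read.
#' @return `read_droplet_csv()` returns a `droplet_set` (no truth);
#'   the writer returns `path` invisibly.
#' @export
write_droplet_csv <- function(droplets, path) {
  df <- data.frame(sample_id = droplets$sample_id,
                   well_id = droplets$well_id,
                   fam_amplitude = droplets$amplitudes$fam,
                   hex_amplitude = droplets$amplitudes$hex)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_droplet_csv
#' @export
read_droplet_csv <- function(path, fam_col = "fam_amplitude",
                             hex_col = "hex_amplitude") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c(fam_col, hex_col) %in% names(df)))
  structure(
    list(amplitudes = data.frame(fam = df[[fam_col]], hex = df[[hex_col]]),
         truth = NULL,
         sample_id = if ("sample_id" %in% names(df)) df$sample_id[1]
                     else NA_character_,
         well_id = if ("well_id" %in% names(df)) df$well_id[1]
                   else NA_character_,
         n_droplets = nrow(df)),
    class = "droplet_set")
}

#' Write / read per-sample quantification results as CSV
#'
#' @param results `sample_result` data.frame (rows from
#'   [quantify_well()], possibly after [apply_cutoff()]).
#' @param path CSV path.
#' @return The reader returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
write_results_csv <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a calibration result as JSON
#'
#' All calibration fields plus provenance (quantile convention,
#' fallback delta, configuration hash, seed).
#'
#' @param calibration A `calibration_result`.
#' @param path Output path.
#' @param seed Seed recorded in the provenance block.
#' @param extra Optional named list merged into the provenance block.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(calibration, path, seed = NA,
                                   extra = list()) {
  stopifnot(inherits(calibration, "calibration_result"))
  payload <- c(unclass(calibration),
               list(provenance = c(list(
                 quantile_convention = "weighted-average (R type 7)",
                 seed = seed,
                 config_hash = config_hash(unclass(calibration))), extra)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a diagnostic report as JSON
#'
#' @param report A `diagnostic_report`.
#' @param path Output path.
#' @param seed Seed recorded in the provenance block.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, seed = NA) {
  stopifnot(inherits(report, "diagnostic_report"))
  payload <- list(
    markers = report$markers, combined = report$combined,
    overlap = report$overlap,
    paired_maf = if (!is.null(report$paired_maf))
      unclass(report$paired_maf) else NULL,
    case_group = report$case_group,
    provenance = list(seed = seed,
                      config_hash = config_hash(report$markers)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Writes one droplet CSV per well plus a cohort manifest
#' (`manifest.csv`: sample_id, group, assay, file, truth fields).
#' Byte-identical across runs with the same config.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  manifest <- cohort$samples
  manifest$assay <- manifest$marker
  manifest$file <- file.path(out_dir,
                             paste0(manifest$sample_id, "_",
                                    manifest$marker, ".csv"))
  for (i in seq_len(nrow(manifest))) {
    key <- paste0(manifest$sample_id[i], ".", manifest$marker[i])
    write_droplet_csv(cohort$wells[[key]], manifest$file[i])
  }
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  message(sprintf("simulated %d wells for %d samples into %s",
                  nrow(manifest), length(unique(manifest$sample_id)),
                  out_dir))
  invisible(manifest)
}

quantify_cohort_rows <- function(wells, meta, thresholds, k,
                                 droplet_volume_nl) {
  failures <- character(0)
  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    rows[[i]] <- tryCatch(
      quantify_well(wells[[i]], assay = meta$assay[i],
                    thresholds = thresholds, k = k,
                    droplet_volume_nl = droplet_volume_nl,
                    group = meta$group[i]),
      error = function(e) {
        failures <<- c(failures,
                       paste0(meta$sample_id[i], "/", meta$assay[i],
                              ": ", conditionMessage(e)))
        NULL
      })
  }
  list(results = do.call(rbind, rows), failures = failures)
}

#' Analyze a cohort end-to-end
#'
#' Stage order mirrors the study: classify and quantify every well,
#' calibrate the false-positive MAF cutoff per marker on the control
#' samples, subtract it from every sample, then evaluate the cohort.
#' Per-well failures (e.g. saturated wells) are logged to stderr and
#' excluded, with a reported count.
#'
#' `analyze_cohort()` works on an in-memory [simulate_cohort()]
#' result; [run_analyze()] is the file-based equivalent.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param control_groups Groups used to set the cutoff (default
#'   "control", i.e. healthy volunteers only).
#' @param case_group Case group label (default "UBC").
#' @param thresholds,k Passed to [classify_droplets()].
#' @param delta Cutoff fallback offset, see [determine_cutoff()].
#' @return List of class `cohort_analysis`: `results` (calibrated
#'   sample_result rows), `calibrations` (per marker), `report`
#'   (a `diagnostic_report`), `n_failed`.
#' @export
analyze_cohort <- function(cohort, control_groups = "control",
                           case_group = "UBC", thresholds = "auto",
                           k = 6, delta = 0.05) {
  stopifnot(inherits(cohort, "cohort"))
  meta <- cohort$samples
  meta$assay <- meta$marker
  keys <- paste0(meta$sample_id, ".", meta$marker)
  q <- quantify_cohort_rows(cohort$wells[keys], meta, thresholds, k,
                            cohort$config$droplet_volume_nl)
  finish_analysis(q, control_groups, case_group, delta,
                  seed = cohort$config$seed)
}

#' @param data_dir Directory holding `manifest.csv` and droplet CSVs
#'   (as written by [run_simulate()]).
#' @param out_dir Optional output directory; when given, writes
#'   `results.csv`, one `calibration_<marker>.json` per marker and
#'   `report.json`.
#' @param droplet_volume_nl Droplet volume, nL.
#' @param seed Seed recorded in output provenance blocks.
#' @rdname analyze_cohort
#' @export
run_analyze <- function(data_dir, out_dir = NULL,
                        control_groups = "control", case_group = "UBC",
                        thresholds = "auto", k = 6, delta = 0.05,
                        droplet_volume_nl = 0.85, seed = NA) {
  manifest_path <- file.path(data_dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("no manifest.csv in ", data_dir)
  meta <- read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!any(meta$group %in% control_groups)) {
    stop("calibration impossible: manifest has no control-group rows")
  }
  wells <- lapply(meta$file, read_droplet_csv)
  message(sprintf("read %d wells (%d droplets total)", length(wells),
                  sum(vapply(wells, function(w) w$n_droplets, numeric(1)))))
  q <- quantify_cohort_rows(wells, meta, thresholds, k, droplet_volume_nl)
  out <- finish_analysis(q, control_groups, case_group, delta, seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_csv(out$results, file.path(out_dir, "results.csv"))
    for (mk in names(out$calibrations)) {
      write_calibration_json(out$calibrations[[mk]],
                             file.path(out_dir,
                                       paste0("calibration_", mk, ".json")),
                             seed = seed, extra = list(marker = mk))
    }
    write_report_json(out$report, file.path(out_dir, "report.json"),
                      seed = seed)
  }
  out
}

finish_analysis <- function(q, control_groups, case_group, delta, seed) {
  results <- q$results
  if (length(q$failures)) {
    message(sprintf("%d well(s) failed quantification and were excluded:",
                    length(q$failures)))
    for (f in q$failures) message("  ", f)
  }
  if (is.null(results) || !any(results$group %in% control_groups)) {
    stop("calibration impossible: no quantified control-group samples")
  }
  markers <- unique(results$assay)
  calibrations <- list()
  calibrated <- list()
  for (mk in markers) {
    m <- results[results$assay == mk, ]
    ctrl <- m$raw_maf[m$group %in% control_groups]
    cases <- m$raw_maf[m$group == case_group]
    cal <- determine_cutoff(ctrl, cases, delta = delta)
    calibrations[[mk]] <- cal
    calibrated[[mk]] <- apply_cutoff(m, cal$cutoff)
  }
  results <- do.call(rbind, calibrated)
  report <- evaluate_cohort(results, case_group = case_group)
  message(sprintf(
    "quantified %d wells; cutoffs: %s; %d/%d cases panel-positive",
    nrow(results),
    paste(sprintf("%s %.3f%%", markers,
                  vapply(calibrations, function(c) c$cutoff, numeric(1))),
          collapse = ", "),
    report$combined$n_detected, report$combined$n_cases))
  structure(list(results = results, calibrations = calibrations,
                 report = report, n_failed = length(q$failures),
                 seed = seed),
            class = "cohort_analysis")
}
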