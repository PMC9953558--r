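#' Two-channel droplet fluorescence amplitude model
#'
#' Cluster geometry for endpoint fluorescence in each channel:
#' negative and positive clusters are Gaussian; a small fraction of
#' positive droplets fall as "rain", uniform between the two cluster
#' means. Defaults are chosen to resemble typical two-dimensional
#' ddPCR scatter plots; classification tests use well-separated
#' settings (see `rain_fraction = 0`).
#'
#' @param neg_mean,neg_sd Negative-cluster mean / SD (arbitrary units).
#' @param pos_mean,pos_sd Positive-cluster mean / SD; `pos_mean` must
#'   exceed `neg_mean`.
#' @param rain_fraction Probability a positive droplet's amplitude is
#'   drawn uniformly between the cluster means, in [0, 1).
#' @return A list with one set of cluster parameters per channel
#'   (`fam`, `hex`).
#' @export
amplitude_model <- function(neg_mean = 1000, neg_sd = 150,
                            pos_mean = 8000, pos_sd = 400,
                            rain_fraction = 0.002) {
  stopifnot(pos_mean > neg_mean, neg_sd > 0, pos_sd > 0,
            rain_fraction >= 0, rain_fraction < 1)
  ch <- list(neg_mean = neg_mean, neg_sd = neg_sd,
             pos_mean = pos_mean, pos_sd = pos_sd,
             rain_fraction = rain_fraction)
  list(fam = ch, hex = ch)
}

#' Configuration for one simulated ddPCR well
#'
#' @param copies Named non-negative counts of template molecules loaded
#'   into the well, e.g. `c(WT = 5000, M1 = 500)`. Every non-"WT" name
#'   is treated as a mutant genotype.
#' @param n_droplets Number of droplets in the well (default 20000,
#'   the usual scale of a QX200 well).
#' @param droplet_volume_nl Droplet volume in nL (default 0.85,
#'   the nominal QX200 droplet volume).
#' @param epsilon Probability that a wild-type template molecule is
#'   misread as mutant-channel positive. This per-molecule mechanism
#'   makes false-positive mutant *copies* proportional to DNA input
#'   while the false-positive *MAF* stays near `epsilon`,
#'   input-independent — the behaviour observed in wild-type-only
#'   urine DNA. Default 0.003 puts the control-group false-positive
#'   MAF at the observed few-tenths-of-a-percent scale.
#' @param model An [amplitude_model()].
#' @param seed RNG seed; all outputs are pure functions of the config.
#' @param sample_id,well_id Identifiers carried into the output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(copies = c(WT = 5000),
                              n_droplets = 20000,
                              droplet_volume_nl = 0.85,
                              epsilon = 0.003,
                              model = amplitude_model(),
                              seed = 1L,
                              sample_id = "S1", well_id = "A01") {
  stopifnot(n_droplets > 0, droplet_volume_nl > 0,
            epsilon >= 0, epsilon <= 1,
            all(copies >= 0), !is.null(names(copies)))
  structure(list(copies = copies, n_droplets = as.integer(n_droplets),
                 droplet_volume_nl = droplet_volume_nl, epsilon = epsilon,
                 model = model, seed = seed,
                 sample_id = sample_id, well_id = well_id),
            class = "simulation_config")
}

#' Partition template molecules into droplets
#'
#' Each molecule is assigned to one droplet independently and uniformly
#' at random (multinomial partitioning), so per-genotype totals are
#' conserved exactly; Poisson occupancy statistics emerge in the
#' many-droplet limit.
#'
#' @param copies Named non-negative molecule counts per genotype.
#' @param n_droplets Number of droplets.
#' @param seed Optional seed set before drawing.
#' @return Integer occupancy matrix, `n_droplets` rows, one column per
#'   genotype.
#' @export
partition_templates <- function(copies, n_droplets, seed = NULL) {
  stopifnot(all(copies >= 0), n_droplets > 0)
  if (!is.null(seed)) set.seed(seed)
  n_droplets <- as.integer(n_droplets)
  occ <- vapply(copies, function(k) {
    if (k == 0) return(integer(n_droplets))
    tabulate(sample.int(n_droplets, size = k, replace = TRUE), n_droplets)
  }, integer(n_droplets))
  if (is.null(dim(occ))) occ <- matrix(occ, nrow = n_droplets)
  colnames(occ) <- names(copies)
  occ
}

#' Flag misread wild-type molecules
#'
#' Each WT molecule is independently flagged with probability `epsilon`;
#' a droplet holding at least one flagged molecule will render
#' mutant-channel positive downstream.
#'
#' @param occupancy Occupancy matrix from [partition_templates()] with
#'   a "WT" column.
#' @param epsilon Per-molecule misread probability in [0, 1].
#' @param seed Optional seed.
#' @return `occupancy` with an extra integer `misread` column
#'   (misread molecules per droplet; `misread <= WT` rowwise).
#' @export
apply_misread <- function(occupancy, epsilon, seed = NULL) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (!is.null(seed)) set.seed(seed)
  wt <- if ("WT" %in% colnames(occupancy)) occupancy[, "WT"] else
    integer(nrow(occupancy))
  misread <- rbinom(length(wt), size = wt, prob = epsilon)
  cbind(occupancy, misread = misread)
}

draw_channel <- function(positive, ch) {
  n <- length(positive)
  amp <- rnorm(n, ch$neg_mean, ch$neg_sd)
  npos <- sum(positive)
  if (npos > 0) {
    a <- rnorm(npos, ch$pos_mean, ch$pos_sd)
    rain <- runif(npos) < ch$rain_fraction
    if (any(rain)) a[rain] <- runif(sum(rain), ch$neg_mean, ch$pos_mean)
    amp[positive] <- a
  }
  amp
}

#' Render endpoint fluorescence amplitudes for a well
#'
#' Droplets with at least one non-misread WT molecule light the HEX
#' (wild-type) channel; droplets with at least one mutant or misread
#' molecule light the FAM (mutant) channel; droplets with both light
#' both (double-positive cluster); empty droplets stay in the negative
#' clusters.
#'
#' @param occupancy Occupancy matrix with `misread` column
#'   (from [apply_misread()]); a plain [partition_templates()] matrix
#'   is accepted and treated as misread-free.
#' @param model An [amplitude_model()].
#' @param seed Optional seed.
#' @param sample_id,well_id Identifiers.
#' @return A `droplet_set`: list with `amplitudes` (data.frame
#'   `fam`, `hex`), `truth` (occupancy, per-droplet channel truth),
#'   `sample_id`, `well_id`, `n_droplets`.
#' @export
render_amplitudes <- function(occupancy, model = amplitude_model(),
                              seed = NULL, sample_id = "S1",
                              well_id = "A01") {
  if (!is.null(seed)) set.seed(seed)
  if (!"misread" %in% colnames(occupancy)) {
    occupancy <- cbind(occupancy, misread = integer(nrow(occupancy)))
  }
  wt <- if ("WT" %in% colnames(occupancy)) occupancy[, "WT"] else
    integer(nrow(occupancy))
  misread <- occupancy[, "misread"]
  mut_cols <- setdiff(colnames(occupancy), c("WT", "misread"))
  mut <- if (length(mut_cols)) rowSums(occupancy[, mut_cols, drop = FALSE])
         else numeric(nrow(occupancy))
  hex_true <- (wt - misread) >= 1
  fam_true <- (mut + misread) >= 1
  structure(
    list(amplitudes = data.frame(
           fam = draw_channel(fam_true, model$fam),
           hex = draw_channel(hex_true, model$hex)),
         truth = list(occupancy = occupancy,
                      fam_positive = fam_true, hex_positive = hex_true),
         sample_id = sample_id, well_id = well_id,
         n_droplets = nrow(occupancy)),
    class = "droplet_set")
}

#' @export
print.droplet_set <- function(x, ...) {
  cat("<droplet_set> sample ", x$sample_id, ", well ", x$well_id, ": ",
      x$n_droplets, " droplets\n", sep = "")
  invisible(x)
}

#' Simulate one complete ddPCR well
#'
#' Composition of [partition_templates()], [apply_misread()] and
#' [render_amplitudes()]; deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A `droplet_set` with ground truth, including `true_maf`
#'   (percent, from loaded copies) in its `truth` element.
#' @export
simulate_well <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  occ <- partition_templates(config$copies, config$n_droplets)
  occ <- apply_misread(occ, config$epsilon)
  ds <- render_amplitudes(occ, config$model,
                          sample_id = config$sample_id,
                          well_id = config$well_id)
  wt <- sum(config$copies[names(config$copies) == "WT"])
  mut <- sum(config$copies[names(config$copies) != "WT"])
  ds$truth$copies <- config$copies
  ds$truth$true_maf <- if (wt + mut > 0) 100 * mut / (wt + mut) else NA_real_
  ds$config <- config
  ds
}

#' Fit a truncated log-normal to a printed MAF median and IQR
#'
#' UBC mutant allele fractions are modelled log-normal, truncated to
#' (0, 100] percent. Because truncation shifts quantiles, the
#' parameters are fitted numerically so that the *truncated*
#' distribution reproduces the target median and quartiles
#' (least-squares in log-quantile space).
#'
#' @param median,q25,q75 Target quantiles, percent.
#' @param upper Truncation point, percent (default 100).
#' @return List with `meanlog`, `sdlog`, `upper`.
#' @export
fit_maf_lognormal <- function(median, q25, q75, upper = 100) {
  stopifnot(q25 < median, median < q75)
  target <- log(c(q25, median, q75))
  obj <- function(par) {
    ml <- par[1]; sl <- exp(par[2])
    pu <- plnorm(upper, ml, sl)
    q <- qlnorm(c(0.25, 0.5, 0.75) * pu, ml, sl)
    sum((log(q) - target)^2)
  }
  init <- c(log(median), log(log(q75 / q25) / (2 * qnorm(0.75))))
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]), upper = upper)
}

#' Draw truncated log-normal MAFs
#'
#' @param n Number of draws.
#' @param fit A fit from [fit_maf_lognormal()].
#' @return Numeric vector in (0, `fit$upper`], percent.
#' @export
rmaf_lognormal <- function(n, fit) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- exp(rnorm(n, fit$meanlog, fit$sdlog))
    out <- c(out, x[x <= fit$upper])
  }
  out[seq_len(n)]
}

#' Configuration for a simulated urine liquid-biopsy cohort
#'
#' Emulates the study cohort: healthy volunteers and cystitis patients
#' carry no true mutant templates (any mutant signal arises from the
#' misread mechanism), while a fraction of UBC patients is positive
#' for each marker with log-normal MAFs matched to the printed
#' median/IQR summaries.
#'
#' @param n_control,n_cystitis,n_ubc Group sizes (defaults 50/22/70).
#' @param markers Named list of marker parameter lists, each with
#'   `maf_median`, `maf_q25`, `maf_q75` (percent) and `genotype_probs`
#'   (named probabilities over the marker's mutant genotypes).
#'   Defaults: GPR126 21.61 [8.30, 44.52] with genotype mix
#'   M1/M2/M1M2 = 0.57/0.26/0.17; TERT 28.29 [19.03, 38.08].
#' @param positivity Joint UBC positivity for the two markers, a list
#'   with `both`, `first_only`, `second_only` probabilities (first =
#'   first marker in `markers`). Defaults 18/70, 7/70, 22/70, giving
#'   marginals 25/70 and 40/70 and union 47/70.
#' @param input_range Range of total cell-free DNA copies loaded per
#'   well; input is drawn log-uniformly, spanning two orders of
#'   magnitude by default (200–20000 copies). For mutation-positive
#'   samples the mutant fraction of that input is the drawn MAF, so
#'   the total template load stays inside the droplet dynamic range
#'   regardless of MAF.
#' @param epsilon Per-molecule misread probability (default 0.003).
#' @param n_droplets Droplets per well.
#' @param droplet_volume_nl Droplet volume, nL.
#' @param model An [amplitude_model()].
#' @param seed Cohort seed; per-well seeds are derived from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 50, n_cystitis = 22, n_ubc = 70,
                          markers = list(
                            GPR126 = list(maf_median = 21.61,
                                          maf_q25 = 8.30, maf_q75 = 44.52,
                                          genotype_probs = c(M1 = 0.57,
                                                             M2 = 0.26,
                                                             M1M2 = 0.17)),
                            TERT = list(maf_median = 28.29,
                                        maf_q25 = 19.03, maf_q75 = 38.08,
                                        genotype_probs = c(M1 = 1))),
                          positivity = list(both = 18 / 70,
                                            first_only = 7 / 70,
                                            second_only = 22 / 70),
                          input_range = c(200, 20000),
                          epsilon = 0.003,
                          n_droplets = 20000,
                          droplet_volume_nl = 0.85,
                          model = amplitude_model(),
                          seed = 1L) {
  stopifnot(n_control >= 0, n_cystitis >= 0, n_ubc >= 0,
            length(markers) >= 1, input_range[1] > 0,
            input_range[2] >= input_range[1],
            epsilon >= 0, epsilon <= 1)
  stopifnot(all(unlist(positivity) >= 0), sum(unlist(positivity)) <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a full cohort of ddPCR wells
#'
#' One well per sample per marker. Control and cystitis samples carry
#' zero true mutant copies; UBC samples are assigned a joint
#' positivity category, and positive samples draw a true MAF from the
#' marker's truncated log-normal, which partitions the sample's total
#' cell-free DNA input into mutant and wild-type copies.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with `samples` (one row per
#'   sample x marker: sample_id, group, marker, wt_copies, mut_copies,
#'   genotype, true_maf, true_positive, well_seed) and `wells`
#'   (named list of `droplet_set`s, names `sample_id.marker`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- rep(c("control", "cystitis", "UBC"),
                c(config$n_control, config$n_cystitis, config$n_ubc))
  n <- length(groups)
  marker_names <- names(config$markers)
  fits <- lapply(config$markers, function(m)
    fit_maf_lognormal(m$maf_median, m$maf_q25, m$maf_q75))

  sample_ids <- sprintf("S%03d", seq_len(n))
  total_copies <- round(exp(runif(n, log(config$input_range[1]),
                                  log(config$input_range[2]))))
  # joint positivity category per UBC sample (markers beyond the first
  # two are drawn independently at rate first_only + both)
  p <- config$positivity
  cat_levels <- c("both", "first_only", "second_only", "neither")
  probs <- c(p$both, p$first_only, p$second_only,
             1 - p$both - p$first_only - p$second_only)
  category <- ifelse(groups == "UBC",
                     sample(cat_levels, n, replace = TRUE, prob = probs),
                     "neither")

  rows <- list()
  wells <- list()
  for (i in seq_len(n)) {
    for (j in seq_along(marker_names)) {
      mk <- marker_names[j]
      positive <- groups[i] == "UBC" &&
        ((j == 1 && category[i] %in% c("both", "first_only")) ||
         (j == 2 && category[i] %in% c("both", "second_only")))
      if (positive) {
        maf <- rmaf_lognormal(1, fits[[mk]])
        mut <- min(total_copies[i] - 1L,
                   max(1L, round(total_copies[i] * maf / 100)))
        gp <- config$markers[[mk]]$genotype_probs
        genotype <- sample(names(gp), 1, prob = gp)
      } else {
        maf <- 0; mut <- 0L; genotype <- NA_character_
      }
      wt <- total_copies[i] - mut
      copies <- c(WT = wt)
      if (mut > 0) copies[genotype] <- mut
      well_seed <- sample.int(.Machine$integer.max, 1)
      wcfg <- simulation_config(
        copies = copies, n_droplets = config$n_droplets,
        droplet_volume_nl = config$droplet_volume_nl,
        epsilon = config$epsilon, model = config$model,
        seed = well_seed, sample_id = sample_ids[i],
        well_id = paste0(sample_ids[i], ".", mk))
      wells[[paste0(sample_ids[i], ".", mk)]] <- simulate_well(wcfg)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_ids[i], group = groups[i], marker = mk,
        wt_copies = wt, mut_copies = mut,
        genotype = genotype,
        true_maf = if (mut > 0) 100 * mut / total_copies[i] else 0,
        true_positive = positive, well_seed = well_seed,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(samples = do.call(rbind, rows), wells = wells,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(unique(x$samples$sample_id)), " samples x ",
      length(unique(x$samples$marker)), " markers (",
      length(x$wells), " wells)\n", sep = "")
  print(table(unique(x$samples[, c("sample_id", "group")])$group))
  invisible(x)
}
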