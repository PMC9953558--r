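test_that("multinomial partitioning conserves template counts exactly", {
  set.seed(3)
  for (i in 1:10) {
    copies <- c(WT = sample(0:5000, 1), M1 = sample(0:500, 1))
    occ <- partition_templates(copies, 2000)
    expect_equal(colSums(occ), copies)
  }
  occ0 <- partition_templates(c(WT = 0), 50)
  expect_true(all(occ0 == 0))
  occ1 <- partition_templates(c(WT = 1), 10, seed = 5)
  expect_equal(sum(occ1), 1)
  expect_equal(sum(occ1 == 1), 1)
})

test_that("occupancy approaches the Poisson limit at low load", {
  # 2000 copies in 20000 droplets: occupied fraction ~ 1 - exp(-0.1)
  expected <- 1 - exp(-0.1)
  se <- sqrt(expected * (1 - expected) / 20000)
  for (seed in 1:5) {
    occ <- partition_templates(c(WT = 2000), 20000, seed = seed)
    frac <- mean(occ[, "WT"] > 0)
    expect_lt(abs(frac - expected), 3 * se)
  }
})

test_that("misread flags follow the per-molecule binomial model", {
  occ <- partition_templates(c(WT = 10000), 20000, seed = 1)
  expect_equal(sum(apply_misread(occ, 0)[, "misread"]), 0)
  expect_equal(sum(apply_misread(occ, 1)[, "misread"]), 10000)
  se <- sqrt(10000 * 0.003 * 0.997)
  for (seed in 1:5) {
    m <- apply_misread(occ, 0.003, seed = seed)
    expect_lt(abs(sum(m[, "misread"]) - 30), 3 * se)
    expect_true(all(m[, "misread"] <= m[, "WT"]))
  }
})

test_that("rendered amplitudes respect cluster geometry", {
  model <- separated_model()
  empty <- render_amplitudes(partition_templates(c(WT = 0), 500), model,
                             seed = 2)
  expect_true(all(empty$amplitudes$fam < model$fam$neg_mean +
                    6 * model$fam$neg_sd))
  expect_true(all(empty$amplitudes$hex < model$hex$neg_mean +
                    6 * model$hex$neg_sd))

  occ <- partition_templates(c(WT = 3000, M1 = 300), 20000, seed = 4)
  ds <- render_amplitudes(apply_misread(occ, 0), model, seed = 4)
  cl <- classify_droplets(ds)
  expect_equal(unname(cl$labels == "double" | cl$labels == "mut_only"),
               ds$truth$fam_positive)
  expect_equal(unname(cl$labels == "double" | cl$labels == "wt_only"),
               ds$truth$hex_positive)
})

test_that("simulate_well is deterministic and carries ground truth", {
  cfg <- simulation_config(copies = c(WT = 5000, M1 = 500), epsilon = 0,
                           seed = 99)
  a <- simulate_well(cfg)
  b <- simulate_well(cfg)
  expect_identical(a$amplitudes, b$amplitudes)
  expect_equal(a$truth$true_maf, 100 * 500 / 5500)
  expect_equal(colSums(a$truth$occupancy)[c("WT", "M1")],
               c(WT = 5000, M1 = 500))
})

test_that("truncated log-normal fits reproduce the printed MAF summaries", {
  targets <- list(c(21.61, 8.30, 44.52), c(28.29, 19.03, 38.08))
  set.seed(123)
  for (t in targets) {
    fit <- fit_maf_lognormal(t[1], t[2], t[3])
    x <- rmaf_lognormal(10000, fit)
    expect_true(all(x > 0 & x <= 100))
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    expect_lt(abs(q[2] - t[1]) / t[1], 0.10)
    expect_lt(abs(q[1] - t[2]) / t[2], 0.15)
    expect_lt(abs(q[3] - t[3]) / t[3], 0.15)
  }
})

test_that("cohort simulation matches the study design", {
  cfg <- cohort_config(n_droplets = 1000, seed = 21)
  coh <- simulate_cohort(cfg)
  samples <- unique(coh$samples[, c("sample_id", "group")])
  expect_equal(nrow(samples), 142)
  expect_equal(as.integer(table(samples$group)[c("control", "cystitis",
                                                 "UBC")]),
               c(50L, 22L, 70L))
  expect_equal(nrow(coh$samples), 142 * 2)
  expect_equal(length(coh$wells), 142 * 2)
  # non-UBC samples carry zero true mutant templates
  non_ubc <- coh$samples[coh$samples$group != "UBC", ]
  expect_true(all(non_ubc$mut_copies == 0))
  expect_true(all(non_ubc$true_maf == 0))
  # positive UBC samples record a consistent truth MAF
  pos <- coh$samples[coh$samples$true_positive, ]
  expect_true(all(pos$mut_copies >= 1))
  expect_equal(pos$true_maf,
               100 * pos$mut_copies / (pos$wt_copies + pos$mut_copies))
})

test_that("an epsilon-free control cohort has no FAM-true droplets", {
  cfg <- cohort_config(n_control = 5, n_cystitis = 0, n_ubc = 0,
                       epsilon = 0, n_droplets = 2000, seed = 8)
  coh <- simulate_cohort(cfg)
  fam_true <- vapply(coh$wells, function(w) sum(w$truth$fam_positive),
                     numeric(1))
  expect_true(all(fam_true == 0))
})

test_that("cohort simulation is a pure function of its config", {
  cfg <- cohort_config(n_control = 3, n_cystitis = 1, n_ubc = 4,
                       n_droplets = 500, seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$wells[[5]]$amplitudes, b$wells[[5]]$amplitudes)
})
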