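test_that("auto thresholding rejects degenerate input", {
  expect_error(auto_threshold(rep(1000, 50)), ">= 100 droplets")
  expect_error(auto_threshold(rep(1000, 500)), "zero spread")
})

test_that("droplet labels follow the quadrant definition", {
  ds <- list(amplitudes = data.frame(
    fam = c(100, 100, 9000, 9000),
    hex = c(100, 9000, 100, 9000)))
  cl <- classify_droplets(ds, thresholds = c(fam = 2000, hex = 2000))
  expect_equal(as.character(cl$labels),
               c("empty", "wt_only", "mut_only", "double"))
  expect_equal(sum(cl$counts), 4L)
})

test_that("well-separated wells are classified without error", {
  cfg <- simulation_config(copies = c(WT = 4000, M1M2 = 400), epsilon = 0,
                           model = separated_model(), seed = 12)
  ds <- simulate_well(cfg)
  cl <- classify_droplets(ds)
  fam_called <- cl$labels %in% c("mut_only", "double")
  hex_called <- cl$labels %in% c("wt_only", "double")
  expect_equal(unname(fam_called), ds$truth$fam_positive)
  expect_equal(unname(hex_called), ds$truth$hex_positive)
})

test_that("Poisson inversion matches the closed form", {
  expect_equal(poisson_concentration(0, 20000)$concentration, 0)
  pc <- poisson_concentration(2000, 20000, 0.85)
  expect_equal(pc$lambda, -log(0.9), tolerance = 1e-10)
  expect_equal(pc$concentration, -log(0.9) / 0.00085, tolerance = 1e-10)
  expect_equal(round(pc$concentration, 2), 123.95)
  expect_true(pc$ci_low <= pc$concentration &&
                pc$concentration <= pc$ci_high)
  expect_error(poisson_concentration(20000, 20000), "saturated")
})

test_that("concentration is strictly increasing in the positive count", {
  conc <- vapply(seq(0, 19000, by = 500),
                 function(k) poisson_concentration(k, 20000)$concentration,
                 numeric(1))
  expect_true(all(diff(conc) > 0))
})

test_that("MAF arithmetic is correct and scale invariant", {
  expect_equal(compute_maf(90, 10), 10)
  expect_equal(compute_maf(0, 5), 100)
  expect_equal(compute_maf(123.95, 123.95), 50)
  expect_error(compute_maf(0, 0), "undefined MAF")
  set.seed(5)
  for (i in 1:10) {
    x <- runif(1, 1, 500); y <- runif(1, 1, 500); a <- runif(1, 0.1, 20)
    expect_equal(compute_maf(a * x, a * y), compute_maf(x, y))
  }
})

test_that("quantify_well recovers simulated wells", {
  # wild-type-only well without misreads: no mutant signal at all
  r0 <- quick_well(c(WT = 3000), seed = 17)
  expect_equal(r0$c_mut, 0)
  expect_equal(r0$raw_maf, 0)

  # spiked well: raw MAF close to the loaded 9.09 %
  r <- quick_well(c(WT = 5000, M1 = 500), seed = 18)
  expect_lt(abs(r$raw_maf - 100 * 500 / 5500), 1)
  expect_equal(r$n_droplets, 20000L)

  # screening assay pools all mutant genotypes into one concentration
  r2 <- quick_well(c(WT = 3000, M1 = 150, M2 = 150, M1M2 = 100), seed = 19)
  expect_lt(abs(r2$raw_maf - 100 * 400 / 3400), 1)
})
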