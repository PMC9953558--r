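test_that("tie-aware AUC matches hand-computable cases", {
  expect_equal(roc_auc(1, 0)$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 0), c(0, 0))$auc, 4 / 6)
  # all ties: pure chance
  expect_equal(roc_auc(rep(0, 5), rep(0, 7))$auc, 0.5)
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("AUC equals the brute-force pair count and the U normalization", {
  set.seed(92)
  for (i in 1:15) {
    cases <- sample(0:5, sample(3:50, 1), replace = TRUE) + runif(1)
    controls <- sample(0:5, sample(3:50, 1), replace = TRUE)
    r <- roc_auc(cases, controls)
    expect_equal(r$auc, oracle_auc(cases, controls))
    u <- mann_whitney(cases, controls)$statistic
    expect_equal(r$auc, u / (length(cases) * length(controls)))
  }
})

test_that("AUC agrees with pROC on tied score vectors", {
  cases <- c(rep(3.2, 25), rep(0, 45))
  controls <- rep(0, 72)
  r <- roc_auc(cases, controls)
  p <- pROC::roc(response = c(rep(1, 70), rep(0, 72)),
                 predictor = c(cases, controls), quiet = TRUE,
                 direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(p)))
})

test_that("ROC points trace sensitivity/specificity monotonically", {
  set.seed(15)
  r <- roc_auc(rnorm(30, 1), rnorm(40))
  expect_true(all(diff(r$points$sensitivity) >= 0))
  expect_true(all(diff(r$points$specificity) <= 0))
  expect_equal(r$points$sensitivity[1], 0)
  expect_equal(r$points$specificity[1], 1)
})

test_that("sensitivity and specificity come out in percent", {
  calls <- c(rep(TRUE, 25), rep(FALSE, 45), rep(FALSE, 72))
  is_case <- c(rep(TRUE, 70), rep(FALSE, 72))
  ss <- sensitivity_specificity(calls, is_case)
  expect_equal(ss$sensitivity, 100 * 25 / 70)
  expect_equal(round(ss$sensitivity, 1), 35.7)
  expect_equal(ss$specificity, 100)
  expect_equal(sensitivity_specificity(c(TRUE, FALSE),
                                       c(TRUE, FALSE))$sensitivity, 100)
  expect_error(sensitivity_specificity(c(TRUE, TRUE), c(TRUE, TRUE)),
               "at least one")
})

test_that("panel combination is the union of marker calls", {
  # marginals 25 and 40 with overlap 18 -> union 47
  m <- matrix(FALSE, 70, 2, dimnames = list(NULL, c("GPR126", "TERT")))
  m[1:25, 1] <- TRUE
  m[8:47, 2] <- TRUE
  p <- combine_panel(m)
  expect_equal(unname(p$per_marker), c(25, 40))
  expect_equal(p$n_intersection, 18)
  expect_equal(p$n_union, 47)
  expect_equal(round(100 * p$n_union / 70, 1), 67.1)

  disjoint <- cbind(a = c(TRUE, TRUE, rep(FALSE, 8)),
                    b = c(FALSE, FALSE, TRUE, TRUE, TRUE, rep(FALSE, 5)))
  expect_equal(combine_panel(disjoint)$n_union, 5)
  expect_equal(combine_panel(matrix(FALSE, 4, 2))$n_union, 0)
  expect_error(combine_panel(matrix(c(TRUE, NA), 1)), "mismatched")
})

test_that("combined panel dominates individual markers in sensitivity", {
  set.seed(55)
  for (i in 1:10) {
    calls <- matrix(runif(60) < 0.4, 30, 2)
    p <- combine_panel(calls)
    expect_gte(p$n_union, max(colSums(calls)))
  }
})

test_that("paired Wilcoxon matches exact sign-flip enumeration", {
  # one-sided dominance with distinct difference magnitudes: V maximal
  set.seed(66)
  x <- sort(runif(8, 1, 10)) + (1:8) / 100
  y <- x - (1:8) / 2
  res <- paired_wilcoxon(x, y)
  expect_equal(res$statistic, 8 * 9 / 2)
  # oracle: enumerate all 2^8 sign assignments of the |d| ranks
  d <- x - y
  r <- rank(abs(d))
  vs <- vapply(0:(2^8 - 1), function(mask) {
    sum(r[bitwAnd(bitwShiftR(mask, 0:7), 1) == 1])
  }, numeric(1))
  v_obs <- sum(r[d > 0])
  p_exact <- mean(vs >= v_obs) + mean(vs <= 8 * 9 / 2 - v_obs)
  expect_equal(res$p_value, p_exact)

  # swap antisymmetry: V maps to n(n+1)/2 - V
  swapped <- paired_wilcoxon(y, x)
  expect_equal(swapped$statistic, 0)

  deg <- paired_wilcoxon(1:5, 1:5)
  expect_true(is.na(deg$p_value))
  expect_match(deg$note, "degenerate")
  expect_error(paired_wilcoxon(1:3, 1:4), "equal length")
})

test_that("Mann-Whitney U handles ties and matches exact enumeration", {
  expect_equal(mann_whitney(1, 1)$statistic, 0.5)
  expect_equal(mann_whitney(1, 1)$p_value, 1)
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  # oracle: all choose(6,3) = 20 label assignments; two-sided counts
  # the two extreme orderings, U = 0 and U = 9
  expect_equal(res$p_value, 2 / 20)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  expect_equal(spearman(1:10, (1:10)^2)$statistic, 1)
  expect_equal(spearman(1:10, -(1:10)^3)$statistic, -1)
  set.seed(30)
  for (i in 1:10) {
    x <- sample(1:8, 12, replace = TRUE)
    y <- sample(1:8, 12, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(spearman(x, y)$statistic,
                 cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  r <- fisher_exact(matrix(c(5, 0, 0, 5), 2))
  expect_equal(r$p_value, 2 / choose(10, 5))
  expect_equal(fisher_exact(matrix(c(3, 3, 4, 4), 2))$p_value, 1)
  a <- matrix(c(7, 2, 3, 8), 2)
  expect_equal(fisher_exact(a)$p_value, fisher_exact(a[2:1, ])$p_value)
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
})

test_that("linearity R2 is affine-invariant and matches closed-form OLS", {
  e <- c(0.5, 1, 2, 5, 10, 20, 50)
  expect_equal(linearity_r2(e, e), 1)
  expect_equal(linearity_r2(e, 2 * e + 3), 1)
  x <- c(1, 2, 4); y <- c(1.1, 1.9, 4.4)
  # closed form: squared Pearson correlation
  r2 <- (sum((x - mean(x)) * (y - mean(y)))^2 /
           (sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_equal(linearity_r2(x, y), r2)
  expect_error(linearity_r2(rep(1, 4), 1:4), "vary")
})

test_that("cohort evaluation reproduces the counted-score scenario", {
  mk_rows <- function(marker, n_pos) {
    data.frame(
      sample_id = sprintf("S%03d", 1:142),
      group = c(rep("UBC", 70), rep("control", 50), rep("cystitis", 22)),
      assay = marker,
      corrected_maf = c(runif(n_pos, 1, 50), rep(0, 142 - n_pos)),
      call = c(rep(TRUE, n_pos), rep(FALSE, 142 - n_pos)))
  }
  set.seed(9)
  g <- mk_rows("GPR126", 25)
  t <- mk_rows("TERT", 40)
  # force overlap 18: TERT positives are cases 8..47
  t$corrected_maf[1:70] <- 0; t$call[1:70] <- FALSE
  t$corrected_maf[8:47] <- runif(40, 1, 50); t$call[8:47] <- TRUE
  rep <- evaluate_cohort(rbind(g, t))
  expect_equal(rep$markers$auc, c(0.679, 0.786), tolerance = 1e-3)
  expect_equal(rep$combined$auc, 0.836, tolerance = 1e-3)
  expect_equal(rep$combined$n_detected, 47)
  expect_equal(rep$overlap$all_markers, 18)
  expect_equal(rep$markers$specificity, c(100, 100))
  expect_false(is.null(rep$paired_maf))

  # no positive cases at all: AUC collapses to chance
  null_rows <- mk_rows("GPR126", 0)
  null_rows2 <- mk_rows("TERT", 0)
  rep0 <- evaluate_cohort(rbind(null_rows, null_rows2))
  expect_equal(rep0$markers$auc, c(0.5, 0.5))
})

test_that("for all-zero controls the AUC is (1 + sensitivity) / 2", {
  for (n_pos in c(25, 40, 47)) {
    cases <- c(runif(n_pos, 0.1, 60), rep(0, 70 - n_pos))
    auc <- roc_auc(cases, rep(0, 72))$auc
    expect_equal(auc, (1 + n_pos / 70) / 2, tolerance = 1e-12)
  }
})
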