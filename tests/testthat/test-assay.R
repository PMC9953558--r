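test_that("reverse_complement handles simple cases and rejects bad input", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement("A"), "T")
  expect_error(reverse_complement(""), "invalid DNA")
  expect_error(reverse_complement("ATGN"), "invalid DNA")
})

test_that("reverse_complement is an involution and agrees with Biostrings", {
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 121, replace = TRUE),
               collapse = "")
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(s))))
  }
})

test_that("mismatch_count matches hand counts on the printed probe set", {
  wt <- "TTTGTATGAACATACAAAGAGCCTC"
  m1 <- "TTTGTATAAACATACAAAGAGCCTC"
  m1m2 <- "TTTGTATAAATATACAAAGAGCCTC"
  expect_equal(mismatch_count(wt, wt), 0)
  expect_equal(mismatch_count(wt, m1), 1)
  expect_equal(mismatch_count(wt, m1m2), 2)
  expect_error(mismatch_count(wt, "ACGT"), "equal length")
})

test_that("mismatch_count is symmetric and satisfies the triangle property", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    mk <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
    a <- mk(); b <- mk(); cc <- mk()
    expect_equal(mismatch_count(a, b), mismatch_count(b, a))
    expect_lte(abs(mismatch_count(a, cc) - mismatch_count(a, b)),
               mismatch_count(b, cc))
  }
})

test_that("the screening assay discriminates all four genotypes", {
  m <- discrimination_matrix(gpr126_assay())
  expect_equal(dim(m), c(4, 4))
  expect_equal(unname(diag(m)), rep(0L, 4))
  off <- m[row(m) != col(m)]
  expect_true(all(off %in% c(1L, 2L)))
  # a single-mismatch probe still sees the double mutant at distance 1
  expect_equal(m["GPR126_M1", "M1M2"], 1L)
  # each probe has exactly one perfect-match genotype
  expect_equal(unname(rowSums(m == 0)), rep(1L, 4))
})

test_that("screening-to-single-target conversion triples the kept probe", {
  a <- gpr126_assay()
  st <- to_single_target_assay(a, "M1")
  fam <- st$oligos[st$oligos$fluorophore == "FAM", ]
  expect_equal(nrow(fam), 1L)
  expect_equal(fam$concentration, 3 * 0.083)
  # primers and HEX probe records are untouched
  keep <- a$oligos$fluorophore != "FAM"
  expect_identical(st$oligos[st$oligos$fluorophore != "FAM", ],
                   a$oligos[keep, ])
  # reduced assay discriminates its own genotype perfectly
  m <- discrimination_matrix(st)
  expect_equal(unname(m["GPR126_M1", "M1"]), 0L)
  expect_error(to_single_target_assay(st, "M1"), "already single-target")
  expect_error(to_single_target_assay(a, "M9"), "no FAM probe")
})

test_that("assay validation balances probe concentrations and places primers", {
  a <- gpr126_assay()
  v <- validate_assay(a)
  expect_equal(v$fam_total, 0.249)
  expect_equal(v$hex_total, 0.25)
  expect_true(v$conc_balanced)

  ref <- read_reference_fasta(
    system.file("extdata", "gpr126_region_synthetic.fa",
                package = "ddscreen"))
  v2 <- validate_assay(a, ref)
  expect_equal(v2$amplicon_length, 121L)
  expect_true(v2$amplicon_matches_declared)

  expect_error(validate_assay(a, paste(rep("ACGT", 50), collapse = "")),
               "ambiguous priming")
})

test_that("assay definitions survive a JSON round trip", {
  a <- gpr126_assay()
  path <- withr::local_tempfile(fileext = ".json")
  write_assay_json(a, path)
  b <- read_assay_json(path)
  expect_equal(b$oligos, a$oligos)
  expect_equal(b$variants, a$variants)
  expect_equal(b$amplicon_length, a$amplicon_length)
  expect_identical(discrimination_matrix(b), discrimination_matrix(a))
})
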