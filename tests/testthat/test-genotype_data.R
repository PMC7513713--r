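test_that("wide CSV calls are read back, missing preserved", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,L1,L2",
               "i1,AA,AG",
               "i2,..,GG"), f)
  p <- read_genotypes(f, "wide_csv", panel_id = "toy")
  expect_equal(p$loci, c("L1", "L2"))
  expect_equal(unname(p$a1["i1", ]), c("A", "A"))
  expect_equal(unname(p$a2["i1", ]), c("A", "G"))
  expect_true(is.na(p$a1["i2", "L1"]) && is.na(p$a2["i2", "L1"]))
  expect_equal(sum(is.na(p$a1)), 1L)
})

test_that("VCF GT 0/1 at a C->T site becomes the allele pair {C,T}", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "i1", "i2", sep = "\t"),
               paste("1", "100", "rs1", "C", "T", ".", "PASS", ".", "GT",
                     "0/1", "1/1", sep = "\t"),
               paste("1", "200", "rs2", "A", "G", ".", "PASS", ".", "GT",
                     "./.", "0/0", sep = "\t")), f)
  p <- read_genotypes(f, "vcf")
  expect_setequal(c(p$a1["i1", "rs1"], p$a2["i1", "rs1"]), c("C", "T"))
  expect_equal(unname(c(p$a1["i2", "rs1"], p$a2["i2", "rs1"])), c("T", "T"))
  expect_true(is.na(p$a1["i1", "rs2"]))
})

test_that("multi-allelic VCF records are rejected with a clear message", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "i1", "i2", sep = "\t"),
               paste("1", "100", "rs1", "C", "T,G", ".", "PASS", ".", "GT",
                     "0/1", "1/2", sep = "\t")), f)
  expect_error(read_genotypes(f, "vcf"), "multi-allelic")
})

test_that("two-column microsatellite CSV reads allele pairs and 0 as missing", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,M1.1,M1.2,M2.1,M2.2",
               "i1,212,216,100,100",
               "i2,0,0,102,104"), f)
  p <- read_genotypes(f, "two_col_csv", panel_id = "MHC")
  expect_equal(p$loci, c("M1", "M2"))
  expect_setequal(c(p$a1["i1", "M1"], p$a2["i1", "M1"]), c("212", "216"))
  expect_true(is.na(p$a1["i2", "M1"]))
  expect_equal(unname(p$a1["i2", "M2"]), "102")
})

test_that("duplicate individual ids are a validation error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,L1", "i1,AA", "i1,AG"), f)
  expect_error(read_genotypes(f, "wide_csv"), "duplicate individual id")
})

test_that("half-calls are demoted to missing", {
  a1 <- matrix(c("A", "A", "A", NA), 2, 2,
               dimnames = list(c("i1", "i2"), c("L1", "L2")))
  a2 <- matrix(c("G", "A", "T", "C"), 2, 2,
               dimnames = list(c("i1", "i2"), c("L1", "L2")))
  expect_warning(p <- genotype_panel(a1, a2, "x"), "half-call")
  expect_true(is.na(p$a1["i2", "L2"]) && is.na(p$a2["i2", "L2"]))
})

test_that("roster rows are validated against the breeding invariants", {
  f <- withr::local_tempfile(fileext = ".csv")
  base <- "individual_id,enclosure_year,sex,age,weight,bred,n_offspring"
  writeLines(c(base, "d1,E1,F,2,7.2,1,2", "d2,E1,M,4,9.9,0,0"), f)
  r <- read_roster(f)
  expect_s3_class(r, "roster")
  expect_equal(nrow(r), 2L)

  writeLines(c(base, "d1,E1,F,2,7.2,1,5"), f)
  expect_error(read_roster(f), "more than 4 offspring")

  writeLines(c(base, "d1,E1,M,4,9.9,0,1"), f)
  expect_error(read_roster(f), "inconsistent")

  writeLines(c(base, "d1,E1,X,4,9.9,0,0"), f)
  expect_error(read_roster(f), "sex")

  writeLines(c(base, "d1,E1,M,4,9.9,1,6"), f)  # males may exceed 4
  expect_silent(r <- read_roster(f))
  expect_equal(r$n_offspring, 6L)
})

test_that("sMLH matches the hand-computed two-individual example", {
  # ind1 het at both loci, ind2 het at none: Hbar = (0.5, 0.5),
  # h_std = 2/1 and 0/1
  a1 <- matrix(c("A", "A", "A", "C"), 2, 2,
               dimnames = list(c("i1", "i2"), c("L1", "L2")))
  a2 <- matrix(c("G", "A", "T", "C"), 2, 2,
               dimnames = list(c("i1", "i2"), c("L1", "L2")))
  h <- smlh(genotype_panel(a1, a2, "toy"))
  expect_equal(h$h_std, c(2, 0))
  expect_equal(h$h_raw, c(2L, 0L))
  expect_equal(h$n_typed, c(2L, 2L))
})

test_that("with complete data mean sMLH is exactly 1; oracle agrees under missingness", {
  set.seed(41)
  for (rep in 1:10) {
    p <- random_panel(12, 30, missing_rate = 0)
    h <- smlh(p)
    expect_equal(mean(h$h_std), 1, tolerance = 1e-12)
    pm <- random_panel(12, 30, missing_rate = 0.2)
    expect_equal(smlh(pm)$h_std, oracle_smlh(pm))
  }
})

test_that("sMLH is invariant to allele relabeling and locus order", {
  set.seed(42)
  p <- random_panel(10, 20, missing_rate = 0.1)
  h <- smlh(p)
  relab <- c(a = "w", b = "x", c = "y", d = "z")
  p2 <- genotype_panel(matrix(relab[p$a1], nrow = 10, dimnames = dimnames(p$a1)),
                       matrix(relab[p$a2], nrow = 10, dimnames = dimnames(p$a2)),
                       p$panel_id)
  expect_equal(smlh(p2)$h_std, h$h_std)
  shuffle <- sample(p$loci)
  p3 <- subset(p, loci = shuffle)
  expect_equal(smlh(p3)$h_std, h$h_std)
})

test_that("permuting individuals permutes sMLH rows identically", {
  set.seed(43)
  p <- random_panel(8, 15, missing_rate = 0.1)
  h <- smlh(p)
  perm <- sample(p$individuals)
  hp <- smlh(subset(p, individuals = perm))
  expect_equal(hp$h_std, h$h_std[match(perm, h$individual_id)])
})

test_that("degenerate panels are flagged: all-homozygous and untyped loci", {
  a1 <- a2 <- matrix(c("A", "A", "C", "C"), 2, 2,
                     dimnames = list(c("i1", "i2"), c("L1", "L2")))
  h <- smlh(genotype_panel(a1, a2, "hom"))
  expect_true(all(is.na(h$h_std)))  # zero denominator: undefined, flagged

  a1 <- matrix(c("A", "A", NA, NA), 2, 2,
               dimnames = list(c("i1", "i2"), c("L1", "L2")))
  a2 <- matrix(c("G", "A", NA, NA), 2, 2,
               dimnames = list(c("i1", "i2"), c("L1", "L2")))
  expect_warning(h <- smlh(genotype_panel(a1, a2, "x")), "typed in no individual")
  expect_equal(h$n_typed, c(1L, 1L))
})

test_that("unmatched roster ids are reported", {
  set.seed(44)
  p <- random_panel(4, 5)
  roster <- data.frame(individual_id = c(p$individuals[1:2], "ghost"),
                       enclosure_year = "E1", sex = c("F", "M", "F"),
                       age = 2L, weight = 7, bred = 0L, n_offspring = 0L)
  expect_equal(unmatched_ids(as_roster(roster), p), "ghost")
})
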