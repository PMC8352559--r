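test_that("summary statistics read from TSV with normalization and row filtering", {
  recs <- read_summary_stats(fixture_exposure_path(), trait = "pth")
  expect_s3_class(recs, "gwas_summary")
  expect_equal(nrow(recs), 5L)
  expect_equal(recs$beta, c(0.07, 0.03, 0.04, 0.02, 0.03))

  # header-only file -> empty table
  empty <- read_summary_stats(write_tsv_fixture(
    "SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn"))
  expect_equal(nrow(empty), 0L)

  # lower-case alleles are upper-cased
  lower <- read_summary_stats(write_tsv_fixture(c(
    "SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\tt\ta\t0.3\t0.05\t0.01\t1e-12\t1000")))
  expect_equal(lower$effect_allele, "T")
  expect_equal(lower$other_allele, "A")

  # rows missing beta are dropped with a message
  expect_message(
    dropped <- read_summary_stats(write_tsv_fixture(c(
      "SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
      "rs1\tT\tA\t0.3\t0.05\t0.01\t1e-12\t1000",
      "rs2\tT\tC\t0.3\t\t0.01\t1e-12\t1000"))),
    "dropped")
  expect_equal(dropped$SNP, "rs1")

  # non-numeric beta fails fast
  expect_error(
    read_summary_stats(write_tsv_fixture(c(
      "SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
      "rs1\tT\tA\t0.3\tbroken\t0.01\t1e-12\t1000"))),
    "non-numeric")

  # remapped columns resolve; unmapped requirements error
  mapped <- read_summary_stats(write_tsv_fixture(c(
    "rsid\tEA\tOA\tfreq\tb\tstderr\tp\tsize",
    "rs1\tT\tA\t0.3\t0.05\t0.01\t1e-12\t1000")),
    column_map = c(SNP = "rsid", effect_allele = "EA", other_allele = "OA",
                   eaf = "freq", beta = "b", se = "stderr", pval = "p",
                   n = "size"))
  expect_equal(mapped$SNP, "rs1")
  expect_error(
    read_summary_stats(write_tsv_fixture(c("a\tb", "1\t2")),
                       column_map = c(SNP = "nope")),
    "absent")
})

test_that("record validation enforces invariants", {
  expect_error(gwas_records(c("rs1", "rs1"), "T", "A", 0.3, 0.1, 0.01,
                            1e-9, 100), "duplicate")
  expect_error(gwas_records("rs1", "T", "T", 0.3, 0.1, 0.01, 1e-9, 100),
               "identical")
  expect_error(gwas_records("rs1", "X", "A", 0.3, 0.1, 0.01, 1e-9, 100),
               "allele")
  expect_error(gwas_records("rs1", "T", "A", 0.3, 0.1, -0.01, 1e-9, 100),
               "standard error")
})

test_that("instrument selection uses a strict genome-wide threshold", {
  recs <- read_summary_stats(fixture_exposure_path())
  expect_equal(nrow(select_instruments(recs)), 5L)

  boundary <- gwas_records(c("rs1", "rs2"), c("T", "G"), c("A", "A"),
                           0.3, 0.1, 0.01, c(5e-8, 4.99e-8), 1000)
  expect_equal(select_instruments(boundary)$SNP, "rs2")

  none <- gwas_records(c("rs1", "rs2"), c("T", "G"), c("A", "A"),
                       0.3, 0.1, 0.01, 0.5, 1000)
  expect_message(out <- select_instruments(none), "no records")
  expect_equal(nrow(out), 0L)
})

test_that("LD lookup is symmetric with identity and zero defaults", {
  ld <- ld_table("rs1", "rs2", 0.38)
  expect_equal(ld_r2(ld, "rs2", "rs1"), 0.38)
  expect_equal(ld_r2(ld, "rs1", "rs1"), 1)
  expect_equal(ld_r2(ld, "rs1", "rs9"), 0)
})

test_that("greedy LD pruning drops the weaker SNP of a correlated pair", {
  fx <- make_fixture_lead6()
  pruned <- ld_prune(fx$records, fx$ld, 0.01)
  expect_setequal(pruned$SNP, make_fixture_table2()$SNP)
  expect_false("rs35194449" %in% pruned$SNP)

  # all pairs independent -> unchanged
  expect_equal(ld_prune(fx$records, ld_table(), 0.01), fx$records)

  # three mutually perfectly correlated SNPs -> only smallest-p retained;
  # exhaustive enumeration of pairwise-independent subsets agrees
  trio <- gwas_records(c("rsA", "rsB", "rsC"), "T", "A", 0.3, 0.1, 0.01,
                       c(1e-10, 1e-20, 1e-15), 1000)
  ld_all <- ld_table(c("rsA", "rsA", "rsB"), c("rsB", "rsC", "rsC"),
                     c(1, 1, 1))
  expect_equal(ld_prune(trio, ld_all, 0.01)$SNP, "rsB")
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(trio$SNP, k, simplify = FALSE)), recursive = FALSE)
  independent <- Filter(function(s) {
    length(s) == 1L ||
      all(utils::combn(s, 2, function(p) ld_r2(ld_all, p[1], p[2])) < 0.01)
  }, subsets)
  expect_true(list("rsB") %in% independent)
  expect_equal(max(lengths(independent)), 1L)
})

test_that("pruned output is pairwise independent for random LD structures", {
  for (seed in 1:20) {
    dat <- withr::with_seed(seed, {
      L <- 12L
      ids <- sprintf("rs%03d", seq_len(L))
      pairs <- t(utils::combn(ids, 2))
      list(records = gwas_records(ids, "T", "G", 0.3, 0.1, 0.01,
                                  stats::runif(L, 1e-30, 1e-8), 1000),
           ld = ld_table(pairs[, 1], pairs[, 2],
                         stats::rbinom(nrow(pairs), 1, 0.3) *
                           stats::runif(nrow(pairs))))
    })
    kept <- ld_prune(dat$records, dat$ld, 0.01)$SNP
    if (length(kept) > 1L) {
      pairwise <- utils::combn(kept, 2,
                               function(p) ld_r2(dat$ld, p[1], p[2]))
      expect_true(all(pairwise < 0.01))
    }
  }
})

test_that("palindrome detection covers complement pairs only", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("T", "C"))
  expect_equal(is_palindromic(c("a", "G"), c("t", "C")), c(TRUE, TRUE))
  expect_error(is_palindromic("N", "A"), "invalid base")
})

test_that("allele flip is an involution on beta and eaf", {
  recs <- read_summary_stats(fixture_exposure_path())
  expect_equal(flip_effect_allele(flip_effect_allele(recs)), recs)
  once <- flip_effect_allele(recs)
  expect_equal(once$beta, -recs$beta)
  expect_equal(once$eaf, 1 - recs$eaf)
})

test_that("harmonization aligns swapped, complemented and palindromic records", {
  exp1 <- gwas_records("rs1", "G", "A", 0.30, 0.05, 0.01, 1e-12, 1000)

  # swapped alleles: sign and frequency flip
  out_swapped <- gwas_records("rs1", "A", "G", 0.30, 0.02, 0.01, 0.1, 5000)
  h <- harmonize(exp1, out_swapped)
  expect_equal(h$beta_out, -0.02)
  expect_equal(h$eaf_out, 0.70)

  # strand complements for a non-palindromic SNP
  exp2 <- gwas_records("rs2", "A", "G", 0.2, 0.05, 0.01, 1e-12, 1000)
  out_comp <- gwas_records("rs2", "T", "C", 0.2, 0.03, 0.01, 0.1, 5000)
  h2 <- harmonize(exp2, out_comp)
  expect_equal(h2$beta_out, 0.03)

  # palindromic with intermediate frequency cannot be resolved
  exp3 <- gwas_records("rs3", "A", "T", 0.50, 0.05, 0.01, 1e-12, 1000)
  out3 <- gwas_records("rs3", "A", "T", 0.50, 0.03, 0.01, 0.1, 5000)
  expect_message(h3 <- harmonize(exp3, out3), "intermediate")
  expect_equal(nrow(h3), 0L)
  expect_equal(attr(h3, "dropped")$SNP, "rs3")

  # palindromic outside the band, frequencies on opposite sides of 0.5
  exp4 <- gwas_records("rs4", "A", "T", 0.30, 0.05, 0.01, 1e-12, 1000)
  out4 <- gwas_records("rs4", "A", "T", 0.70, 0.03, 0.01, 0.1, 5000)
  h4 <- harmonize(exp4, out4)
  expect_equal(h4$beta_out, -0.03)
  expect_equal(h4$eaf_out, 0.30)

  # non-concordant allele sets are excluded
  exp5 <- gwas_records("rs5", "A", "G", 0.3, 0.05, 0.01, 1e-12, 1000)
  out5 <- gwas_records("rs5", "A", "C", 0.3, 0.03, 0.01, 0.1, 5000)
  expect_message(h5 <- harmonize(exp5, out5), "non-concordant")
  expect_equal(nrow(h5), 0L)

  # SNPs absent from either table are dropped with a log entry
  expect_message(harmonize(rbind(exp1, exp2), out_swapped), "absent")
})

test_that("published instrument tables harmonize without exclusions", {
  exposure <- read_summary_stats(fixture_exposure_path(), trait = "pth")
  outcome <- read_summary_stats(fixture_outcome_path(), trait = "oa")
  h <- harmonize(exposure, outcome)
  expect_equal(nrow(h), 5L)
  expect_equal(nrow(attr(h, "dropped")), 0L)
  fx <- make_fixture_table2()
  expect_equal(h$beta_exp, fx$beta_exp)
  expect_equal(h$beta_out, fx$beta_out)
  expect_equal(h$palindromic, fx$palindromic)
})

test_that("harmonization is idempotent", {
  exposure <- read_summary_stats(fixture_exposure_path(), trait = "pth")
  outcome <- read_summary_stats(fixture_outcome_path(), trait = "oa")
  h1 <- harmonize(exposure, outcome)
  # express the harmonized outcome as records on the exposure alleles
  outcome2 <- outcome
  outcome2$beta <- h1$beta_out[match(outcome2$SNP, h1$SNP)]
  outcome2$eaf <- h1$eaf_out[match(outcome2$SNP, h1$SNP)]
  h2 <- harmonize(exposure, outcome2)
  expect_equal(h2, h1, ignore_attr = TRUE)
})

test_that("selection then pruning on the six lead SNPs yields the five instruments", {
  lead <- read_summary_stats(
    system.file("extdata", "pth_lead6_synthetic.tsv", package = "mrkit"))
  ld <- read_ld_table(
    system.file("extdata", "ld_lead_snps.tsv", package = "mrkit"))
  kept <- ld_prune(select_instruments(lead), ld)
  expect_setequal(kept$SNP, make_fixture_table2()$SNP)
})
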