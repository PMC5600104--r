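test_that("summary tables parse at full precision in file order", {
  tab <- read_summary_stats(mrkin_fixture("ccgc_exposure"), "exposure")
  expect_s3_class(tab, "variant_assoc")
  expect_equal(nrow(tab), 8L)
  expect_equal(tab$snp_id[1], "rs1260326")
  row <- tab[tab$snp_id == "rs2470893", ]
  expect_equal(row$effect_allele, "T")
  expect_equal(row$other_allele, "C")
  expect_equal(row$beta, 0.09)
  expect_equal(row$se, 0.01)
  expect_equal(tab$phenotype, rep("exposure", 8))

  out <- read_summary_stats(mrkin_fixture("ukbiobank_outcome"),
                            "outcome")
  row <- out[out$snp_id == "rs6265", ]
  expect_equal(row$beta, 0.207)
  expect_equal(row$se, 0.167)
})

test_that("a header-only table yields an empty association list", {
  path <- write_tsv_fixture(
    "snp_id\tgene\teffect_allele\tother_allele\tbeta\tse")
  tab <- read_summary_stats(path, "exposure")
  expect_equal(nrow(tab), 0L)
})

test_that("malformed summary tables fail with informative errors", {
  no_se <- write_tsv_fixture(c(
    "snp_id\tgene\teffect_allele\tother_allele\tbeta",
    "rs1\tG1\tA\tG\t0.1"))
  expect_error(read_summary_stats(no_se, "exposure"), "se")

  bad_row <- write_tsv_fixture(c(
    "snp_id\tgene\teffect_allele\tother_allele\tbeta\tse",
    "rs1\tG1\tA\tG\t0.1\t0.01",
    "rs2\tG2\tA\tG\txx\t0.01"))
  expect_error(read_summary_stats(bad_row, "exposure"), "row")

  neg_se <- write_tsv_fixture(c(
    "snp_id\tgene\teffect_allele\tother_allele\tbeta\tse",
    "rs1\tG1\tA\tG\t0.1\t-0.01"))
  expect_error(read_summary_stats(neg_se, "exposure"), "row")

  dup <- write_tsv_fixture(c(
    "snp_id\tgene\teffect_allele\tother_allele\tbeta\tse",
    "rs1\tG1\tA\tG\t0.1\t0.01",
    "rs1\tG1\tA\tG\t0.2\t0.01"))
  expect_error(read_summary_stats(dup, "exposure"), "duplicate")
})

test_that("harmonize keeps matched alleles and flips swapped ones", {
  exposure <- variant_assoc("rs1", "C", "T", 0.05, 0.01, "exposure")
  same <- variant_assoc("rs1", "C", "T", -0.07, 0.02, "outcome")
  set <- harmonize(exposure, same)
  expect_equal(set$entries$beta_x, 0.05)
  expect_equal(set$entries$beta_y, -0.07)

  swapped <- variant_assoc("rs1", "T", "C", 0.07, 0.02, "outcome")
  set2 <- harmonize(exposure, swapped)
  expect_equal(set2$entries$beta_y, -0.07)
  expect_equal(set2$entries$effect_allele, "C")
})

test_that("harmonize rejects palindromic and irreconcilable SNPs", {
  pal <- variant_assoc("rs1", "A", "T", 0.05, 0.01, "exposure")
  pal_out <- variant_assoc("rs1", "A", "T", 0.07, 0.02, "outcome")
  expect_error(harmonize(pal, pal_out), "palindromic")
  expect_silent(harmonize(pal, pal_out, palindromic = "allow"))

  exposure <- variant_assoc("rs1", "A", "G", 0.05, 0.01, "exposure")
  clash <- variant_assoc("rs1", "A", "C", 0.07, 0.02, "outcome")
  expect_error(harmonize(exposure, clash), "rs1")
})

test_that("outcome-only SNPs are ignored; missing outcome SNPs error", {
  exposure <- variant_assoc("rs1", "A", "G", 0.05, 0.01, "exposure")
  outcome <- variant_assoc(c("rs1", "rs9"), c("A", "C"), c("G", "T"),
                           c(0.07, 0.1), c(0.02, 0.02), "outcome")
  expect_message(set <- harmonize(exposure, outcome), "rs9")
  expect_equal(set$entries$snp_id, "rs1")

  expect_error(harmonize(outcome, exposure), "rs9")
})

test_that("harmonization is idempotent and a sign-flip involution", {
  exposure <- coffee_exposure()
  outcome <- smoking_outcome()
  set <- harmonize(exposure, outcome)

  # feed the harmonized outcome back through: nothing changes
  rebuilt <- variant_assoc(set$entries$snp_id, set$entries$effect_allele,
                           set$entries$other_allele, set$entries$beta_y,
                           set$entries$se_y, "outcome")
  expect_equal(harmonize(exposure, rebuilt)$entries, set$entries)

  # flipping outcome allele labels and beta sign leaves the set invariant
  flipped <- variant_assoc(outcome$snp_id, outcome$other_allele,
                           outcome$effect_allele, -outcome$beta,
                           outcome$se, "outcome")
  expect_equal(harmonize(exposure, flipped)$entries, set$entries)
})

test_that("ld_prune drops one of a correlated pair, reproducibly", {
  exposure <- variant_assoc(c("rs6968554", "rs4410790"), c("A", "C"),
                            c("G", "T"), c(0.05, 0.05), c(0.01, 0.01),
                            "exposure")
  outcome <- variant_assoc(c("rs6968554", "rs4410790"), c("A", "C"),
                           c("G", "T"), c(-0.07, -0.0679),
                           c(0.09, 0.0906), "outcome")
  r2 <- matrix(c(1, 0.99, 0.99, 1), 2, 2,
               dimnames = list(c("rs6968554", "rs4410790"),
                               c("rs6968554", "rs4410790")))
  set <- harmonize(exposure, outcome, ld_r2 = r2)
  pruned <- ld_prune(set, threshold = 0.0006, seed = 7)
  expect_equal(nrow(pruned$entries), 1L)
  expect_true(pruned$entries$snp_id %in% c("rs6968554", "rs4410790"))
  again <- ld_prune(set, threshold = 0.0006, seed = 7)
  expect_identical(pruned$entries, again$entries)
})

test_that("ld_prune leaves independent sets unchanged and validates r2", {
  set <- smoking_set()
  snps <- set$entries$snp_id
  r2 <- matrix(0, 8, 8, dimnames = list(snps, snps))
  diag(r2) <- 1
  set$ld_r2 <- r2
  pruned <- ld_prune(set, threshold = 0.0006, seed = 1)
  expect_equal(pruned$entries, set$entries)

  r2[1, 2] <- r2[2, 1] <- NA
  set$ld_r2 <- r2
  expect_error(ld_prune(set, threshold = 0.0006, seed = 1), "pair")
})

test_that("pruned sets never retain a pair at or above threshold", {
  set.seed(11)
  for (rep in 1:20) {
    snps <- paste0("rs", 1:6)
    r2 <- matrix(0, 6, 6, dimnames = list(snps, snps))
    vals <- stats::runif(15)
    r2[upper.tri(r2)] <- vals
    r2 <- r2 + t(r2); diag(r2) <- 1
    set <- instrument_set(
      data.frame(snp_id = snps, beta_x = 0.05, se_x = 0.01,
                 beta_y = 0.1, se_y = 0.05),
      ld_r2 = r2)
    pruned <- ld_prune(set, threshold = 0.5, seed = rep)
    kept <- pruned$entries$snp_id
    if (length(kept) > 1) {
      pairs <- utils::combn(kept, 2)
      worst <- max(apply(pairs, 2, function(p) r2[p[1], p[2]]))
      expect_lt(worst, 0.5)
    }
  }
})

test_that("instrument models have the published membership and nest", {
  set <- smoking_set()
  m2 <- select_model(set, "2-SNP")
  expect_setequal(m2$entries$snp_id, c("rs4410790", "rs2470893"))
  m6 <- select_model(set, "6-SNP")
  expect_equal(nrow(m6$entries), 6L)
  expect_false(any(c("rs1481012", "rs6265") %in% m6$entries$snp_id))
  m8 <- select_model(set, "8-SNP")
  expect_true(all(m2$entries$snp_id %in% m6$entries$snp_id))
  expect_true(all(m6$entries$snp_id %in% m8$entries$snp_id))

  smaller <- instrument_set(set$entries[set$entries$snp_id != "rs17685", ])
  expect_error(select_model(smaller, "6-SNP"), "rs17685")
})

test_that("instrument sets serialize to JSON with provenance", {
  js <- instrument_set_json(select_model(smoking_set(), "2-SNP"))
  doc <- jsonlite::fromJSON(js)
  expect_equal(doc$model_label, "2-SNP")
  expect_equal(nrow(doc$entries), 2L)
  expect_equal(doc$provenance$package, "mrkin")
})
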