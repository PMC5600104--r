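# In-code copies of the published per-SNP summary statistics used as
# oracles, and small builders shared across test files.

coffee_exposure <- function() {
  variant_assoc(
    snp_id = c("rs1260326", "rs1481012", "rs4410790", "rs7800944",
               "rs17685", "rs6265", "rs2470893", "rs9902453"),
    effect_allele = c("C", "A", "C", "C", "A", "C", "T", "G"),
    other_allele = c("T", "G", "T", "T", "G", "T", "C", "A"),
    beta = c(0.03, 0.03, 0.05, 0.06, 0.05, 0.03, 0.09, 0.03),
    se = c(0.01, 0.02, 0.01, 0.02, 0.01, 0.01, 0.01, 0.01),
    phenotype = "exposure"
  )
}

smoking_outcome <- function() {
  variant_assoc(
    snp_id = c("rs1260326", "rs1481012", "rs4410790", "rs7800944",
               "rs17685", "rs6265", "rs2470893", "rs9902453"),
    effect_allele = c("C", "A", "C", "C", "A", "C", "T", "G"),
    other_allele = c("T", "G", "T", "T", "G", "T", "C", "A"),
    beta = c(-0.0821, 0.0297, -0.0679, -0.0881, 0.1387, 0.0465,
             -0.2125, -0.0642),
    se = c(0.0826, 0.1355, 0.0906, 0.0973, 0.1377, 0.1045, 0.0964,
           0.0817),
    phenotype = "outcome"
  )
}

smoking_set <- function() harmonize(coffee_exposure(), smoking_outcome())

# minimal wald_estimate table from raw vectors
wald_table <- function(ratio, se, snp_id = paste0("rs", seq_along(ratio))) {
  out <- data.frame(snp_id = snp_id, ratio = ratio, se = se,
                    weight = se^-2, stringsAsFactors = FALSE)
  class(out) <- c("wald_estimate", "data.frame")
  out
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
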