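#' Construct a table of variant-phenotype associations
#'
#' A variant association table holds one row per SNP with its effect and
#' other alleles and the per-effect-allele regression coefficient (beta)
#' and standard error against a single phenotype. It is the unit of
#' exchange for GWAS summary statistics: exposure tables carry e.g. cups
#' of coffee per day per allele, outcome tables cigarettes per day or SD
#' units of a biomarker per allele.
#'
#' @param snp_id character vector of rsIDs (non-empty, unique).
#' @param effect_allele,other_allele single-base allele codes (A/C/G/T);
#'   `beta` is expressed per copy of `effect_allele`.
#' @param beta,se numeric coefficient and its standard error (`se > 0`).
#' @param phenotype either `"exposure"` or `"outcome"`.
#' @param gene optional gene labels.
#' @param n optional per-SNP sample sizes.
#' @return A data frame of class `"variant_assoc"` with columns
#'   `snp_id`, `gene`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `phenotype`, `n`.
#' @export
variant_assoc <- function(snp_id, effect_allele, other_allele, beta, se,
                          phenotype = c("exposure", "outcome"),
                          gene = NA_character_, n = NA_real_) {
  phenotype <- match.arg(phenotype)
  snp_id <- as.character(snp_id)
  effect_allele <- toupper(as.character(effect_allele))
  other_allele <- toupper(as.character(other_allele))
  beta <- as.numeric(beta)
  se <- as.numeric(se)
  m <- length(snp_id)
  stopifnot(length(effect_allele) == m, length(other_allele) == m,
            length(beta) == m, length(se) == m)
  if (any(!nzchar(snp_id)))
    stop("snp_id must be non-empty", call. = FALSE)
  if (anyDuplicated(snp_id))
    stop("duplicate snp_id: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "),
         call. = FALSE)
  bad_allele <- !(effect_allele %in% c("A", "C", "G", "T")) |
    !(other_allele %in% c("A", "C", "G", "T"))
  if (any(bad_allele))
    stop("invalid allele code for: ",
         paste(snp_id[bad_allele], collapse = ", "), call. = FALSE)
  if (any(effect_allele == other_allele))
    stop("effect and other allele identical for: ",
         paste(snp_id[effect_allele == other_allele], collapse = ", "),
         call. = FALSE)
  bad_se <- !is.finite(se) | se <= 0
  if (any(bad_se))
    stop("se must be finite and > 0; offending rows: ",
         paste(which(bad_se), collapse = ", "), call. = FALSE)
  if (any(!is.finite(beta)))
    stop("beta must be finite", call. = FALSE)
  out <- data.frame(
    snp_id = snp_id,
    gene = rep_len(as.character(gene), m),
    effect_allele = effect_allele,
    other_allele = other_allele,
    beta = beta,
    se = se,
    phenotype = rep_len(phenotype, m),
    n = rep_len(as.numeric(n), m),
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_assoc", "data.frame")
  out
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated file with header columns `snp_id`, `gene`,
#' `effect_allele`, `other_allele`, `beta`, `se` (extra columns are
#' ignored) into a validated [variant_assoc()] table. Numeric fields are
#' parsed at full precision; no rounding is applied.
#'
#' @param path path to a tab-separated file with the required header.
#' @param phenotype tag recorded on every row: `"exposure"` or
#'   `"outcome"`.
#' @return A `variant_assoc` data frame, rows in file order; a file with
#'   a header but no data rows yields a zero-row table.
#' @export
read_summary_stats <- function(path, phenotype = c("exposure", "outcome")) {
  phenotype <- match.arg(phenotype)
  if (!file.exists(path))
    stop("summary-statistics file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  gene <- if ("gene" %in% names(raw)) raw$gene else NA_character_
  if (nrow(raw) == 0L) {
    out <- variant_assoc(character(), character(), character(),
                         numeric(), numeric(), phenotype)
    return(out)
  }
  beta <- suppressWarnings(as.numeric(raw$beta))
  se <- suppressWarnings(as.numeric(raw$se))
  bad <- which(is.na(beta) | is.na(se) | se <= 0)
  if (length(bad))
    stop("non-numeric or invalid beta/se at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  variant_assoc(raw$snp_id, raw$effect_allele, raw$other_allele,
                beta, se, phenotype, gene = gene)
}

#' @export
print.variant_assoc <- function(x, ...) {
  cat(sprintf("Variant associations (%s): %d SNP(s)\n",
              if (nrow(x)) x$phenotype[1] else "empty", nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

is_palindromic <- function(effect, other) {
  (effect == "A" & other == "T") | (effect == "T" & other == "A") |
    (effect == "C" & other == "G") | (effect == "G" & other == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two summary-association tables onto a shared effect allele so
#' that each SNP's exposure and outcome betas refer to the same allele.
#' SNPs whose alleles match exactly are kept as-is; SNPs whose effect
#' and other alleles are swapped between the two sources have the
#' outcome beta sign flipped (and alleles relabelled); SNPs whose
#' alleles cannot be reconciled raise an error. Palindromic SNPs (A/T or
#' C/G) are ambiguous with respect to strand and are rejected under the
#' default `"strict"` policy.
#'
#' Outcome SNPs absent from the exposure table are ignored (with a
#' message); exposure SNPs absent from the outcome table are an error.
#'
#' @param exposure,outcome `variant_assoc` tables (see
#'   [read_summary_stats()]).
#' @param palindromic `"strict"` (reject palindromic SNPs with an error)
#'   or `"allow"` (keep them, assuming both sources report the same
#'   strand).
#' @param model_label label stored on the returned set.
#' @param ld_r2 optional symmetric matrix of pairwise r-squared values
#'   with dimnames covering the harmonized SNPs (used by [ld_prune()]).
#' @return An object of class `"instrument_set"`: a list with `entries`
#'   (data frame `snp_id`, `effect_allele`, `other_allele`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`), `model_label` and optional `ld_r2`.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic = c("strict", "allow"),
                      model_label = "custom", ld_r2 = NULL) {
  palindromic <- match.arg(palindromic)
  stopifnot(inherits(exposure, "variant_assoc"),
            inherits(outcome, "variant_assoc"))
  missing_snps <- setdiff(exposure$snp_id, outcome$snp_id)
  if (length(missing_snps))
    stop("exposure SNP(s) absent from outcome table: ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  extra <- setdiff(outcome$snp_id, exposure$snp_id)
  if (length(extra))
    message("ignoring ", length(extra),
            " outcome-only SNP(s): ", paste(extra, collapse = ", "))
  oi <- match(exposure$snp_id, outcome$snp_id)
  ea_x <- exposure$effect_allele; oa_x <- exposure$other_allele
  ea_y <- outcome$effect_allele[oi]; oa_y <- outcome$other_allele[oi]
  pal <- is_palindromic(ea_x, oa_x)
  if (palindromic == "strict" && any(pal))
    stop("palindromic SNP(s) under strict policy: ",
         paste(exposure$snp_id[pal], collapse = ", "), call. = FALSE)
  same <- ea_x == ea_y & oa_x == oa_y
  swapped <- ea_x == oa_y & oa_x == ea_y
  bad <- !(same | swapped)
  if (any(bad))
    stop("irreconcilable alleles for SNP(s): ",
         paste(exposure$snp_id[bad], collapse = ", "), call. = FALSE)
  beta_y <- outcome$beta[oi]
  beta_y[swapped] <- -beta_y[swapped]
  entries <- data.frame(
    snp_id = exposure$snp_id,
    effect_allele = ea_x,
    other_allele = oa_x,
    beta_x = exposure$beta,
    se_x = exposure$se,
    beta_y = beta_y,
    se_y = outcome$se[oi],
    stringsAsFactors = FALSE
  )
  instrument_set(entries, model_label = model_label, ld_r2 = ld_r2)
}

#' Construct an instrument set from harmonized entries
#'
#' @param entries data frame with columns `snp_id`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y` (allele columns optional), one row per SNP.
#' @param model_label one of `"8-SNP"`, `"6-SNP"`, `"2-SNP"` or
#'   `"custom"`.
#' @param ld_r2 optional symmetric pairwise r-squared matrix.
#' @return An object of class `"instrument_set"`.
#' @export
instrument_set <- function(entries, model_label = "custom", ld_r2 = NULL) {
  needed <- c("snp_id", "beta_x", "se_x", "beta_y", "se_y")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols))
    stop("instrument entries missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(entries$snp_id))
    stop("duplicate snp_id in instrument set", call. = FALSE)
  if (any(entries$se_x <= 0) || any(entries$se_y <= 0))
    stop("all standard errors must be > 0", call. = FALSE)
  model_label <- match.arg(model_label,
                           c("8-SNP", "6-SNP", "2-SNP", "custom"))
  if (!is.null(ld_r2)) {
    ld_r2 <- as.matrix(ld_r2)
    if (is.null(dimnames(ld_r2)) ||
        !all(entries$snp_id %in% rownames(ld_r2)) ||
        !all(entries$snp_id %in% colnames(ld_r2)))
      stop("ld_r2 must have dimnames covering every instrument SNP",
           call. = FALSE)
  }
  structure(list(entries = entries, model_label = model_label,
                 ld_r2 = ld_r2),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set [%s]: %d SNP(s)\n",
              x$model_label, nrow(x$entries)))
  print.data.frame(x$entries, row.names = FALSE, ...)
  invisible(x)
}

#' Prune an instrument set for linkage disequilibrium
#'
#' Removes SNPs until every remaining pair has r-squared below
#' `threshold`. Pairs are scanned in sorted `snp_id` order; within an
#' offending pair the SNP to drop is chosen uniformly at random under
#' the supplied seed, so the result is reproducible.
#'
#' @param set an `instrument_set` whose `ld_r2` matrix covers all pairs.
#' @param threshold r-squared cutoff in (0, 1]; pairs at or above it are
#'   in LD.
#' @param seed integer seed driving the random within-pair choice.
#' @return The pruned `instrument_set` (ld_r2 subset accordingly).
#' @export
ld_prune <- function(set, threshold, seed) {
  stopifnot(inherits(set, "instrument_set"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  snps <- sort(set$entries$snp_id)
  if (length(snps) < 2L) return(set)
  if (is.null(set$ld_r2))
    stop("ld_prune requires an ld_r2 matrix on the instrument set",
         call. = FALSE)
  r2 <- set$ld_r2
  pairs <- utils::combn(snps, 2L)
  miss <- apply(pairs, 2L, function(p) is.na(r2[p[1L], p[2L]]))
  if (any(miss)) {
    p <- pairs[, which(miss)[1L]]
    stop("missing r-squared for pair: ", p[1L], " / ", p[2L],
         call. = FALSE)
  }
  keep <- snps
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  repeat {
    if (length(keep) < 2L) break
    pr <- utils::combn(keep, 2L)
    vals <- apply(pr, 2L, function(p) r2[p[1L], p[2L]])
    offending <- which(vals >= threshold)
    if (!length(offending)) break
    p <- pr[, offending[1L]]
    drop <- p[sample.int(2L, 1L)]
    keep <- setdiff(keep, drop)
  }
  entries <- set$entries[set$entries$snp_id %in% keep, , drop = FALSE]
  rownames(entries) <- NULL
  instrument_set(entries, model_label = set$model_label,
                 ld_r2 = set$ld_r2[entries$snp_id, entries$snp_id,
                                   drop = FALSE])
}

#' SNP membership of the coffee-consumption instrument models
#'
#' Three nested instrument models for coffee consumption (cups/day) are
#' supported: the full eight-SNP genome-wide-significant set, a six-SNP
#' subset with stronger replication evidence, and a conservative
#' two-SNP subset restricted to loci with a direct role in caffeine
#' metabolism (AHR, CYP1A1).
#'
#' @param model one of `"8-SNP"`, `"6-SNP"`, `"2-SNP"`.
#' @return Character vector of rsIDs belonging to the model.
#' @export
model_snps <- function(model = c("8-SNP", "6-SNP", "2-SNP")) {
  model <- match.arg(model)
  full <- c("rs1260326", "rs1481012", "rs4410790", "rs7800944",
            "rs17685", "rs6265", "rs2470893", "rs9902453")
  switch(model,
         "8-SNP" = full,
         "6-SNP" = setdiff(full, c("rs1481012", "rs6265")),
         "2-SNP" = c("rs4410790", "rs2470893"))
}

#' Subset an instrument set to a named model
#'
#' @param set an `instrument_set` containing at least the model's SNPs.
#' @param model one of `"8-SNP"`, `"6-SNP"`, `"2-SNP"`.
#' @return The subset `instrument_set`, relabelled with the model name.
#' @export
select_model <- function(set, model = c("8-SNP", "6-SNP", "2-SNP")) {
  model <- match.arg(model)
  stopifnot(inherits(set, "instrument_set"))
  wanted <- model_snps(model)
  absent <- setdiff(wanted, set$entries$snp_id)
  if (length(absent))
    stop("SNP(s) required by the ", model, " model are absent: ",
         paste(absent, collapse = ", "), call. = FALSE)
  entries <- set$entries[set$entries$snp_id %in% wanted, , drop = FALSE]
  rownames(entries) <- NULL
  ld <- if (is.null(set$ld_r2)) NULL else
    set$ld_r2[entries$snp_id, entries$snp_id, drop = FALSE]
  instrument_set(entries, model_label = model, ld_r2 = ld)
}

#' Serialize an instrument set to JSON
#'
#' @param set an `instrument_set`.
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
instrument_set_json <- function(set, path = NULL) {
  stopifnot(inherits(set, "instrument_set"))
  doc <- list(
    model_label = set$model_label,
    entries = set$entries,
    provenance = list(
      package = "mrkin",
      version = as.character(utils::packageVersion("mrkin")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
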