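# Canonical column schema for GWAS summary statistics.
.canonical_cols <- c("SNP", "effect_allele", "other_allele", "eaf",
                     "beta", "se", "pval", "n")

.valid_bases <- c("A", "C", "G", "T")

#' Construct a table of GWAS summary-statistic records
#'
#' One row per SNP-trait association. Alleles are upper-cased and validated
#' against A/C/G/T; basic invariants (distinct alleles, `eaf` in \[0, 1\],
#' positive `se`, `pval` in (0, 1\]) are enforced. Duplicated SNP ids are an
#' error: summary files are expected to be pre-aggregated, one row per rsID.
#'
#' @param snp character rsIDs.
#' @param effect_allele,other_allele single bases (A/C/G/T), any case.
#' @param eaf effect-allele frequency in \[0, 1\].
#' @param beta per-allele effect (log-odds for binary traits).
#' @param se standard error of `beta`, strictly positive.
#' @param pval association p-value in (0, 1\].
#' @param n sample size.
#' @param trait free-text trait label, recycled.
#' @return A `data.frame` with class `gwas_summary`.
#' @export
#' @examples
#' gwas_records("rs1", "T", "C", 0.3, 0.05, 0.01, 1e-12, 10000, "pth")
gwas_records <- function(snp, effect_allele, other_allele, eaf, beta, se,
                         pval, n, trait = "") {
  df <- data.frame(
    SNP = as.character(snp),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    eaf = as.numeric(eaf),
    beta = as.numeric(beta),
    se = as.numeric(se),
    pval = as.numeric(pval),
    n = as.numeric(n),
    trait = rep_len(as.character(trait), length(snp)),
    stringsAsFactors = FALSE
  )
  validate_gwas_records(df)
}

#' Validate a GWAS summary table's invariants
#'
#' @param df a data.frame carrying the canonical columns.
#' @return `df` with class `gwas_summary`, invisibly checked.
#' @export
validate_gwas_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.canonical_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$SNP)) {
    dup <- unique(df$SNP[duplicated(df$SNP)])
    stop("duplicate SNP ids in summary table: ", paste(dup, collapse = ", "))
  }
  bad_allele <- !(df$effect_allele %in% .valid_bases) |
    !(df$other_allele %in% .valid_bases)
  if (any(bad_allele)) {
    stop("invalid allele codes for: ", paste(df$SNP[bad_allele], collapse = ", "))
  }
  if (any(df$effect_allele == df$other_allele)) {
    stop("effect and other allele identical for: ",
         paste(df$SNP[df$effect_allele == df$other_allele], collapse = ", "))
  }
  if (any(df$eaf < 0 | df$eaf > 1, na.rm = TRUE)) stop("eaf outside [0, 1]")
  if (any(df$se <= 0)) stop("non-positive standard errors")
  if (any(df$pval <= 0 | df$pval > 1)) stop("p-values outside (0, 1]")
  class(df) <- unique(c("gwas_summary", class(df)))
  df
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Expects a header row. Columns may be renamed through `column_map`, a named
#' character vector mapping canonical names (`SNP`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) to the file's column
#' names. Rows with missing beta, se, or alleles are dropped with a message;
#' non-numeric text in a numeric column is an error.
#'
#' @param path file path to a TSV with header.
#' @param column_map named character vector, canonical -> file column. `NULL`
#'   means the file already uses canonical names.
#' @param trait trait label attached to every record.
#' @return A `gwas_summary` data.frame.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    missing_map <- setdiff(unname(column_map), names(raw))
    if (length(missing_map) > 0L) {
      stop("mapped columns absent from file: ",
           paste(missing_map, collapse = ", "))
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(.canonical_cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(gwas_records(character(), character(), character(), numeric(),
                        numeric(), numeric(), numeric(), numeric(), trait))
  }
  num_cols <- c("eaf", "beta", "se", "pval", "n")
  for (col in num_cols) {
    txt <- trimws(raw[[col]])
    val <- suppressWarnings(as.numeric(txt))
    bad <- is.na(val) & !is.na(txt) & txt != "" & toupper(txt) != "NA"
    if (any(bad)) {
      stop("non-numeric value in column '", col, "' at data row ",
           which(bad)[1L], ": '", txt[which(bad)[1L]], "'")
    }
    raw[[col]] <- val
  }
  keep <- !is.na(raw$beta) & !is.na(raw$se) &
    trimws(raw$effect_allele) != "" & trimws(raw$other_allele) != ""
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped for missing beta/se/alleles")
    raw <- raw[keep, , drop = FALSE]
  }
  gwas_records(trimws(raw$SNP), trimws(raw$effect_allele),
               trimws(raw$other_allele), raw$eaf, raw$beta, raw$se,
               raw$pval, raw$n, trait)
}

#' Write GWAS summary statistics as TSV
#'
#' @param records a `gwas_summary` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  utils::write.table(records[, c(.canonical_cols, "trait")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a pairwise LD table
#'
#' Stores r-squared for unordered SNP pairs. Lookups are symmetric; a SNP
#' with itself has r-squared 1 and an absent pair is treated as 0.
#'
#' @param snp_a,snp_b character vectors of SNP ids.
#' @param r2 numeric r-squared values in \[0, 1\].
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(snp_a = character(), snp_b = character(), r2 = numeric()) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_b) == length(r2))
  if (any(r2 < 0 | r2 > 1)) stop("r2 outside [0, 1]")
  df <- data.frame(snp_a = as.character(snp_a), snp_b = as.character(snp_b),
                   r2 = as.numeric(r2), stringsAsFactors = FALSE)
  structure(df, class = c("ld_table", "data.frame"))
}

#' Read a three-column LD table (snp_a, snp_b, r2) from TSV
#'
#' @param path file path.
#' @return An `ld_table`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t")
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(raw))) {
    stop("LD table requires columns: ", paste(need, collapse = ", "))
  }
  ld_table(raw$snp_a, raw$snp_b, raw$r2)
}

#' Look up pairwise LD r-squared
#'
#' @param ld an `ld_table`.
#' @param a,b SNP ids (vectorised over pairs of equal length).
#' @return numeric r-squared; 1 for a SNP with itself, 0 for unlisted pairs.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"), length(a) == length(b))
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  lut <- stats::setNames(ld$r2, key(ld$snp_a, ld$snp_b))
  out <- unname(lut[key(as.character(a), as.character(b))])
  out[is.na(out)] <- 0
  out[as.character(a) == as.character(b)] <- 1
  out
}

#' Select genome-wide-significant instruments
#'
#' Keeps records with p strictly below the threshold (conventionally
#' 5e-8), preserving input order.
#'
#' @param records a `gwas_summary` data.frame.
#' @param p_threshold significance threshold; comparison is strict (<).
#' @return The filtered `gwas_summary`.
#' @export
select_instruments <- function(records, p_threshold = 5e-8) {
  stopifnot(nrow(records) > 0L)
  out <- records[records$pval < p_threshold, , drop = FALSE]
  if (nrow(out) == 0L) message("no records pass p < ", p_threshold)
  out
}

#' Greedy LD pruning of instruments
#'
#' Standard clumping semantics: records are visited in order of ascending
#' p-value (ties broken by lexicographic SNP id) and accepted only if their
#' r-squared with every already-accepted SNP is below the threshold. The
#' retained set is therefore pairwise independent at the threshold.
#'
#' @param records a `gwas_summary` data.frame with p-values.
#' @param ld an `ld_table`; pairs not listed count as r-squared 0.
#' @param r2_threshold LD r-squared cut-off (default 0.01).
#' @return The pruned `gwas_summary`, original row order preserved.
#' @export
ld_prune <- function(records, ld, r2_threshold = 0.01) {
  if (nrow(records) == 0L) return(records)
  ord <- order(records$pval, records$SNP)
  accepted <- character()
  for (i in ord) {
    snp <- records$SNP[i]
    if (length(accepted) == 0L ||
        all(ld_r2(ld, rep(snp, length(accepted)), accepted) < r2_threshold)) {
      accepted <- c(accepted, snp)
    }
  }
  records[records$SNP %in% accepted, , drop = FALSE]
}

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) SNP carries complementary alleles, so
#' the pair reads the same on both strands: A/T or C/G.
#'
#' @param effect_allele,other_allele single bases, vectorised.
#' @return logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  if (any(!(ea %in% .valid_bases) | !(oa %in% .valid_bases))) {
    stop("invalid base in allele pair")
  }
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Complement alleles to the opposite strand
#' @param alleles character vector of bases.
#' @return complemented bases.
#' @export
complement_alleles <- function(alleles) {
  chartr("ACGT", "TGCA", toupper(alleles))
}

#' Flip a record's effect allele
#'
#' Swaps effect and other allele, negates beta and replaces eaf by 1 - eaf.
#' Applying the flip twice restores the original record.
#'
#' @param records a `gwas_summary` data.frame.
#' @return The flipped `gwas_summary`.
#' @export
flip_effect_allele <- function(records) {
  tmp <- records$effect_allele
  records$effect_allele <- records$other_allele
  records$other_allele <- tmp
  records$beta <- -records$beta
  records$eaf <- 1 - records$eaf
  records
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome records onto the exposure's effect allele, matching on
#' SNP id. Outcome records with swapped alleles have beta negated and eaf
#' reflected; non-palindromic records matching only as strand complements
#' are complemented first. Palindromic SNPs are aligned by allele-frequency
#' agreement (flip when the two frequencies sit on opposite sides of 0.5)
#' unless either frequency falls in the intermediate band
#' \[`intermediate_eaf`, 1 - `intermediate_eaf`\], where strand cannot be
#' resolved and the SNP is excluded. Non-concordant allele sets are
#' excluded. Exclusions and unmatched SNPs are reported via messages and in
#' the `"dropped"` attribute.
#'
#' @param exposure,outcome `gwas_summary` data.frames; SNP ids must be
#'   unique within each.
#' @param intermediate_eaf lower edge of the ambiguous frequency band
#'   (default 0.42, i.e. band \[0.42, 0.58\]).
#' @return A data.frame of class `harmonized_instruments` with columns
#'   `SNP`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`,
#'   `eaf_out`, `palindromic`.
#' @export
harmonize <- function(exposure, outcome, intermediate_eaf = 0.42) {
  exposure <- validate_gwas_records(as.data.frame(exposure))
  outcome <- validate_gwas_records(as.data.frame(outcome))
  shared <- intersect(exposure$SNP, outcome$SNP)
  unmatched <- setdiff(union(exposure$SNP, outcome$SNP), shared)
  if (length(unmatched) > 0L) {
    message(length(unmatched), " SNP(s) absent from one table dropped: ",
            paste(unmatched, collapse = ", "))
  }
  band_lo <- min(intermediate_eaf, 1 - intermediate_eaf)
  band_hi <- max(intermediate_eaf, 1 - intermediate_eaf)

  rows <- vector("list", length(shared))
  dropped <- character()
  drop_reason <- character()
  for (k in seq_along(shared)) {
    snp <- shared[k]
    ex <- exposure[exposure$SNP == snp, ]
    ou <- outcome[outcome$SNP == snp, ]
    pal <- is_palindromic(ex$effect_allele, ex$other_allele)

    aligned <- NULL
    if (ou$effect_allele == ex$effect_allele &&
        ou$other_allele == ex$other_allele) {
      aligned <- ou
    } else if (ou$effect_allele == ex$other_allele &&
               ou$other_allele == ex$effect_allele) {
      aligned <- flip_effect_allele(ou)
    } else if (!pal) {
      # strand mismatch: try the complementary representation
      oc <- ou
      oc$effect_allele <- complement_alleles(ou$effect_allele)
      oc$other_allele <- complement_alleles(ou$other_allele)
      if (oc$effect_allele == ex$effect_allele &&
          oc$other_allele == ex$other_allele) {
        aligned <- oc
      } else if (oc$effect_allele == ex$other_allele &&
                 oc$other_allele == ex$effect_allele) {
        aligned <- flip_effect_allele(oc)
      }
    }
    if (is.null(aligned)) {
      dropped <- c(dropped, snp)
      drop_reason <- c(drop_reason, "non-concordant alleles")
      next
    }
    if (pal) {
      # strand is ambiguous: resolve via frequency agreement, impossible
      # when either frequency is near 0.5
      if ((ex$eaf >= band_lo && ex$eaf <= band_hi) ||
          (aligned$eaf >= band_lo && aligned$eaf <= band_hi)) {
        dropped <- c(dropped, snp)
        drop_reason <- c(drop_reason, "palindromic with intermediate EAF")
        next
      }
      if ((ex$eaf < 0.5) != (aligned$eaf < 0.5)) {
        aligned$beta <- -aligned$beta
        aligned$eaf <- 1 - aligned$eaf
      }
    }
    rows[[k]] <- data.frame(
      SNP = snp, beta_exp = ex$beta, se_exp = ex$se,
      beta_out = aligned$beta, se_out = aligned$se,
      eaf_exp = ex$eaf, eaf_out = aligned$eaf,
      palindromic = pal, stringsAsFactors = FALSE
    )
  }
  if (length(dropped) > 0L) {
    message(length(dropped), " SNP(s) excluded in harmonization: ",
            paste(paste0(dropped, " (", drop_reason, ")"), collapse = "; "))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(SNP = character(), beta_exp = numeric(),
                      se_exp = numeric(), beta_out = numeric(),
                      se_out = numeric(), eaf_exp = numeric(),
                      eaf_out = numeric(), palindromic = logical(),
                      stringsAsFactors = FALSE)
  }
  # keep exposure-table order
  out <- out[order(match(out$SNP, exposure$SNP)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(SNP = dropped, reason = drop_reason,
                                     stringsAsFactors = FALSE)
  class(out) <- unique(c("harmonized_instruments", class(out)))
  out
}

#' Assemble harmonized instruments directly from aligned effect columns
#'
#' Convenience constructor used when exposure and outcome effects are
#' already expressed on a shared effect allele (e.g. a published
#' instrument table).
#'
#' @param snp SNP ids.
#' @param beta_exp,se_exp exposure effect and its SE.
#' @param beta_out,se_out outcome effect and its SE on the same allele.
#' @param eaf_exp,eaf_out aligned effect-allele frequencies.
#' @param palindromic logical flag.
#' @return A `harmonized_instruments` data.frame.
#' @export
harmonized_instruments <- function(snp, beta_exp, se_exp, beta_out, se_out,
                                   eaf_exp = NA_real_, eaf_out = NA_real_,
                                   palindromic = FALSE) {
  stopifnot(all(se_exp > 0), all(se_out > 0))
  df <- data.frame(SNP = as.character(snp), beta_exp = beta_exp,
                   se_exp = se_exp, beta_out = beta_out, se_out = se_out,
                   eaf_exp = rep_len(eaf_exp, length(snp)),
                   eaf_out = rep_len(eaf_out, length(snp)),
                   palindromic = rep_len(palindromic, length(snp)),
                   stringsAsFactors = FALSE)
  class(df) <- unique(c("harmonized_instruments", class(df)))
  df
}
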