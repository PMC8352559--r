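#' Configuration for simulated two-sample summary statistics
#'
#' Defaults describe a well-powered two-sample design with moderately
#' strong instruments: 50 SNPs with per-allele exposure effects of
#' uniform magnitude 0.02-0.08 (the range seen for serum-biomarker
#' instruments), exposure and outcome samples of 50,000, allele
#' frequencies in 0.1-0.9, a protective causal slope of -0.4 on the
#' log-odds scale, and no pleiotropy.
#'
#' @param n_snps number of instruments L.
#' @param true_beta causal slope on the log-odds scale.
#' @param gamma_range low/high bounds of the uniform magnitude of true
#'   instrument effects (drawn positive).
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct
#'   effects) or `"directional"` (mean `pleio_mean`).
#' @param pleio_mean mean pleiotropic effect under directional mode.
#' @param pleio_sd spread of pleiotropic effects.
#' @param frac_invalid fraction of SNPs receiving a pleiotropic effect.
#' @param n_exp,n_out sample sizes driving the standard errors.
#' @param eaf_range bounds for simulated effect-allele frequencies.
#' @param seed integer seed; identical seeds reproduce exactly.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_snps = 50, true_beta = -0.4,
                             gamma_range = c(0.02, 0.08),
                             pleiotropy_mode = c("none", "balanced",
                                                 "directional"),
                             pleio_mean = 0.02, pleio_sd = 0.01,
                             frac_invalid = 0, n_exp = 50000, n_out = 50000,
                             eaf_range = c(0.1, 0.9), seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, frac_invalid >= 0, frac_invalid <= 1,
            length(gamma_range) == 2L, gamma_range[1] > 0,
            diff(gamma_range) >= 0, length(eaf_range) == 2L,
            eaf_range[1] > 0, eaf_range[2] < 1, n_exp > 2, n_out > 2)
  structure(list(n_snps = n_snps, true_beta = true_beta,
                 gamma_range = gamma_range,
                 pleiotropy_mode = pleiotropy_mode,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 frac_invalid = frac_invalid, n_exp = n_exp, n_out = n_out,
                 eaf_range = eaf_range, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Non-palindromic allele pairs cycled over simulated SNPs.
.nonpal_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                        ncol = 2, byrow = TRUE)

#' Simulate a two-sample GWAS summary dataset with known truth
#'
#' Per SNP j: an allele frequency f_j and a strictly positive true
#' instrument effect gamma_j are drawn; a direct (pleiotropic) outcome
#' effect alpha_j is 0 for valid SNPs and otherwise drawn per the
#' configured mode; standard errors follow the standard per-allele scaling
#' for a unit-variance phenotype, `1 / sqrt(2 f (1 - f) n)`; observed
#' effects are the truth plus normal noise at those standard errors, with
#' the outcome mean `true_beta * gamma_j + alpha_j`. Alleles are assigned
#' non-palindromic so harmonization is unambiguous; to exercise effect
#' orientation downstream, a random half of the SNPs is reported on the
#' opposite effect allele (both observed effects negated, frequency
#' reflected) in both tables.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_dataset`: `exposure` and `outcome`
#'   (`gwas_summary` tables) and `truth` (data.frame with per-SNP `gamma`,
#'   `alpha`, the flip indicator and `true_beta`).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- config$n_snps
  withr::with_seed(config$seed, {
    f <- stats::runif(L, config$eaf_range[1], config$eaf_range[2])
    gamma <- stats::runif(L, config$gamma_range[1], config$gamma_range[2])
    alpha <- numeric(L)
    invalid <- stats::runif(L) < config$frac_invalid
    if (config$pleiotropy_mode == "balanced") {
      alpha[invalid] <- stats::rnorm(sum(invalid), 0, config$pleio_sd)
    } else if (config$pleiotropy_mode == "directional") {
      alpha[invalid] <- stats::rnorm(sum(invalid), config$pleio_mean,
                                     config$pleio_sd)
    }
    se_exp <- 1 / sqrt(2 * f * (1 - f) * config$n_exp)
    se_out <- 1 / sqrt(2 * f * (1 - f) * config$n_out)
    g_hat <- stats::rnorm(L, gamma, se_exp)
    G_hat <- stats::rnorm(L, config$true_beta * gamma + alpha, se_out)
    flip <- stats::runif(L) < 0.5

    pair <- .nonpal_pairs[(seq_len(L) - 1L) %% nrow(.nonpal_pairs) + 1L, ,
                          drop = FALSE]
    snp <- sprintf("snp%04d", seq_len(L))
    eaf <- ifelse(flip, 1 - f, f)
    ea <- ifelse(flip, pair[, 2], pair[, 1])
    oa <- ifelse(flip, pair[, 1], pair[, 2])
    sgn <- ifelse(flip, -1, 1)
    p_exp <- 2 * stats::pnorm(-abs(g_hat / se_exp))
    p_out <- 2 * stats::pnorm(-abs(G_hat / se_out))
    exposure <- gwas_records(snp, ea, oa, eaf, sgn * g_hat, se_exp,
                             pmax(p_exp, .Machine$double.xmin),
                             config$n_exp, "exposure")
    outcome <- gwas_records(snp, ea, oa, eaf, sgn * G_hat, se_out,
                            pmax(p_out, .Machine$double.xmin),
                            config$n_out, "outcome")
    truth <- data.frame(SNP = snp, gamma = gamma, alpha = alpha,
                        flipped = flip, true_beta = config$true_beta,
                        stringsAsFactors = FALSE)
    structure(list(exposure = exposure, outcome = outcome, truth = truth),
              class = "synthetic_dataset")
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits exposure and outcome TSVs in the canonical summary-statistic
#' schema plus a `truth.json` with the generative parameters.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_summary_stats(dataset$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(dataset$outcome, file.path(dir, "outcome.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Five serum-PTH instruments as harmonized input
#'
#' The five independent genome-wide-significant SNPs for serum parathyroid
#' hormone, with their effects on PTH (exposure, N = 29,155) and on
#' osteoarthritis (outcome log-odds, N = 455,221) already expressed on a
#' shared effect allele. This is the worked example used throughout the
#' package documentation and tests.
#'
#' @return A `harmonized_instruments` data.frame with five rows.
#' @export
#' @examples
#' ivw(make_fixture_table2())
make_fixture_table2 <- function() {
  harmonized_instruments(
    snp = c("rs6127099", "rs4074995", "rs219779", "rs4443100", "rs73186030"),
    beta_exp = c(0.07, 0.03, 0.04, 0.02, 0.03),
    se_exp = rep(0.003, 5),
    beta_out = c(-0.0162, -0.016, -0.0157, -0.0224, -0.0382),
    se_out = c(0.0086, 0.0086, 0.0086, 0.0083, 0.0114),
    eaf_exp = c(0.34, 0.71, 0.75, 0.32, 0.14),
    eaf_out = c(0.34, 0.71, 0.75, 0.32, 0.14),
    palindromic = c(TRUE, FALSE, FALSE, TRUE, FALSE)
  )
}

#' Six lead PTH SNPs for LD-pruning demonstrations
#'
#' The five instruments above plus rs35194449 (p = 1.8e-10), which is in
#' linkage disequilibrium with rs6127099 (r-squared 0.38) and is removed
#' by pruning at r-squared < 0.01. Only rs35194449's p-value and its LD
#' with rs6127099 are published; its beta, SE and EAF here are synthetic
#' placeholders (they never influence pruning, which uses p-values and LD
#' only).
#'
#' @return A list with `records` (six-row `gwas_summary` exposure table)
#'   and `ld` (an `ld_table` with the single known pair).
#' @export
make_fixture_lead6 <- function() {
  five <- make_fixture_table2()
  records <- gwas_records(
    snp = c(five$SNP, "rs35194449"),
    effect_allele = c("T", "G", "G", "G", "T", "A"),
    other_allele = c("A", "A", "A", "C", "C", "G"),
    eaf = c(five$eaf_exp, 0.30),
    beta = c(five$beta_exp, 0.03),
    se = c(five$se_exp, 0.003),
    pval = c(2.4e-72, 3.3e-23, 8.9e-22, 4.1e-11, 1.2e-9, 1.8e-10),
    n = 29155, trait = "pth"
  )
  list(records = records,
       ld = ld_table("rs6127099", "rs35194449", 0.38))
}
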