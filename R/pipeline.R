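#' Build a pipeline run configuration
#'
#' @param exposure path to the exposure summary-statistics TSV.
#' @param outcome path to the outcome summary-statistics TSV.
#' @param ld optional path to a three-column LD TSV (snp_a, snp_b, r2).
#' @param exposure_columns,outcome_columns optional named character
#'   vectors remapping canonical column names to file columns.
#' @param p_threshold instrument-selection p threshold (strict <).
#' @param r2_threshold LD pruning r-squared threshold.
#' @param intermediate_eaf lower edge of the ambiguous palindrome band.
#' @param ivw_mode `"multiplicative_random"` or `"fixed"`.
#' @param n_boot weighted-median bootstrap replicates.
#' @param presso_n_sim MR-PRESSO simulated null size.
#' @param seed integer seed covering every stochastic step.
#' @param exclude_snps SNP ids mapped to confounders by the user, refitted
#'   without; `character()` disables the refit.
#' @param out_dir output directory for report files; `NULL` skips writing.
#' @param power optional list with `n_total`, `n_cases`, `r2_total` and
#'   optionally `alpha`, `power` for the detectable-odds-ratio block.
#' @return A list of class `run_config`.
#' @export
run_config <- function(exposure, outcome, ld = NULL,
                       exposure_columns = NULL, outcome_columns = NULL,
                       p_threshold = 5e-8, r2_threshold = 0.01,
                       intermediate_eaf = 0.42,
                       ivw_mode = "multiplicative_random",
                       n_boot = 1000, presso_n_sim = 10000, seed = 1L,
                       exclude_snps = character(), out_dir = NULL,
                       power = NULL) {
  structure(list(exposure = exposure, outcome = outcome, ld = ld,
                 exposure_columns = exposure_columns,
                 outcome_columns = outcome_columns,
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 intermediate_eaf = intermediate_eaf, ivw_mode = ivw_mode,
                 n_boot = n_boot, presso_n_sim = presso_n_sim,
                 seed = as.integer(seed),
                 exclude_snps = as.character(exclude_snps),
                 out_dir = out_dir, power = power),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_config()]; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (k in c("exposure", "outcome", "ld")) y[[k]] <- resolve(y[[k]])
  for (k in c("exposure_columns", "outcome_columns")) {
    if (!is.null(y[[k]])) y[[k]] <- unlist(y[[k]])
  }
  if (!is.null(y$exclude_snps)) y$exclude_snps <- unlist(y$exclude_snps)
  do.call(run_config, y)
}

#' Run the full two-sample MR pipeline
#'
#' Stages: read exposure and outcome summary statistics, select
#' genome-wide-significant instruments, prune by LD, harmonize, compute
#' per-SNP strength (variance explained and F), estimate the causal
#' effect (IVW, weighted median, MR-Egger when possible, per-SNP Wald
#' ratios), and run the sensitivity battery (Cochran's Q, leave-one-out,
#' MR-PRESSO when at least four instruments remain, and the configured
#' confounder-exclusion refit). Output files are staged in a temporary
#' directory and moved into `out_dir` only on success, so a failed run
#' leaves no partial report.
#'
#' @param config a [run_config()] or path to a YAML accepted by
#'   [read_run_config()].
#' @return A list of class `mr_report`; see the `report.json` it writes
#'   for the serialised layout.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  exposure <- read_summary_stats(config$exposure, config$exposure_columns,
                                 trait = "exposure")
  outcome <- read_summary_stats(config$outcome, config$outcome_columns,
                                trait = "outcome")
  selected <- select_instruments(exposure, config$p_threshold)
  if (!is.null(config$ld)) {
    selected <- ld_prune(selected, read_ld_table(config$ld),
                         config$r2_threshold)
  }
  instruments <- harmonize(selected, outcome, config$intermediate_eaf)
  if (nrow(instruments) == 0L) {
    stop("no instruments remain after selection/pruning/harmonization")
  }

  strength <- instrument_strength(
    selected[selected$SNP %in% instruments$SNP, , drop = FALSE])
  estimates <- mr_all_methods(instruments, ivw_mode = config$ivw_mode,
                              n_boot = config$n_boot, seed = config$seed)
  per_snp <- wald_ratio(instruments)
  heterogeneity <- cochran_q(instruments)
  loo <- leave_one_out(instruments, mode = config$ivw_mode)
  presso <- if (nrow(instruments) >= 4L) {
    mr_presso(instruments, n_sim = config$presso_n_sim, seed = config$seed)
  }
  exclusion <- if (length(config$exclude_snps) > 0L) {
    exclude_snps_and_refit(instruments, config$exclude_snps,
                           mode = config$ivw_mode)
  }
  power <- if (!is.null(config$power)) {
    p <- config$power
    alpha <- if (is.null(p$alpha)) 0.05 else p$alpha
    target <- if (is.null(p$power)) 0.8 else p$power
    ors <- detectable_or(p$n_total, p$n_cases, p$r2_total, alpha, target)
    list(inputs = list(n_total = p$n_total, n_cases = p$n_cases,
                       r2_total = p$r2_total, alpha = alpha,
                       power = target),
         detectable_or_protective = unname(ors["protective"]),
         detectable_or_deleterious = unname(ors["deleterious"]))
  }

  report <- structure(list(
    instruments = instruments, strength = strength, estimates = estimates,
    per_snp = per_snp, heterogeneity = heterogeneity, loo = loo,
    presso = presso, exclusion = exclusion, power = power,
    provenance = list(
      package = "mrkit",
      version = as.character(utils::packageVersion("mrkit")),
      seed = config$seed,
      config = config[setdiff(names(config), "out_dir")]
    )
  ), class = "mr_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Serialise a report into TSV/JSON files; staged then moved so the output
# directory is only touched on success.
#' Write pipeline outputs
#'
#' Emits `report.json`, `instruments.tsv`, `estimates.tsv`,
#' `heterogeneity.json`, `loo.tsv`, `forest.tsv`, `scatter.tsv` and (when
#' computed) `presso.json` into `out_dir`.
#'
#' @param report an `mr_report`.
#' @param out_dir destination directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "mr_report"))
  stage <- tempfile("mrkit_report_")
  dir.create(stage)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(stage, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  inst <- merge(report$instruments, report$strength, by = "SNP", sort = FALSE)
  tsv(inst, "instruments.tsv")
  tsv(report$estimates, "estimates.tsv")
  tsv(report$loo, "loo.tsv")

  # forest-plot data: per-SNP Wald ORs plus pooled rows
  pooled <- report$estimates[report$estimates$method %in%
                               c("ivw", "weighted_median", "egger_slope"), ]
  forest <- rbind(
    data.frame(label = report$per_snp$SNP, report$per_snp[, -1],
               stringsAsFactors = FALSE),
    data.frame(label = pooled$method, pooled, stringsAsFactors = FALSE)
  )
  tsv(forest, "forest.tsv")

  # scatter-plot data: effects with per-axis SEs and per-method fit lines
  eg <- report$estimates[report$estimates$method == "egger_slope", ]
  eg_i <- report$estimates[report$estimates$method == "egger_intercept", ]
  scatter <- report$instruments[, c("SNP", "beta_exp", "se_exp",
                                    "beta_out", "se_out")]
  scatter$fit_ivw <- report$estimates$beta[report$estimates$method == "ivw"] *
    scatter$beta_exp
  scatter$fit_wmedian <-
    report$estimates$beta[report$estimates$method == "weighted_median"] *
    scatter$beta_exp
  if (nrow(eg) == 1L) {
    scatter$fit_egger <- eg_i$beta + eg$beta * abs(scatter$beta_exp) *
      sign(scatter$beta_exp)
  }
  tsv(scatter, "scatter.tsv")

  het <- report$heterogeneity
  jsonlite::write_json(list(q_stat = het$q_stat, df = het$df,
                            pval = het$pval),
                       file.path(stage, "heterogeneity.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$presso)) {
    pr <- report$presso
    jsonlite::write_json(list(rss_obs = pr$rss_obs,
                              global_pval = pr$global_pval,
                              n_sim = pr$n_sim, seed = pr$seed,
                              outliers = as.list(pr$outliers),
                              outlier_pvals = pr$outlier_pvals),
                         file.path(stage, "presso.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  jsonlite::write_json(report_as_list(report),
                       file.path(stage, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage, full.names = TRUE)) {
    file.copy(f, file.path(out_dir, basename(f)), overwrite = TRUE)
  }
  unlink(stage, recursive = TRUE)
  invisible(out_dir)
}

# Plain-list view of a report for JSON serialisation.
report_as_list <- function(report) {
  pr <- report$presso
  list(
    instruments = report$instruments,
    strength = report$strength,
    estimates = report$estimates,
    per_snp = report$per_snp,
    heterogeneity = list(q_stat = report$heterogeneity$q_stat,
                         df = report$heterogeneity$df,
                         pval = report$heterogeneity$pval),
    leave_one_out = report$loo,
    presso = if (!is.null(pr)) {
      list(rss_obs = pr$rss_obs, global_pval = pr$global_pval,
           n_sim = pr$n_sim, seed = pr$seed,
           outliers = as.list(pr$outliers))
    },
    exclusion_refit = report$exclusion,
    power = report$power,
    provenance = list(
      package = report$provenance$package,
      version = report$provenance$version,
      seed = report$provenance$seed
    )
  )
}

#' @export
print.mr_report <- function(x, ...) {
  fmt_or <- function(e) {
    sprintf("%s: OR %.2f (95%% CI %.2f-%.2f), p = %.3g [%d SNPs]",
            e$method, e$or, e$or_ci_low, e$or_ci_high, e$pval, e$n_snps)
  }
  cat("Two-sample MR report (", nrow(x$instruments), " instruments)\n",
      sep = "")
  for (i in seq_len(nrow(x$estimates))) {
    e <- x$estimates[i, ]
    if (e$method == "egger_intercept") {
      cat(sprintf("  egger_intercept: %.3f, p = %.3g\n", e$beta, e$pval))
    } else {
      cat(" ", fmt_or(e), "\n")
    }
  }
  cat(sprintf("  Cochran's Q = %.3f (df %d), p = %.3g\n",
              x$heterogeneity$q_stat, x$heterogeneity$df,
              x$heterogeneity$pval))
  if (!is.null(x$presso)) {
    cat(sprintf("  MR-PRESSO global p = %.3g (%d sims), outliers: %s\n",
                x$presso$global_pval, x$presso$n_sim,
                if (length(x$presso$outliers)) {
                  paste(x$presso$outliers, collapse = ", ")
                } else "none"))
  }
  if (!is.null(x$exclusion)) {
    cat("  after confounder exclusion ->", fmt_or(x$exclusion), "\n")
  }
  if (!is.null(x$power)) {
    cat(sprintf("  detectable OR at %.0f%% power: %.3f\n",
                100 * x$power$inputs$power,
                x$power$detectable_or_protective))
  }
  invisible(x)
}
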