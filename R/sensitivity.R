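#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (ratio_j - beta_ref)^2` over the per-SNP Wald ratios,
#' with the IVW inverse-variance weights, referred to a chi-square
#' distribution with L - 1 degrees of freedom. The reference estimate
#' defaults to the fixed-effect IVW pooled value (the conventional
#' definition) but can be supplied for reuse against other estimators.
#'
#' @param instruments a `harmonized_instruments` data.frame (>= 2 rows).
#' @param beta_ref reference causal estimate; fixed-effect IVW when `NULL`.
#' @return A list of class `heterogeneity_result` with `q_stat`, `df`,
#'   `pval`.
#' @export
#' @examples
#' cochran_q(make_fixture_table2())
cochran_q <- function(instruments, beta_ref = NULL) {
  stopifnot(nrow(instruments) >= 2L)
  wc <- .wald_components(instruments)
  if (is.null(beta_ref)) beta_ref <- ivw(instruments, mode = "fixed")$beta
  q <- sum(wc$w * (wc$ratio - beta_ref)^2)
  df <- length(wc$ratio) - 1L
  structure(list(q_stat = q, df = df,
                 pval = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' Leave-one-out sensitivity series
#'
#' Re-estimates the causal effect with each instrument removed in turn; a
#' final `"All"` row carries the full-set estimate for plotting.
#'
#' @param instruments a `harmonized_instruments` data.frame (>= 2 rows).
#' @param method estimator applied to each subset; only `"ivw"` currently.
#' @param ... passed to the estimator (e.g. `mode`).
#' @return A data.frame, one row per excluded SNP plus the `"All"` row,
#'   with the `mr_estimate` columns and a leading `excluded` column.
#' @export
leave_one_out <- function(instruments, method = "ivw", ...) {
  stopifnot(nrow(instruments) >= 2L)
  method <- match.arg(method, "ivw")
  est_fun <- function(x) ivw(x, ...)
  rows <- lapply(seq_len(nrow(instruments)), function(j) {
    cbind(excluded = instruments$SNP[j],
          est_fun(instruments[-j, , drop = FALSE]),
          stringsAsFactors = FALSE)
  })
  rows <- c(rows, list(cbind(excluded = "All", est_fun(instruments),
                             stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Zero-intercept weighted-least-squares slope: the IVW estimate expressed
# directly in (beta_exp, beta_out) coordinates, used by MR-PRESSO.
.ivw_slope <- function(g, G, w) sum(w * G * g) / sum(w * g^2)

#' MR-PRESSO global and outlier test
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. The observed
#' residual of SNP j is taken about the leave-one-out IVW slope
#' \eqn{\hat\beta_{-j}}: \eqn{r_j = \hat\Gamma_j - \hat\beta_{-j}\hat\gamma_j},
#' and \eqn{RSS_{obs} = \sum_j r_j^2 / se_{out,j}^2}. The null distribution
#' is simulated by drawing, in each replicate, exposure effects
#' \eqn{\hat\gamma_j^* \sim N(\hat\gamma_j, se_{exp,j}^2)} and outcome
#' effects \eqn{\hat\Gamma_j^* \sim N(\hat\beta_{-j}\hat\gamma_j,
#' se_{out,j}^2)} and recomputing the RSS identically (leave-one-out slopes
#' re-estimated on the simulated effects). The global p-value is the
#' add-one empirical tail probability, so it is never exactly zero. Per-SNP
#' outlier p-values compare each observed weighted squared residual with
#' its simulated counterpart and are Bonferroni-scaled by the number of
#' instruments; when outliers are flagged, the IVW estimate with them
#' removed is attached. The distortion test is not implemented.
#'
#' @param instruments a `harmonized_instruments` data.frame (>= 4 rows so
#'   every leave-one-out slope is estimable from >= 3 instruments).
#' @param n_sim simulated null replicates (default 10000; below 100 a
#'   warning is raised as the empirical p is too coarse).
#' @param seed integer seed, required.
#' @param outlier_alpha significance level applied to the
#'   Bonferroni-adjusted outlier p-values (default 0.05).
#' @return A list of class `presso_result` with `rss_obs`, `global_pval`,
#'   `n_sim`, `outlier_pvals` (data.frame: `SNP`, `pval`, `pval_bonf`),
#'   `outliers`, `seed`, and `ivw_outliers_removed` (an `mr_estimate` or
#'   `NULL`).
#' @export
mr_presso <- function(instruments, n_sim = 10000, seed,
                      outlier_alpha = 0.05) {
  if (missing(seed)) stop("a seed is required for the simulated null")
  L <- nrow(instruments)
  if (L < 4L) stop("MR-PRESSO requires at least 4 instruments")
  if (n_sim < 100) warning("n_sim < 100 gives a very coarse empirical p")
  g <- instruments$beta_exp
  G <- instruments$beta_out
  sg <- instruments$se_exp
  sG <- instruments$se_out
  w <- 1 / sG^2

  loo_slopes <- function(gv, Gv) {
    num <- sum(w * Gv * gv) - w * Gv * gv
    den <- sum(w * gv^2) - w * gv^2
    num / den
  }
  b_loo <- loo_slopes(g, G)
  r_obs <- G - b_loo * g
  rss_j_obs <- r_obs^2 * w
  rss_obs <- sum(rss_j_obs)

  sim <- withr::with_seed(seed, {
    gs <- matrix(stats::rnorm(n_sim * L, mean = rep(g, each = n_sim),
                              sd = rep(sg, each = n_sim)), n_sim, L)
    Gs <- matrix(stats::rnorm(n_sim * L, mean = rep(b_loo * g, each = n_sim),
                              sd = rep(sG, each = n_sim)), n_sim, L)
    wG <- rep(w, each = n_sim)
    num_tot <- rowSums(Gs * gs * matrix(wG, n_sim, L))
    den_tot <- rowSums(gs^2 * matrix(wG, n_sim, L))
    bl <- (num_tot - Gs * gs * matrix(wG, n_sim, L)) /
      (den_tot - gs^2 * matrix(wG, n_sim, L))
    rs <- (Gs - bl * gs)^2 * matrix(wG, n_sim, L)
    list(rss = rowSums(rs), rss_j = rs)
  })

  global_pval <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  outlier_p <- vapply(seq_len(L), function(j) {
    (1 + sum(sim$rss_j[, j] >= rss_j_obs[j])) / (n_sim + 1)
  }, numeric(1))
  pval_bonf <- pmin(1, outlier_p * L)
  outliers <- instruments$SNP[pval_bonf < outlier_alpha]
  refit <- NULL
  if (length(outliers) > 0L && length(outliers) < L) {
    refit <- ivw(instruments[!(instruments$SNP %in% outliers), , drop = FALSE])
  }
  structure(list(
    rss_obs = rss_obs, global_pval = global_pval, n_sim = n_sim,
    outlier_pvals = data.frame(SNP = instruments$SNP, pval = outlier_p,
                               pval_bonf = pval_bonf,
                               stringsAsFactors = FALSE),
    outliers = outliers, seed = seed, ivw_outliers_removed = refit
  ), class = "presso_result")
}

#' Refit after excluding confounder-associated instruments
#'
#' The confounder-to-SNP mapping (e.g. a SNP also associated with serum
#' calcium) is supplied by the user from external lookup, not computed.
#' Unknown ids are reported and ignored.
#'
#' @param instruments a `harmonized_instruments` data.frame.
#' @param exclusion_ids SNP ids to drop.
#' @param method estimator for the refit (only `"ivw"` currently).
#' @param ... passed to the estimator.
#' @return An `mr_estimate` row on the reduced instrument set.
#' @export
exclude_snps_and_refit <- function(instruments, exclusion_ids,
                                   method = "ivw", ...) {
  method <- match.arg(method, "ivw")
  unknown <- setdiff(exclusion_ids, instruments$SNP)
  if (length(unknown) > 0L) {
    message("exclusion ids not among instruments (ignored): ",
            paste(unknown, collapse = ", "))
  }
  keep <- !(instruments$SNP %in% exclusion_ids)
  if (!any(keep)) stop("all instruments excluded; nothing to refit")
  ivw(instruments[keep, , drop = FALSE], ...)
}
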