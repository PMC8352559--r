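.z975 <- function() stats::qnorm(0.975)

# Per-SNP Wald ratios with first-order delta-method SEs and the
# corresponding inverse-variance weights w_j = beta_exp^2 / se_out^2.
.wald_components <- function(instruments) {
  stopifnot(inherits(instruments, "data.frame"), nrow(instruments) > 0L)
  g <- instruments$beta_exp
  if (any(g == 0)) {
    stop("Wald ratio undefined: zero exposure effect for ",
         paste(instruments$SNP[g == 0], collapse = ", "))
  }
  ratio <- instruments$beta_out / g
  se <- instruments$se_out / abs(g)
  list(snp = instruments$SNP, ratio = ratio, se = se, w = 1 / se^2)
}

#' Assemble a causal-estimate record
#'
#' Packs a log-odds-scale estimate with its normal-theory confidence
#' interval, p-value and odds-ratio counterparts into a one-row data.frame.
#'
#' @param method method label.
#' @param beta causal estimate on the log-odds scale.
#' @param se its standard error.
#' @param n_snps number of instruments used.
#' @param pval two-sided p-value; computed from the normal distribution
#'   when `NULL`.
#' @param weights optional per-SNP weights, kept as an attribute for audit.
#' @return A one-row data.frame of class `mr_estimate` with columns
#'   `method`, `n_snps`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `or`,
#'   `or_ci_low`, `or_ci_high`.
#' @export
mr_estimate <- function(method, beta, se, n_snps, pval = NULL,
                        weights = NULL) {
  z <- .z975()
  if (is.null(pval)) {
    pval <- if (se > 0) 2 * stats::pnorm(-abs(beta / se)) else 0
  }
  pval <- max(pval, .Machine$double.xmin)  # never report exactly 0
  out <- data.frame(
    method = method, n_snps = as.integer(n_snps), beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se, pval = pval,
    or = exp(beta), or_ci_low = exp(beta - z * se),
    or_ci_high = exp(beta + z * se), stringsAsFactors = FALSE
  )
  attr(out, "weights") <- weights
  class(out) <- unique(c("mr_estimate", class(out)))
  out
}

#' Per-SNP Wald ratio estimates
#'
#' The single-instrument causal estimate: outcome effect divided by
#' exposure effect, with the first-order standard error
#' `se_out / |beta_exp|` (exposure-side uncertainty ignored).
#'
#' @param instruments a `harmonized_instruments` data.frame.
#' @return A data.frame of class `mr_estimate`, one row per SNP, with a
#'   leading `SNP` column.
#' @export
wald_ratio <- function(instruments) {
  wc <- .wald_components(instruments)
  rows <- lapply(seq_along(wc$snp), function(j) {
    cbind(SNP = wc$snp[j],
          mr_estimate("wald", wc$ratio[j], wc$se[j], 1L),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- unique(c("mr_estimate", class(out)))
  out
}

#' Inverse-variance-weighted estimator
#'
#' Pools the per-SNP Wald ratios with inverse-variance weights
#' \eqn{w_j = \hat\gamma_j^2 / se_{out,j}^2}; the point estimate equals the
#' slope of a zero-intercept weighted regression of outcome on exposure
#' effects. In `multiplicative_random` mode (default) the fixed-effect
#' standard error is scaled by `max(1, sqrt(Q / (L - 1)))`, with Q the
#' Cochran heterogeneity statistic about the pooled estimate, so that the
#' estimator reduces to fixed effects when heterogeneity is low.
#'
#' @param instruments a `harmonized_instruments` data.frame (>= 1 row; with
#'   a single instrument the result equals its Wald ratio).
#' @param mode `"multiplicative_random"` or `"fixed"`.
#' @return An `mr_estimate` row, method `"ivw"`.
#' @export
#' @examples
#' ivw(make_fixture_table2())
ivw <- function(instruments, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  wc <- .wald_components(instruments)
  L <- length(wc$ratio)
  beta <- sum(wc$w * wc$ratio) / sum(wc$w)
  se <- 1 / sqrt(sum(wc$w))
  if (mode == "multiplicative_random" && L > 1L) {
    q <- sum(wc$w * (wc$ratio - beta)^2)
    se <- se * max(1, sqrt(q / (L - 1)))
  }
  mr_estimate("ivw", beta, se, L, weights = stats::setNames(wc$w, wc$snp))
}

# Weighted-median point estimate by midpoint cumulative-weight
# interpolation of the sorted ratios.
.weighted_median_point <- function(ratio, w) {
  if (length(ratio) == 1L) return(ratio)
  o <- order(ratio)
  b <- ratio[o]
  p <- w[o] / sum(w)
  s <- cumsum(p) - p / 2
  if (0.5 <= s[1L]) return(b[1L])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Point estimate: the Wald ratios are sorted and the ratio at midpoint
#' cumulative weight fraction 0.5 is linearly interpolated; consistent
#' when valid instruments carry more than half the total weight. The
#' standard error comes from a seeded parametric bootstrap that resamples
#' exposure and outcome effects from normal distributions at their
#' reported standard errors.
#'
#' @param instruments a `harmonized_instruments` data.frame.
#' @param n_boot bootstrap replicates for the SE (default 1000).
#' @param seed integer seed, required for reproducibility.
#' @return An `mr_estimate` row, method `"weighted_median"`.
#' @export
weighted_median <- function(instruments, n_boot = 1000, seed) {
  if (missing(seed)) stop("a seed is required for the bootstrap SE")
  wc <- .wald_components(instruments)
  point <- .weighted_median_point(wc$ratio, wc$w)
  g <- instruments$beta_exp
  sg <- instruments$se_exp
  G <- instruments$beta_out
  sG <- instruments$se_out
  L <- length(g)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      gs <- stats::rnorm(L, g, sg)
      Gs <- stats::rnorm(L, G, sG)
      ok <- gs != 0
      .weighted_median_point(Gs[ok] / gs[ok], gs[ok]^2 / sG[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  mr_estimate("weighted_median", point, se, L,
              weights = stats::setNames(wc$w, wc$snp))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept and weights `1 / se_out^2`, after orienting every
#' instrument so its exposure effect is non-negative. The intercept
#' estimates average directional pleiotropy; the slope is a
#' pleiotropy-adjusted causal effect under the InSIDE assumption.
#' Coefficient standard errors have the residual scale floored at 1
#' (division by `min(sigma, 1)`), p-values use the t distribution with
#' L - 2 degrees of freedom, and confidence intervals the normal
#' multiplier.
#'
#' @param instruments a `harmonized_instruments` data.frame with at least
#'   3 rows.
#' @return A list with `mr_estimate` rows `slope` and `intercept` (methods
#'   `"egger_slope"`, `"egger_intercept"`).
#' @export
egger <- function(instruments) {
  L <- nrow(instruments)
  if (L < 3L) stop("MR-Egger requires at least 3 instruments")
  g <- instruments$beta_exp
  G <- instruments$beta_out
  flip <- g < 0
  g[flip] <- -g[flip]
  G[flip] <- -G[flip]
  if (any(g == 0)) stop("zero exposure effect cannot be oriented")
  w <- 1 / instruments$se_out^2
  fit <- stats::lm(G ~ g, weights = w)
  sm <- summary(fit)
  scale_floor <- min(sm$sigma, 1)
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"] / scale_floor
  pvals <- 2 * stats::pt(-abs(est / se), df = L - 2)
  list(
    slope = mr_estimate("egger_slope", est[["g"]], se[["g"]], L,
                        pval = pvals[["g"]],
                        weights = stats::setNames(w, instruments$SNP)),
    intercept = mr_estimate("egger_intercept", est[["(Intercept)"]],
                            se[["(Intercept)"]], L,
                            pval = pvals[["(Intercept)"]])
  )
}

#' Convert a log-odds estimate to an odds ratio with CI
#'
#' @param beta log odds ratio.
#' @param se its standard error (>= 0).
#' @param alpha two-sided CI level (default 0.05 for 95%).
#' @return Named numeric vector `c(or = , ci_low = , ci_high = )`.
#' @export
to_odds_ratio <- function(beta, se, alpha = 0.05) {
  stopifnot(se >= 0)
  z <- stats::qnorm(1 - alpha / 2)
  c(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Run all estimators on one instrument set
#'
#' @param instruments a `harmonized_instruments` data.frame.
#' @param ivw_mode IVW standard-error mode.
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return A data.frame stacking the IVW, weighted-median and (when at
#'   least three instruments are available) MR-Egger slope and intercept
#'   estimates.
#' @export
mr_all_methods <- function(instruments, ivw_mode = "multiplicative_random",
                           n_boot = 1000, seed = 1L) {
  rows <- list(ivw(instruments, mode = ivw_mode),
               weighted_median(instruments, n_boot = n_boot, seed = seed))
  if (nrow(instruments) >= 3L) {
    eg <- egger(instruments)
    rows <- c(rows, list(eg$slope, eg$intercept))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
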