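#' Variance in the exposure explained by a SNP
#'
#' Summary-statistic approximation from the per-allele effect, its standard
#' error, the effect-allele frequency and the sample size:
#' \deqn{R^2 = \frac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + 2\,SE^2\,N\,f(1-f)}}
#' which for a standardized phenotype reduces to
#' \eqn{\beta^2 / (\beta^2 + SE^2 N)}.
#'
#' @param beta per-allele effect on the exposure.
#' @param se standard error of `beta` (> 0).
#' @param eaf effect-allele frequency, strictly inside (0, 1).
#' @param n exposure-study sample size (> 2).
#' @return Fraction of exposure variance explained, in \[0, 1).
#' @export
#' @examples
#' variance_explained(0.07, 0.003, 0.34, 29155)
variance_explained <- function(beta, se, eaf, n) {
  stopifnot(all(se > 0), all(n > 2))
  if (any(eaf <= 0 | eaf >= 1)) {
    stop("eaf must lie strictly inside (0, 1)")
  }
  het <- 2 * eaf * (1 - eaf)
  num <- beta^2 * het
  num / (num + se^2 * n * het)
}

#' Instrument F statistic
#'
#' `r2 * (n - 2) / (1 - r2)`; F > 10 is the conventional threshold above
#' which weak-instrument bias is considered negligible.
#'
#' @param r2 variance explained, in \[0, 1).
#' @param n sample size (> 2).
#' @return F statistic, >= 0.
#' @export
f_statistic <- function(r2, n) {
  stopifnot(all(n > 2))
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)")
  r2 * (n - 2) / (1 - r2)
}

#' Per-SNP strength report
#'
#' @param records a `gwas_summary` data.frame of exposure associations.
#' @param n optional scalar sample size overriding the per-row `n`.
#' @return data.frame with `SNP`, `r2`, `f_stat`.
#' @export
instrument_strength <- function(records, n = NULL) {
  nn <- if (is.null(n)) records$n else rep_len(n, nrow(records))
  r2 <- variance_explained(records$beta, records$se, records$eaf, nn)
  data.frame(SNP = records$SNP, r2 = r2, f_stat = f_statistic(r2, nn),
             stringsAsFactors = FALSE)
}

.check_power_inputs <- function(n_total, n_cases, r2_total, alpha, power = 0.8) {
  stopifnot(n_cases > 0, n_cases < n_total,
            r2_total > 0, r2_total < 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
}

#' Power of a binary-outcome Mendelian randomization study
#'
#' Non-centrality approximation for a case-control outcome: with case
#' fraction \eqn{K} and hypothesized log odds ratio \eqn{b}, power at
#' two-sided level \eqn{\alpha} is
#' \eqn{\Phi(|b|\sqrt{N R^2 K(1-K)} - z_{1-\alpha/2})}.
#'
#' @param n_total outcome-study sample size.
#' @param n_cases number of cases.
#' @param r2_total total exposure variance explained by the instruments.
#' @param or_hypothesis hypothesized causal odds ratio (> 0).
#' @param alpha two-sided significance level.
#' @return Power, a fraction in (0, 1).
#' @export
#' @examples
#' power_binary(455221, 77052, 0.045, 0.948)
power_binary <- function(n_total, n_cases, r2_total, or_hypothesis,
                         alpha = 0.05) {
  .check_power_inputs(n_total, n_cases, r2_total, alpha)
  stopifnot(all(or_hypothesis > 0))
  k <- n_cases / n_total
  b <- abs(log(or_hypothesis))
  stats::pnorm(b * sqrt(n_total * r2_total * k * (1 - k)) -
                 stats::qnorm(1 - alpha / 2))
}

#' Smallest detectable odds ratio at a target power
#'
#' Inverts [power_binary()]: the magnitude of the detectable log odds
#' ratio is \eqn{b^* = (z_{1-\alpha/2} + z_{power}) / \sqrt{N R^2 K(1-K)}}.
#' The protective-direction bound `exp(-b*)` is reported first; the
#' deleterious bound `exp(+b*)` alongside.
#'
#' @inheritParams power_binary
#' @param power target power, in (0, 1).
#' @return Named numeric vector `c(protective = , deleterious = )`.
#' @export
#' @examples
#' detectable_or(455221, 77052, 0.045)
detectable_or <- function(n_total, n_cases, r2_total, alpha = 0.05,
                          power = 0.8) {
  .check_power_inputs(n_total, n_cases, r2_total, alpha, power)
  k <- n_cases / n_total
  b <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
    sqrt(n_total * r2_total * k * (1 - k))
  c(protective = exp(-b), deleterious = exp(b))
}
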