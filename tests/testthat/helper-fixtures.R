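# Shared helpers: random instrument sets for oracle comparisons and
# temporary summary-stat files.

random_instruments <- function(L, seed) {
  withr::with_seed(seed, {
    harmonized_instruments(
      snp = sprintf("rs%05d", seq_len(L)),
      beta_exp = stats::runif(L, 0.01, 0.1) * sample(c(-1, 1), L, TRUE),
      se_exp = stats::runif(L, 0.002, 0.01),
      beta_out = stats::rnorm(L, 0, 0.03),
      se_out = stats::runif(L, 0.005, 0.02)
    )
  })
}

write_tsv_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "stats.tsv")
  writeLines(lines, path)
  path
}

# Hand-rolled weighted least squares via normal equations, independent of
# both the package's weight algebra and stats::lm.
wls_oracle <- function(X, y, w) {
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% y)[, 1]
}

# Loop-based midpoint cumulative-weight interpolation of the weighted
# median, independent of stats::approx.
weighted_median_oracle <- function(ratio, w) {
  o <- order(ratio)
  b <- ratio[o]
  p <- w[o] / sum(w)
  s <- cumsum(p) - p / 2
  if (0.5 <= s[1]) return(b[1])
  n <- length(b)
  if (0.5 >= s[n]) return(b[n])
  for (j in seq_len(n - 1)) {
    if (s[j] <= 0.5 && 0.5 <= s[j + 1]) {
      return(b[j] + (b[j + 1] - b[j]) * (0.5 - s[j]) / (s[j + 1] - s[j]))
    }
  }
  stop("unreachable")
}

fixture_exposure_path <- function() {
  system.file("extdata", "pth_exposure.tsv", package = "mrkit")
}
fixture_outcome_path <- function() {
  system.file("extdata", "oa_outcome.tsv", package = "mrkit")
}
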