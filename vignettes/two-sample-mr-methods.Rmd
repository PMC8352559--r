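---
title: "Methods: two-sample Mendelian randomization in mrkit"
author: "mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The design

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure. Because alleles are assorted at
random at conception, a variant that (i) is robustly associated with the
exposure, (ii) is independent of confounders, and (iii) affects the
outcome only through the exposure, identifies the exposure's causal
effect free of classical confounding and reverse causation. In the
*two-sample* setting the variant-exposure and variant-outcome
associations come from two separate GWAS, and only their summary
statistics — per-allele effect $\hat\gamma_j$ or $\hat\Gamma_j$, standard
error, allele pair, effect-allele frequency (EAF), p-value and sample
size — are needed.

`mrkit` implements that workflow end to end. The worked example running
through the package is the analysis of serum parathyroid hormone (PTH,
exposure GWAS of 29,155 Europeans) against osteoarthritis (OA, case-control
GWAS of 455,221 participants, 77,052 cases); its five-instrument table
ships as `make_fixture_table2()` and as TSV files under `extdata/`.

## Instrument selection and harmonization

**Selection.** Instruments must pass genome-wide significance,
$p < 5\times 10^{-8}$, with a strict inequality (`select_instruments()`).

**LD pruning.** Instruments must be mutually independent. `ld_prune()`
uses greedy p-value-ordered clumping: visit SNPs by ascending p-value
(ties by rsID) and accept a SNP only if its LD $r^2$ with every accepted
SNP is below the threshold (default 0.01). Pairwise $r^2$ values are
inputs (`ld_table()`); an unlisted pair counts as $r^2 = 0$, since LD
tables in practice enumerate only the correlated pairs. In the PTH
example this removes rs35194449 ($p = 1.8\times10^{-10}$, $r^2 = 0.38$
with the far stronger rs6127099) and leaves five instruments.

**Harmonization.** `harmonize()` aligns the outcome records onto the
exposure's effect allele, matching by rsID:

1. same allele pair — copy;
2. swapped alleles — negate the outcome beta, reflect its EAF;
3. non-palindromic pair matching only as strand complements —
   complement, then rule 1 or 2;
4. palindromic pair (A/T or C/G, identical on both strands) — strand
   cannot be read from the alleles, so use frequency agreement: flip
   when the two EAFs sit on opposite sides of 0.5, and *exclude* the SNP
   when either EAF lies in the intermediate band, where frequency is
   uninformative;
5. anything else is non-concordant and excluded.

The intermediate band defaults to $[0.42, 0.58]$. A frequency near 0.5
is ambiguous from both directions, so the published one-sided cut of
0.42 is applied symmetrically. Duplicate rsIDs within a table are an
error rather than silently deduplicated — summary files should arrive
pre-aggregated, and duplicates usually signal an upstream join gone
wrong.

## Instrument strength and power

Per SNP, the variance in the exposure explained is the
summary-statistic approximation

$$R^2_j = \frac{2\hat\gamma_j^2 f_j(1-f_j)}
               {2\hat\gamma_j^2 f_j(1-f_j) + 2\,SE_j^2\,N\,f_j(1-f_j)},$$

and the instrument F statistic is $R^2 (N-2)/(1-R^2)$; $F > 10$ is the
conventional weak-instrument bound. For a binary outcome with case
fraction $K$ and instruments explaining $R^2$ of the exposure, power at
two-sided level $\alpha$ against log odds ratio $b$ uses the
non-centrality approximation
$\Phi(|b|\sqrt{N R^2 K(1-K)} - z_{1-\alpha/2})$, and
`detectable_or()` inverts it:
$b^* = (z_{1-\alpha/2} + z_{\text{power}})/\sqrt{N R^2 K(1-K)}$, reported
as the protective bound $e^{-b^*}$ with the deleterious bound $e^{+b^*}$
alongside. For the OA outcome GWAS ($N = 455{,}221$, $K = 0.169$,
$R^2 = 0.045$) this gives a detectable OR of 0.949 at 80% power.

## Estimators

All estimators work on the harmonized per-SNP pairs
$(\hat\gamma_j, \hat\Gamma_j)$ and report log-odds-scale estimates with
normal 95% confidence intervals (multiplier $z_{0.975} = 1.959964$) and
odds-ratio counterparts.

**Wald ratio.** $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with the
first-order delta-method standard error $SE_{out,j}/|\hat\gamma_j|$.
Exposure-side uncertainty is ignored in the SE and in the weights below
(the NO-Measurement-Error approximation); second-order weights are out
of scope.

**IVW.** The inverse-variance-weighted mean of the ratios with
$w_j = \hat\gamma_j^2/SE_{out,j}^2$, algebraically the slope of the
zero-intercept weighted regression of $\hat\Gamma$ on $\hat\gamma$. The
default standard error is *multiplicative random effects*: the
fixed-effect SE scaled by $\max(1, \sqrt{Q/(L-1)})$, where $Q$ is
Cochran's statistic about the pooled estimate. Under low heterogeneity
the scale floors at 1 and the estimator reduces to fixed effects; under
heterogeneity the point estimate is unchanged and only the uncertainty
widens. This variant is the package default because overdispersion is
the norm in practice, and it is what reproduces the example's published
interval.

**Weighted median.** Sort the ratios, form midpoint cumulative weight
fractions $s_j = \sum_{k\le j} p_k - p_j/2$, and linearly interpolate
the ratio at $s = 0.5$; consistent when valid instruments carry more
than half the total weight. The point estimate is deterministic; the SE
comes from a parametric bootstrap (default 1000 replicates) resampling
$\hat\gamma_j^*, \hat\Gamma_j^*$ from normal distributions at the
reported SEs, and therefore requires a seed. Published weighted-median
intervals from unseeded software can only be matched statistically, not
bit-for-bit.

**MR-Egger.** Orient every instrument so $\hat\gamma_j \ge 0$ (negating
both effects where needed — the fit is not invariant to allele
orientation), then regress $\hat\Gamma$ on $\hat\gamma$ with a free
intercept and weights $1/SE_{out}^2$. The intercept estimates average
directional pleiotropy; the slope is a pleiotropy-adjusted causal
effect under the InSIDE assumption. Numerical conventions: the residual
scale is floored at 1 (coefficient SEs divided by $\min(\hat\sigma,1)$,
the multiplicative-random-effects analogue for a regression with an
intercept), p-values use $t_{L-2}$, and confidence intervals keep the
normal multiplier. The t/normal asymmetry is deliberate: with a handful
of instruments the t distribution protects the test, while the interval
convention matches how such intervals are conventionally reported; the
example's published Egger p-value and interval are jointly consistent
only with this pairing.

## Sensitivity analysis

**Cochran's Q.** $Q = \sum_j w_j(\hat\beta_j - \hat\beta_{IVW})^2$
about the fixed-effect IVW estimate (the conventional reference, but a
`beta_ref` argument allows reuse), referred to $\chi^2_{L-1}$.

**Leave-one-out.** The IVW estimate recomputed with each instrument
removed, plus the all-SNP row for plotting.

**MR-PRESSO.** The global test measures the weighted residual sum of
squares of each SNP about the *leave-one-out* IVW slope,
$RSS_{obs} = \sum_j (\hat\Gamma_j - \hat\beta_{-j}\hat\gamma_j)^2 / SE_{out,j}^2,$
and compares it with a simulated null in which
$\hat\gamma_j^* \sim N(\hat\gamma_j, SE_{exp,j}^2)$ and
$\hat\Gamma_j^* \sim N(\hat\beta_{-j}\hat\gamma_j, SE_{out,j}^2)$, with
the RSS recomputed identically on each replicate. The global p-value is
the add-one empirical tail $(1 + \#\{RSS^* \ge RSS_{obs}\})/(n_{sim}+1)$,
never exactly zero, at a default $n_{sim} = 10{,}000$ (empirical
resolution $\sim 10^{-4}$); a seed is mandatory. Per-SNP outlier
p-values are the empirical tails of the per-SNP weighted squared
residuals, Bonferroni-scaled by $L$, flagged at 0.05; when outliers are
found the IVW estimate without them is attached. The distortion test is
not implemented. Note that because the simulated null preserves the
observed leave-one-out slopes, it absorbs observed heterogeneity and
the global test is conservative relative to the analytic $\chi^2$
heterogeneity p-value on heterogeneous instrument sets — on the
five-SNP PTH example it sits near 0.19 where Cochran's Q gives 0.034.

**Confounder exclusion.** SNPs known (from external catalog lookup,
supplied as configuration) to associate with confounders of the
exposure-outcome pair are removed and the IVW estimate refit
(`exclude_snps_and_refit()`); in the PTH example, rs4074995 is also a
serum-calcium locus.

## The synthetic-data generator

`simulate_two_sample()` draws, per SNP: an EAF $f_j$ uniform on
0.1–0.9; a strictly positive instrument effect $\gamma_j$ uniform on
0.02–0.08 (the magnitude range of the PTH instruments); a direct
(pleiotropic) outcome effect $\alpha_j = 0$ for valid SNPs, or normal
with mean 0 (balanced) or `pleio_mean` (directional) for an invalid
fraction; standard errors from the per-allele scaling
$1/\sqrt{2f(1-f)n}$ for a unit-variance phenotype, so instrument
strength responds to sample size and frequency realistically; observed
effects equal truth plus normal noise, with outcome mean
$\beta\gamma_j + \alpha_j$. Defaults — 50 SNPs, exposure and outcome
samples of 50,000, causal slope $-0.4$, no pleiotropy — describe a
well-powered design of the same order as the PTH-OA study. Alleles are
assigned non-palindromic so harmonization is deterministic, and a
random half of the SNPs is reported on the opposite allele in both
tables to exercise orientation handling end to end.

What the generator does *not* emulate: LD between instruments (pruning
is tested against hand-built LD tables), palindromic strand ambiguity,
winner's-curse selection of instruments, sample overlap between the two
GWAS, and binary-trait liability-scale subtleties. Passing recovery
tests on synthetic data therefore demonstrates estimator correctness
under the stated sampling model, not robustness to those real-data
complications.

The test suite uses the generator at these problem sizes, chosen to
give stable Monte-Carlo checks: 200 replicates for IVW bias and
coverage, 100 replicates for the weighted-median robustness comparison
(with "strong" directional pleiotropy, mean direct effect 0.05 —
larger than the largest mediated effect $|\beta|\gamma_{max} = 0.032$ —
in 40% of SNPs), and 1,000 replicates for the null rejection rate.

## Degenerate inputs and numerical conventions

- A zero exposure effect makes the Wald ratio undefined and is an error;
  orientation for Egger likewise rejects it.
- Empirical p-values use add-one estimators; parametric p-values are
  floored at the smallest positive double rather than reported as 0.
- A single instrument collapses IVW to the Wald ratio; Egger requires
  at least 3 instruments and MR-PRESSO at least 4 (each leave-one-out
  slope needs 3).
- Missing LD pairs are $r^2 = 0$; a SNP with itself is 1.
- Human-readable report rounding is 2 decimals for ORs/CIs, 4 for
  betas/SEs, 3 significant figures for p-values; `report.json` keeps
  full precision.

## Known limitations

- No mode-based estimators, MR-RAPS, debiased IVW, multivariable MR,
  Steiger filtering, or Radial-MR.
- No LD computation from reference panels and no proxy-SNP search;
  rsID matching only, no genome-build liftover.
- The MR-PRESSO distortion test is omitted.
- Exposure-side uncertainty enters only through the bootstrap and the
  MR-PRESSO null, not the IVW/Egger weights.

## Running the pipeline

```{r pipeline, eval = FALSE}
cfg <- read_run_config(system.file("extdata", "pth_oa_config.yaml",
                                   package = "mrkit"))
cfg$out_dir <- "pth_oa_report"
report <- run_pipeline(cfg)
report
```

The report prints the IVW, weighted-median and MR-Egger estimates with
odds ratios and intervals, Cochran's Q, the MR-PRESSO global p, the
confounder-exclusion refit and the detectable odds ratio, and writes
`report.json`, `estimates.tsv`, `instruments.tsv`, `heterogeneity.json`,
`presso.json`, `loo.tsv`, `forest.tsv` and `scatter.tsv` (the latter two
carrying forest- and scatter-plot data) into the output directory,
staged atomically.
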