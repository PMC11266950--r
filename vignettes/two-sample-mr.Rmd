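---
title: "Two-sample Mendelian randomization with mrivw: model, diagnostics and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrivw}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrivw)
```

## The estimation problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure. A variant is a valid instrument if it
(1) associates robustly with the exposure, (2) is independent of
confounders of the exposure–outcome relation, and (3) affects the outcome
only through the exposure. In the *two-sample* design the variant–exposure
and variant–outcome associations come from different GWAS populations, so
only summary statistics are needed.

The motivating application is the causal effect of circulating
anti-Müllerian hormone (AMH), a marker of ovarian reserve and reproductive
aging, on coronary artery disease, ischemic stroke and type 2 diabetes in
women, instrumented by four genome-wide significant variants that jointly
explain $R^2 = 0.0147$ of inverse-normal-transformed AMH. Everything in
the package is, however, generic over exposures, outcomes and instrument
sets.

## Estimators

**Wald ratio.** For variant $i$ with exposure effect $\beta_{x,i}$ and
outcome effect $\beta_{y,i}$ (log-odds per effect allele),
$$\hat\theta_i = \beta_{y,i} / \beta_{x,i}, \qquad
  \mathrm{se}(\hat\theta_i) = \mathrm{se}(\beta_{y,i}) / |\beta_{x,i}|.$$
The default standard error is the first-order delta method, which ignores
exposure-side sampling error; `waldRatio(..., order = 2)` adds the
second-order term
$\hat\theta_i^2\,\mathrm{se}(\beta_{x,i})^2/\beta_{x,i}^2$. First order is
the default because published per-variant confidence intervals in this
setting are consistent with it, and with strong instruments the
second-order correction is negligible.

**Inverse-variance weighted pooling.** With weights $w_i = 1/\mathrm{se}_i^2$,
$$\hat\theta = \frac{\sum_i w_i \hat\theta_i}{\sum_i w_i}, \qquad
  \mathrm{se}_{\mathrm{fixed}} = \Big(\sum_i w_i\Big)^{-1/2},$$
which equals a weighted least-squares fit of the $\hat\theta_i$ on a
constant (a property the test suite checks against an independent
matrix-algebra oracle to $10^{-10}$).

**Heterogeneity and random effects.** Cochran's
$Q = \sum_i w_i(\hat\theta_i - \hat\theta)^2$ is $\chi^2_{k-1}$ under
homogeneity. The default random-effects flavour is *multiplicative*:
$$\mathrm{se}_{\mathrm{used}} = \mathrm{se}_{\mathrm{fixed}} \cdot
  \varphi, \qquad \varphi = \max\!\big(1, \sqrt{Q/(k-1)}\big),$$
so over-dispersion widens the interval and under-dispersion never narrows
it. This flavour was chosen because it is the default behaviour of the
widely used two-sample MR tooling and it reproduces the published AMH
intervals exactly: the CAD interval requires $\varphi > 1$ while the
stroke and T2D intervals require the floor at 1. An additive
DerSimonian–Laird mode (`mode = "additive_random"`) is provided but not
default. Intervals and p-values use the normal reference
($z_{0.975} = 1.959964$); with $k = 4$ instruments a $t$ reference would
be hard to justify either way, and the normal matches the published
numbers.

With $k = 1$ the "pooled" result is the single Wald estimate and $Q$ is
reported absent rather than erroring, which keeps leave-one-out uniform
under total degeneracy.

**Instrument strength.** The summary-level first-stage F-statistic is
$$F = \frac{R^2}{1-R^2}\cdot\frac{n-k-1}{k}.$$
Which $n$ belongs here is a genuine modelling choice. The textbook choice
is the exposure-GWAS sample size; the motivating analysis paired the
discovery $R^2$ with each *outcome* GWAS's sample size, yielding its
printed 558.5 / 65.4 / 1732.1. `fStatistic()` takes $n$ explicitly, so
both conventions are one call away, and the documentation flags the
outcome-sample convention as unconventional.

## Harmonization

Matching is by rsid only. Allele pairs identical after possibly swapping
effect/other (negating the outcome beta, reflecting the frequency) or
strand-complementing are aligned; palindromic variants (A/T, C/G) cannot
be resolved by letters, so they are aligned by allele-frequency
concordance when both frequencies are at least 0.08 from 0.5 and dropped
otherwise (also when a palindromic frequency is missing). The 0.08 window
is configurable; it mirrors common two-sample practice rather than any
published choice of the motivating analysis, which is silent on the
matter. Harmonization is idempotent, and flipping twice restores the
input record exactly — both are property-tested.

## Scale conversion for mixed-model GWAS

Binary-trait GWAS run as linear mixed models (BOLT-LMM style) report
effects on the linear probability scale. With case fraction $\mu$,
$$\beta' = \beta/(\mu(1-\mu)), \qquad \mathrm{se}' = \mathrm{se}/(\mu(1-\mu)).$$
`linearToLogOR()` implements this; the tests verify it end-to-end by
simulating a binary trait, fitting marginal linear models, converting, and
comparing against direct logistic fits on the same data. Printed
odds-ratio confidence intervals are converted back to log-scale standard
errors with `seFromCI()`, which is exact up to the table's rounding.

## The pleiotropy scan

`runScan()` regresses each trait on each variant's dosage and on the
weighted genetic risk score $\mathrm{GRS}_j = \sum_i w_i g_{ij}$ (linear
or logistic by trait family), and reports z-scores aligned with the
direction of higher genetically predicted exposure: a variant whose
exposure-raising allele is the *other* allele has its z negated, so the
heatmap is invariant to allele relabelling. Benjamini–Hochberg FDR is
applied across the whole predictor-by-trait grid by default
(`fdrScope = "global"`); per-predictor families are available. The
motivating analysis does not state its family; the global family is the
more conservative, reproducible default. Failed or non-convergent cells
become missing values and leave the FDR family rather than masquerading
as nulls. Covariates (age, genotyping array, principal components in the
motivating analysis) are caller-supplied, not hard-coded.

## The synthetic-data generator

`simulateTwoSample()` emulates the statistical structure the pipeline
assumes, not any particular cohort:

* Hardy–Weinberg genotypes: dosage = sum of two Bernoulli(EAF) draws;
  defaults are four variants at EAFs 0.1/0.2/0.3/0.4 with equal variance
  shares — the published per-variant effects are not printed in the
  source tables, so the shares are free, realistic parameters rather than
  a calibration.
* Exposure: $x = \sum_i \beta_i g_i + \varepsilon$ with
  $\beta_i = \sqrt{R^2 s_i / (2f_i(1-f_i))}$ so the variants explain
  exactly $R^2$ (default 0.0147) of the unit-variance latent trait,
  followed by the rank-based inverse normal transform
  $\Phi^{-1}((r_i - 3/8)/(n + 1/4))$ (Blom offset, average ranks for
  ties), as the AMH GWAS applied to hormone levels.
* Outcome: logistic, with the intercept solved by bisection to $10^{-8}$
  so the expected case fraction hits the configured prevalence.
* Sample overlap: the exposure and outcome samples share a configurable
  fraction of individuals, with an optional shared confounder acting on
  both the exposure and the outcome logit — enough structure to
  demonstrate that full overlap plus confounding biases weak-instrument
  estimates away from the null toward the observational association,
  which the test suite asserts directionally (medians over 300 paired
  replicates at $F \approx 10$, since weak-instrument Wald ratios are
  heavy-tailed).
* The outcome GWAS is run as a linear model on the 0/1 phenotype and
  converted with `linearToLogOR()` by default, mirroring the
  mixed-model-plus-conversion pipeline of large biobank GWAS.

What the generator does **not** emulate: linkage disequilibrium between
instruments, population stratification, relatedness, assay artefacts, or
phenotype-definition noise. Passing calibration tests therefore shows the
estimator chain is correct under its own assumptions, not that any real
cohort satisfies them.

## Problem sizes and numerical choices

The calibration studies in the test suite use sample sizes of 15,000 per
GWAS and 500 null replicates (type-I error and CI coverage), 120 causal
replicates (bias), and 300 paired replicates for the overlap
demonstration — sizes at which Monte-Carlo error is small relative to the
assertions while a full run of the suite stays near a minute. Under the
multiplicative random-effects default with $k = 4$, the $\varphi$ floor
makes the null rejection rate slightly conservative (theoretical
$\approx 0.037$ at the 0.05 level), which the 3-standard-error acceptance
band accommodates; the fixed-effect mode is exactly calibrated and is
checked against `metafor` as an independent reference.

Other numerical choices: degenerate instruments ($\beta_x = 0$) error
rather than returning infinities; p-values from marginal linear GWAS use
the exact $t$ reference; reported p-values in file I/O are floored at the
smallest positive double to respect the $(0,1]$ contract; outputs keep
input variant order throughout (no reordering, so no tie-breaking).

## Reproducing the published analysis

The package ships the printed per-variant Wald odds ratios and 95% CIs of
the motivating AMH analysis (plus outcome case/control counts) as a
plain-text fixture. `reproducePublished()` back-derives the per-variant
standard errors from the CIs, re-pools them, and compares the pooled ORs,
CI bounds, Cochran's Q and F-statistics against the printed values at
tolerances dominated by the fixture's two-decimal rounding (OR and CI
±0.01, Q ±0.05, F ±0.1):

```{r}
rep <- reproducePublished()
rep[rep$quantity %in% c("or", "cochran_q"), ]
attr(rep, "pass")
```

## Known limitations

* Pleiotropy-robust estimators (MR-Egger, weighted median, MR-PRESSO)
  are out of scope; with four instruments they are not identifiable
  enough to be useful, which is precisely the regime the motivating
  analysis sits in. Heterogeneity and leave-one-out diagnostics are the
  available sensitivity analyses.
* The harmonizer does not search proxies, lift positions over, or query
  LD — matching is by rsid only.
* `seFromCI()` assumes the printed interval was normal-theory symmetric
  on the log scale; intervals from profile likelihoods or exact methods
  would back-convert with bias.
* The GRS scan fits independent regressions per cell; it does not model
  relatedness or mixed effects.
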