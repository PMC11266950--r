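# mrivw

Two-sample Mendelian randomization (MR) from GWAS summary statistics, in
R with S4 classes: per-variant Wald ratios, inverse-variance weighted
(IVW) pooling with fixed or multiplicative random effects, Cochran's Q
heterogeneity, leave-one-out sensitivity analysis, instrument-strength
F-statistics, allele harmonization, conversion of linear-mixed-model
estimates on binary traits to log odds ratios, a weighted
genetic-risk-score (GRS) pleiotropy scan with Benjamini–Hochberg FDR, and
a synthetic two-sample GWAS generator for calibration studies.

The package is written for epidemiologists running summary-level MR: you
bring per-variant association records for an exposure and an outcome, it
returns the pooled causal odds ratio with its diagnostics. Its bundled
application is the question whether circulating anti-Müllerian hormone
(AMH) — a marker of reproductive aging — causally affects coronary artery
disease, ischemic stroke or type 2 diabetes in women, instrumented by
four variants explaining R² = 0.0147 of transformed AMH.

## The model

For variant *i* with exposure effect β<sub>x,i</sub> and outcome effect
β<sub>y,i</sub> (log-odds scale):

- Wald ratio: θ̂<sub>i</sub> = β<sub>y,i</sub>/β<sub>x,i</sub>,
  se(θ̂<sub>i</sub>) = se(β<sub>y,i</sub>)/|β<sub>x,i</sub>| (first-order
  delta method; a second-order option exists).
- IVW: with w<sub>i</sub> = 1/se<sub>i</sub>², θ̂ = Σw<sub>i</sub>θ̂<sub>i</sub>/Σw<sub>i</sub>,
  se<sub>fixed</sub> = (Σw<sub>i</sub>)<sup>−1/2</sup>.
- Heterogeneity: Q = Σw<sub>i</sub>(θ̂<sub>i</sub> − θ̂)², χ² with k−1 df.
- Multiplicative random effects (default): se<sub>used</sub> =
  se<sub>fixed</sub> · max(1, √(Q/(k−1))).
- Instrument strength: F = (R²/(1−R²)) · ((n−k−1)/k).
- LMM scale conversion for a binary trait with case fraction μ:
  β′ = β/(μ(1−μ)), se′ = se/(μ(1−μ)).

See `vignettes/two-sample-mr.Rmd` for the reasoning behind each choice.

## Worked example

Pool the published per-variant coronary-artery-disease estimates shipped
with the package (printed odds ratios and 95% CIs; log-scale SEs are
recovered from the CIs with `seFromCI()`):

```r
library(mrivw)
tab <- read.table(publishedFixture("estimates"), header = TRUE,
                  sep = "\t", na.strings = "NA")
cad <- tab[tab$outcome == "coronary_artery_disease" & tab$method == "wald", ]
ivwFromPublished(cad)
#> IVW (multiplicative_random), k = 4: OR 1.129 [95% CI 0.947-1.346], p = 0.176
#>   Cochran's Q = 4.416 (df 3, p = 0.22), phi = 1.213
fStatistic(0.0147, 149752, 4)
#> F-statistic 558.5 (R2 = 0.0147, n = 149752, k = 4)
```

The pooled OR of 1.13 (0.95–1.35) says the exposure-raising genotypes do
not significantly raise CAD risk; φ = 1.21 means the four Wald ratios are
slightly over-dispersed, so the random-effects CI is 21% wider than the
fixed-effect one; F ≫ 10 indicates strong instruments. Leave-one-out
shows no single variant drives the result:

```r
est <- data.frame(rsid = cad$rsid, theta = log(cad$or),
                  se = seFromCI(cad$ci_lower, cad$ci_upper))
leaveOneOut(est)[, c("excluded", "or", "ci_lower", "ci_upper", "pval")]
#>     excluded   or ci_lower ci_upper  pval
#> 1 rs10417628 1.16    0.905     1.49 0.238
#> 2 rs13009019 1.04    0.883     1.23 0.616
#> 3 rs16991615 1.12    0.880     1.43 0.350
#> 4 rs11683493 1.19    0.998     1.42 0.052
```

The same machinery runs on synthetic data with known truth:

```r
cfg <- simConfig(nExposure = 50000, nOutcome = 50000,
                 causalLogOR = 0.3, seed = 42)
sim <- simulateTwoSample(cfg)
ivw(waldRatio(harmonize(sim$exposure, sim$outcome)))
#> IVW (multiplicative_random), k = 4: OR 1.167 [95% CI 0.917-1.485], p = 0.21
#>   Cochran's Q = 2.706 (df 3, p = 0.439), phi = 1.000
```

Here the true causal OR is exp(0.3) ≈ 1.35 and the estimate's CI covers
it; the test suite repeats this kind of run hundreds of times to check
type-I error, CI coverage and bias.

A thin command-line wrapper with subcommands `mr`, `loo`, `scan`,
`simulate` and `reproduce` lives at `inst/scripts/mrivw-cli.R`.

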