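# mrpipe

Two-sample Mendelian randomization (MR) for GWAS summary statistics, with
pleiotropy- and heterogeneity-gated model selection, MR-PRESSO outlier
correction, and cross-cohort inverse-variance meta-analysis.

MR treats genetic variants as instrumental variables for a modifiable
exposure: because alleles are randomized at conception, a variant that
robustly shifts, say, circulating ascorbate can be used to estimate the
causal effect of ascorbate on a disease outcome free of classical
confounding. In the two-sample design the SNP–exposure effects
(β<sub>Xj</sub>, σ<sub>Xj</sub>) and SNP–outcome effects
(β<sub>Yj</sub>, σ<sub>Yj</sub>) come from separate GWAS. Each instrument
gives a Wald ratio θ̂<sub>j</sub> = β<sub>Yj</sub>/β<sub>Xj</sub>; the
package pools these with six estimators that trade efficiency against
robustness to invalid instruments:

| method | assumption it relaxes |
|---|---|
| inverse-variance weighted (IVW) | none — efficient when all instruments valid |
| maximum likelihood | accounts for exposure-side sampling error |
| MR-Egger | directional pleiotropy (under InSIDE); intercept = pleiotropy test |
| weighted median | up to half of total weight invalid |
| penalized weighted median | a minority of grossly invalid instruments |
| MR-PRESSO | detects and removes pleiotropic outliers |

The pipeline follows the decision tree used in applied two-sample MR
studies: Egger intercept test (p < 0.05 → Egger primary, otherwise IVW);
Cochran's Q (p < 0.05 → random-effects IVW); per-method minimum
instrument counts (Egger/medians need J > 2, PRESSO J > 3); per-cohort
analysis followed by inverse-variance meta-analysis (DerSimonian–Laird
random effects under cross-cohort heterogeneity); and Bonferroni tiers
(p < 0.01 significant for five outcomes, 0.01–0.05 suggestive).

A seeded synthetic-data generator (`simulate_two_sample()`) produces
exposure/outcome summary files with known causal effect, per-SNP
instrument strengths, and configurable pleiotropy, so every stage is
testable by parameter recovery without any external downloads.

## Worked example

Simulate a two-cohort study (a large biobank and a smaller registry
cohort) with a true protective effect of log-OR −0.25, and run the whole
pipeline:

```r
library(mrpipe)

sim_ukb <- simulate_two_sample(sim_config(n_snps = 10, theta = -0.25, seed = 101))
sim_fin <- simulate_two_sample(sim_config(n_snps = 10, theta = -0.25,
  n_out = 175809, case_fraction = 1803 / 175809, seed = 102))

res <- mr_pipeline(
  sim_ukb$exposure,
  list(uk_biobank = sim_ukb$outcome, finngen = sim_fin$outcome),
  config = mr_config(seed = 1),
  exposure_name = "ascorbate", outcome_name = "colon cancer"
)
res
#> Two-sample MR pipeline: ascorbate -> colon cancer
#> Cohorts analysed: uk_biobank, finngen
#>   uk_biobank [ivw]: OR 0.666 (0.524-0.847), p = 0.001
#>   finngen [ivw]: OR 0.646 (0.465-0.896), p = 0.009
#> Combined (fixed effects): OR 0.659 (0.543-0.800), p = 0.000 [significant]
```

The primary method is IVW in both cohorts because the Egger intercept
test found no directional pleiotropy, and the fixed-effect model is used
because Cochran's Q showed no heterogeneity — each gate outcome is in
`res$trace`. `tidy(res)` returns every estimator's row; `autoplot(res)`
draws the forest plot. The per-unit ORs here sit above exp(−0.25) ≈ 0.78
sampling noise aside; with ten instruments explaining 1.7% of exposure
variance the per-cohort CIs are wide, which is exactly the regime the
method set is designed for.

Published per-cohort results can be combined directly from their printed
OR and 95% CI:

```r
m <- meta_combine(dplyr::bind_rows(
  estimate_from_ci(0.774, 0.608, 0.985, cohort = "uk_biobank"),
  estimate_from_ci(0.738, 0.504, 1.081, cohort = "finngen")
))
m[, c("or", "ci_low", "ci_high", "pvalue", "model", "tier")]
#>      or ci_low ci_high  pvalue model        tier
#> 1 0.764  0.623   0.936 0.00951 fixed significant
```

i.e. a combined OR of 0.764 (95% CI 0.623–0.936, p = 0.010): ascorbate's
suggestive protection against colon cancer survives pooling across the
two biobanks.

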