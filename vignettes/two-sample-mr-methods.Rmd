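---
title: "Two-sample Mendelian randomization with mrpipe: models, gates, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure — here, circulating antioxidant levels
instrumenting digestive-system cancer risk is the motivating design — so
that a causal effect can be estimated from observational data without the
confounding and reverse causation that afflict direct regression. In the
*two-sample* setting, the SNP–exposure associations
$(\hat\beta_{Xj}, \sigma_{Xj})$ and SNP–outcome associations
$(\hat\beta_{Yj}, \sigma_{Yj})$ come from separate GWAS, and everything is
computed from summary statistics alone.

Each instrument $j$ yields a Wald ratio
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ with first-order standard
error $\sigma_{Yj}/|\hat\beta_{Xj}|$. All multi-SNP estimators in the
package are different ways of pooling these ratios; they differ in which
violations of the instrumental-variable assumptions they tolerate.

## From raw summary statistics to instruments

`read_summary_stats()` reads delimited text with a configurable column
map; `harmonize()` joins exposure and outcome records by variant id and
re-expresses the outcome effect on the exposure's effect allele (swapped
labels negate the beta; strand complements are recognised; A/T and C/G
palindromes are resolved by allele frequency or dropped). Variant matching
is by rsID string only — position-based matching and reference-panel
strand inference are deliberately out of scope, and proxy lookup is
supported only through a user-supplied table, never an external service.

Instrument selection follows the conventional thresholds: genome-wide
significance $p < 5\times10^{-8}$ for absolute trait levels and
$p < 1\times10^{-5}$ for metabolite concentrations, greedy clumping at
$r^2 \le 0.001$ within 10,000 kb, and retention only of variants with
$F = \beta^2/\mathrm{SE}^2$ strictly above 10. Per-variant explained
variance uses
$R^2 = 2f(1-f)\beta^2 / [2f(1-f)\beta^2 + 2f(1-f)N\,\mathrm{SE}^2]$,
which reduces to $F/(F+N)$ — the package tests exploit that identity as an
independent check. Clumping works from user-supplied positions and
(optionally) pairwise LD; without LD information, proximity alone removes
a candidate, which is the conservative choice.

The palindromic ambiguity window defaults to 0.08 (drop when the effect
allele frequency lies in $[0.42, 0.58]$). The choice is a convention, not
a reconstruction of any particular study's behaviour: published analyses
rarely state how their tooling treated palindromes, so the window is
exposed as a parameter and every decision is recorded in the output.

## The six estimators

**Wald ratio** (single instrument). Used only when one instrument
survives.

**IVW.** With weights $w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2$ (inverse
ratio variance under the no-measurement-error approximation), the
estimate is $\sum w_j\hat\theta_j / \sum w_j$ and the fixed-effect SE is
$(\sum w_j)^{-1/2}$. Cochran's $Q = \sum w_j(\hat\theta_j - \hat\theta)^2$
on $J-1$ df and $I^2 = \max(0, (Q-\mathrm{df})/Q)$ quantify heterogeneity;
the random-effects variant inflates the SE multiplicatively by
$\max(1, \sqrt{Q/(J-1)})$. The multiplicative (rather than additive)
inflation, floored at one, matches the convention of the standard
two-sample MR software family.

**Maximum likelihood.** The bivariate measurement model
$\hat\beta_{Xj}\sim N(\gamma_j, \sigma_{Xj}^2)$,
$\hat\beta_{Yj}\sim N(\theta\gamma_j, \sigma_{Yj}^2)$ is maximized in
$\theta$ after profiling out the nuisance means, which are closed-form
given $\theta$. The search is one-dimensional (started at the IVW
estimate, interval widened automatically if the optimum brackets an
edge), and the SE comes from the numerical curvature of the profile
log-likelihood at the optimum — identical to the observed-information SE
for $\theta$, at a fraction of the cost of a $(J+1)$-dimensional
optimization. Unlike IVW, this accounts for exposure-side sampling error.

**MR-Egger.** Instruments are first oriented so every exposure effect is
positive (both betas negated otherwise) — without a fixed orientation the
intercept is meaningless. Weighted least squares of
$\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with weights $\sigma_{Yj}^{-2}$ and a
free intercept gives a slope robust to *directional* pleiotropy under the
InSIDE assumption; the intercept, its SE, and a two-sided $t_{J-2}$
p-value constitute the pleiotropy test. Analytic SEs are the $t_{J-2}$
WLS ones; an optional residual-resampling bootstrap (seeded, defaults to
1000 draws in the pipeline) replaces the reported SEs while the analytic
values remain in `se_analytic`/`intercept_se_analytic`, so both variants
are always visible side by side. All-equal exposure effects make the
regressors collinear and raise a typed error rather than returning a
meaningless fit.

**Weighted median.** Ratios are sorted (ties broken by a stable sort on
variant id); with normalized weights $w'_j$ and
$S_j = \sum_{k\le j} w'_k - w'_j/2$, the estimate interpolates $\theta$
linearly across $S$ at $S = 0.5$. It is consistent when at least half the
total weight comes from valid instruments. The SE is the standard
deviation over seeded parametric-bootstrap redraws of both effect
estimates (5000 by default).

**Penalized weighted median.** Each instrument's disagreement with the
plain weighted median, $Q_j = w_j(\hat\theta_j - \hat\theta_{WM})^2$, is
referred to $\chi^2_1$; weights become
$w_j \cdot \min(1, 20\,p_j)$ and the median is recomputed. The penalty
constant 20 follows the original formulation of the penalized estimator
and is configurable.

**MR-PRESSO.** The observed statistic is the leave-one-out weighted
residual sum of squares
$\mathrm{RSS} = \sum_j (\hat\beta_{Yj} - \hat\theta_{(-j)}\hat\beta_{Xj})^2
/ \sigma_{Yj}^2$. Its null distribution is simulated parametrically
(exposure effects redrawn around their observed values, outcome effects
around the leave-one-out predictions), giving a `+1`-corrected empirical
global p-value that can never be exactly zero and is bounded below by
$1/(n_{\mathrm{sim}}+1)$. When the global test is significant, per-SNP
empirical p-values (Bonferroni-adjusted across $J$) flag outliers at 0.05;
the IVW estimate is recomputed without them, and a distortion test
compares the resulting shift against the shifts from removing equally many
random instruments. The distortion test is reported but never gates
anything — corrected estimates are shown regardless. The simulation count
defaults to 1000 and the outlier level to Bonferroni-adjusted 0.05; both
are echoed in the result object since published analyses rarely state
them.

## The decision tree and meta-analysis

Per cohort, `mr_pipeline()` applies the gates in a fixed order, recording
each outcome in a decision trace so that every reported number can be
audited:

1. instrument count: $J=1$ Wald only; $J=2$ adds IVW and maximum
   likelihood; $J\ge3$ adds Egger and both medians; $J\ge4$ adds
   MR-PRESSO (the `>1`, `>2`, `>3` minimums of the published method
   notes);
2. pleiotropy gate: Egger intercept $p < 0.05$ makes Egger the primary
   estimator, otherwise IVW;
3. heterogeneity gate: Cochran's $Q$ $p < 0.05$ switches IVW to random
   effects.

Per-cohort primary estimates are combined by inverse-variance
meta-analysis: fixed effect by default, DerSimonian–Laird additive
$\tau^2$ random effects when the cross-cohort $Q$ p-value is below 0.05.
P-values are two-sided normal — validated against the published combined
estimates (0.764, $p=0.010$; 0.747, $p=0.020$), which a $t$ reference
would not reproduce. Significance tiers follow the Bonferroni convention
for five outcomes: $p<0.01$ significant, $[0.01, 0.05)$ suggestive,
otherwise null.

`estimate_from_ci()` reconstructs $\hat\beta = \ln \mathrm{OR}$ and
$\mathrm{SE} = (\ln \mathrm{CI_{hi}} - \ln \mathrm{CI_{lo}})/(2z)$ from
printed results so published per-cohort rows can enter the meta-analysis
directly. The constant $z = 1.959964$ is used rather than 1.96: the
difference moves reconstructed SEs in the third decimal, which is visible
when matching published tables to print precision.

## What the synthetic-data generator emulates

`simulate_two_sample()` produces paired exposure/outcome summary files
with known truth. Allele frequencies are uniform on a configurable range;
per-SNP true exposure effects are sized so instrument $j$ explains a share
of the configured total $R^2$ (equal shares by default, or
exponentially-skewed shares mimicking instrument sets dominated by a lead
locus); sampling SEs use the large-sample approximations
$\sigma_{Xj} \approx (2f_j(1-f_j)\,n_{\mathrm{exp}})^{-1/2}$ and, for a
binary outcome,
$\sigma_{Yj} \approx (2f_j(1-f_j)\,n_{\mathrm{out}}\,cf(1-cf))^{-1/2}$.
Pleiotropy can be balanced, directional, or correlated with instrument
strength (InSIDE-violating, at configurable correlation, default 0.5 —
the regime in which Egger's slope is biased and the medians earn their
keep); a single outlier can be implanted at a chosen multiple of
$\sigma_{Yj}$. A configurable fraction of outcome records is written with
swapped allele labels, and a fraction of variants is made palindromic, to
exercise harmonization.

Defaults mirror a realistic regime from the motivating study family: 10
instruments explaining 1.7% of variance in a 52,018-sample exposure GWAS,
against a 420,531-sample biobank outcome with a 0.9% case fraction
(a colon-cancer-sized endpoint). `make_paper_like_fixtures()` emits one
fixture per published instrument-set shape (3, 10, 2, 2, 5, and 27 SNPs
with their respective $R^2$ totals and GWAS sizes) under fixed seeds; the
shared true causal log-OR of $-0.25$ is an arbitrary modest protective
effect chosen once.

What the generator does **not** emulate: LD between instruments (the
post-clumping regime is independence by construction), individual-level
genotypes, winner's-curse in instrument discovery, sample overlap between
exposure and outcome GWAS, and case-control ascertainment beyond the
variance approximation. Passing tests therefore demonstrate correctness
of the estimators and gates under the stated sampling model, not
robustness to those additional real-data features.

## Numerical choices and degenerate inputs

- Ratio weights use the NOME approximation $w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2$;
  exposure-side error is handled only by the likelihood estimator.
- $\hat\beta_{Xj} = 0$ raises an error (the ratio is undefined) rather
  than propagating an infinity.
- Median interpolation at the 0.5 crossing is linear in cumulative
  weight; at the boundary the extreme ratio is returned. Ties in
  $\hat\theta_j$ are broken by a stable sort on variant id so results are
  order-independent. Note the interpolated median is *not* exactly
  invariant to duplicating the instrument list (each normalized weight
  halves, shifting every $S_j$); the closed-form estimators are.
- The likelihood search interval is $\pm2$ around the IVW start and
  quadruples on boundary hits, up to eight times, before raising an
  estimation error.
- Empirical p-values (PRESSO) use the $+1$ correction.
- Duplicate variant ids keep the smallest p-value record; stated
  p-values inconsistent with $|\beta/\mathrm{SE}|$ by more than a factor
  of 10 warn but are retained.
- All bootstraps and simulations restore the caller's RNG state, so a
  seeded pipeline is reproducible bit-for-bit without contaminating the
  session stream.

## Simulation scale and calibration

The test suite runs its heaviest checks at 2000 null replicates (type-I
error), 500 recovery replicates, 200 grid-oracle draws, and 200
implanted-outlier replicates — sizes at which binomial 95% bands are tight
enough to be informative while a full run stays a desk-scale job. Under
this regime IVW and maximum likelihood hold their nominal 0.05 size. The
weighted median does not: its parametric-bootstrap SE overstates the true
sampling SD by roughly 10% at $J=10$–25 (the bootstrap's known small-$n$
behaviour for quantile-type statistics), so its empirical size lands
around 0.03. The package reports the estimator exactly as defined rather
than substituting a differently-calibrated SE; users should read weighted
median p-values as mildly conservative at small instrument counts.

## Known limitations

Multivariable MR, nonlinear exposure-outcome relationships, reference
panel LD computation, and external database lookups (proxy retrieval,
confounder screening) are out of scope. The pipeline accepts
user-supplied proxy and LD tables instead. Ratio-based SEs ignore
exposure-side error except in the likelihood estimator; with all
instruments at $F > 10$ the approximation is standard practice.
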