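---
title: "Modelling total SVD burden and cognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling total SVD burden and cognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(svdburden)
```

## The scientific problem

Cerebral small vessel disease (SVD) is visible on MRI through four marker
families: white matter hyperintensities (WMH), visible perivascular spaces
(PVS), lacunes, and cerebral microbleeds. Because the markers co-occur and
share aetiology, a *total burden* construct — a latent variable measured by
all four — is a more faithful severity measure than any single marker or a
coarse 0–4 count. `svdburden` implements the full latent-variable analysis
of that construct against general and domain-specific cognitive abilities:

1. a **measurement model** for latent SVD burden from two continuous
   computational markers (WMH volume / intracranial volume, PVS count) and
   two binary markers (lacunes, microbleeds present/absent);
2. an alternative **ordinal reconstruction** from visual ratings (deep and
   periventricular Fazekas 0–3, basal-ganglia PVS rating 0–4, binary
   lacunes/microbleeds);
3. **latent regressions** of cognitive factors (general ability g,
   processing speed, verbal memory, visuospatial ability) on SVD burden,
   with covariates (age, sex, a vascular-risk factor score, depression
   score, age-11 IQ) entered stepwise;
4. an **orthogonal bifactor model** separating domain-specific from shared
   (g) variance, with all covariates entered simultaneously;
5. **predictor comparisons** (Williams test for dependent overlapping
   correlations) and **Benjamini–Hochberg FDR** control.

Because the cohort data that motivated this design are restricted, the
package ships a synthetic cohort generator calibrated to the published
marginals and standardized estimates; every claim the package makes is
validated by parameter recovery on simulated data, by closed-form oracles,
or by internal identities.

## The estimator

All models are fitted in the correlation metric by diagonally weighted
least squares (DWLS), the estimator commonly reported as WLSMV:

* **Stage one** estimates a mixed correlation matrix pairwise: Pearson for
  continuous pairs, polyserial for continuous–categorical, polychoric for
  categorical pairs, with probit thresholds
  \(\tau_j = \Phi^{-1}(\text{cumulative proportion})\) fixed from the
  marginals (two-stage, Olsson-type). Pairwise-present rows are used
  throughout, matching the design's treatment of its small amount of
  missing cognitive data. Bivariate-normal rectangle probabilities are
  evaluated by Plackett's identity with a sine substitution and 48-point
  Gauss–Legendre quadrature (absolute error below 1e-12, verified against
  an independent adaptive-quadrature oracle).
* **Stage two** minimizes
  \(F(\theta) = \sum_{i<j} (r_{ij} - \sigma_{ij}(\theta))^2 / v_{ij}\),
  where \(v_{ij}\) is each correlation's estimated asymptotic variance
  (observed information for polychoric/polyserial, normal-theory
  \((1-r^2)^2/n\) for Pearson). Latent response variances are fixed to 1
  (delta parameterization) and indicator residual variances are implied by
  the unit diagonal, so under the default unit-factor-variance
  identification every free parameter is already a standardized quantity.
  A marker identification (first loading fixed) is available and the
  standardized solution is invariant to the choice (tested).

**Uncertainty.** The full asymptotic covariance \(\Gamma\) of the stacked
correlations is estimated from per-observation influence functions: exact
analytic influence for Pearson, an empirical two-stage influence for
polychoric (directional derivatives of the estimator with respect to the
cell proportions, which propagates threshold estimation exactly), and a
score/information influence for polyserial (thresholds treated as fixed —
the one approximation, acceptable at the 1% missingness and moderate
thresholds used here). Standard errors are sandwich-form
\((\Delta' W \Delta)^{-1} \Delta' W \Gamma W \Delta (\Delta' W \Delta)^{-1}\);
the test statistic uses the Satterthwaite mean-and-variance adjustment
\(T^\ast = T \cdot \mathrm{tr}(U\Gamma)/\mathrm{tr}((U\Gamma)^2)\) with
fractional adjusted degrees of freedom
\(\mathrm{tr}(U\Gamma)^2/\mathrm{tr}((U\Gamma)^2)\). The exact adjustment
variant used by commercial SEM software is not published; ours is validated
by its defining property — across 500 replications of a correctly specified
four-binary-indicator model at n = 540, the mean adjusted statistic is
within 1% of the mean adjusted df (the test suite asserts 10%).

**Fit indices.** RMSEA, CFI, TLI and SRMR are computed from the adjusted
statistic, as is conventional in WLSMV reporting, with thresholds
RMSEA < 0.06, CFI > 0.95, TLI > 0.95, SRMR < 0.08. The RMSEA denominator
uses \(n-1\) (configurable to \(n\); reference implementations differ).
TLI is deliberately not clamped at 1 — values slightly above 1 indicate
better-than-exact fit and are reported as such. The baseline model fixes
all correlations at zero; since thresholds are saturated in stage one it
has no free parameters.

**Heywood cases.** A negative implied residual variance (indicator or
latent disturbance) is flagged and reported, never silently truncated: the
near-degenerate visuospatial domain factor — its tests load heavily on g,
leaving little domain-specific variance — is an expected feature of this
model family, and the pipeline tolerates it with a flag.

**Optimization.** BFGS on the free parameters with numerically evaluated
gradients, relative convergence at a gradient norm below
\(10^{-6} \times \bar w\) (the weights scale with n, so an absolute
tolerance would be meaningless), at most 500 iterations and 5
deterministically jittered restarts. Flat polychoric likelihoods break
ties toward smaller |rho| via a microscopic ridge; estimates at the
boundary are clamped at |rho| = 1 − 1e-6 with a warning so pipeline runs
survive degenerate simulated draws.

## The synthetic cohort generator

`default_generating_parameters()` encodes the study conditions:

* **SVD marker loadings** are the square roots of the published
  communalities — 25%, 10%, 32%, 18% of variance in WMH/TIV, PVS count,
  lacunes, microbleeds — i.e. loadings (0.500, 0.316, 0.566, 0.424).
* **Marginals** match the published cohort table: lacunes 5.1% and
  microbleeds 12.0% present; PVS count mean 258.7 (SD 94.6); WMH/TIV mean
  0.008 (SD 0.009); age 72.6 (0.7); blood pressure, HbA1c, cholesterol,
  depression and age-11 IQ likewise.
* **Structural paths** default to the bifactor estimates (SVD→g −0.224,
  →speed −0.325, →memory −0.133, →visuospatial 0.075), since the
  generative cognitive model is the bifactor; recovery experiments for the
  separate-regression estimates set the g path to the corresponding table
  value with the domain structure switched off.
* **Cognitive loadings** use documented defaults in the published ranges
  (g loadings 0.5–0.8; domain loadings 0.3–0.6, smallest for the
  visuospatial tests so that the near-degenerate visuospatial factor is
  reproduced).
* **Covariate structure**: age is uncorrelated with SVD (the cohort is a
  single-year birth cohort, age SD 0.7 y); vascular risk correlates 0.20
  with SVD; age-11 IQ −0.10; covariate effects on g default to
  (−0.05, 0.03, −0.10, −0.10, 0.55) for age, sex, vascular risk,
  depression and age-11 IQ — childhood IQ dominating, as it does
  empirically. All are overridable.
* **Scan–test interval**: days between imaging and testing, N(65, 38)
  rounded and floored at zero (the design does not publish this marginal;
  a two-month mean gap is typical of multi-visit cohort waves), with a
  −0.002 SD/day linear effect on every manifest cognitive score.
  `residualize_for_interval()` removes it before modelling, exactly as the
  analysis prescribes.
* **Missingness**: 1% MCAR per cognitive column, mirroring "all cognitive
  variables had n ≥ 530" of 540.

Binary and ordinal indicators are produced by probit thresholding of
standard-normal continua (consistent with the reported standardized probit
loadings); continuous markers are linear in the latent and affinely
rescaled. The WMH/TIV marginal is normal by default: the real distribution
is right-skewed, but every model here consumes correlations only, so shape
is irrelevant to recovery; a moment-matched log-normal switch
(`wmh_distribution = "lognormal"`) exists for realism-sensitive uses.
What the generator deliberately does **not** emulate: images or spatial
lesion structure, scanner artefacts, informative missingness, count-valued
lacunes/microbleeds, or skew/kurtosis in the cognitive battery. Passing
recovery tests therefore demonstrate correctness of the estimators under
the model's own assumptions, not robustness to real-data pathologies.

## Design choices on open points

* The design text describes WLSMV as using a "logit link for continuous"
  variables; standard WLSMV treats continuous indicators linearly with
  probit thresholds for categorical ones, and that standard is what we
  implement.
* Whether the bifactor's domain factors were mutually orthogonal is not
  stated; the standard fully orthogonal bifactor is implemented (the
  orthogonality applies to disturbances once SVD and covariates are
  regressed in).
* The covariates regress onto all endogenous factors by default
  (`covariates_on = "all"`), with a `"g_only"` switch, since the original
  specification is ambiguous.
* The Williams comparisons score both predictors and outcomes per
  participant (regression factor scores for latents, the standardized
  observed column for WMH/TIV) and use the complete-case n; how latent
  uncertainty entered the published tests is unstated, so this
  observable-proxy convention is the documented default. Comparisons are
  oriented so that a negative t means the first predictor carries the
  larger association magnitude, matching the published sign convention.
* The FDR family is one BH correction per results grid (one per predictor
  table, one across the four bifactor paths), configurable to a global
  family; the published family is not recoverable from the printed values.
* Age-11 IQ enters standardized (raw-score entry is a linear rescaling and
  leaves standardized estimates unchanged).
* Factor scores use regression-method weights on the observed-scale
  correlation matrix, with latent-scale loadings attenuated through the
  thresholds (\(\lambda \sum_j \phi(\tau_j)/\mathrm{sd}(y)\)) for
  categorical indicators; participants are scored from whatever indicators
  they have, and the score column is standardized.

## Problem sizes used in validation

Recovery tests simulate n = 100,000 for acceptance-grade checks (three
Monte-Carlo SEs of the published values) and n = 10,000–30,000 for module
tests; replication-style properties use n = 540 — the study's own size —
with 30–500 seeded replications depending on the cost of each fit. One
deliberate deviation: the qualitative bifactor replication ("g and speed
paths significant, memory and visuospatial not") is asserted in aggregate
across replications rather than per replication, because at n = 540 the
speed-specific path (−0.325, SE ≈ 0.15–0.19 in both the published model
and our simulations) has roughly 60% per-replication power, so no correct
implementation can show the full significance pattern in ≥90% of draws.
The aggregate test checks unbiased recovery of the sign/magnitude pattern
and that the speed path is detected more often than the null domain paths.

## Known limitations

* Polyserial influence functions ignore threshold-estimation noise; with
  rare binary markers (5% lacunes) this slightly understates a few entries
  of \(\Gamma\). The chi-square calibration test bounds the practical
  effect.
* The full-weight (non-diagonal) WLS estimator, FIML, multi-group and
  longitudinal models are out of scope.
* Factor scores for categorical indicators use a linearized observed-scale
  approximation rather than EAP scoring; adequate for the comparison and
  covariate roles they play here.
* The generator's cognitive scores are z-scaled; raw test-score metrics
  (e.g. Moray House points) are not reproduced, only their correlation
  structure.
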