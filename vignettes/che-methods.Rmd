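---
title: "Methods: data-driven CHE thresholds and multilevel determinant models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven CHE thresholds and multilevel determinant models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical content of `chetools`: what the
data-driven catastrophic health expenditure (CHE) threshold is, how the
multilevel determinant models are fitted, what the synthetic survey
generator does and does not emulate, and the numerical and design choices a
maintainer should know about.

## Accounting identities and the threshold construction

Every household record carries monthly total, food and health expenditure.
The package enforces `nonfood = total − food ≥ 0` and `health ≤ nonfood`:
out-of-pocket health spending is treated as a component of nonfood
consumption, the standard capacity-to-pay accounting. Without that
inclusion a "health share of nonfood spending" could exceed one and the
nonfood-basis threshold would be ill-posed.

Shares (`health/nonfood`, `health/total`) are computed from household-level
monthly values; they are invariant to division by household size. Poverty
status is not, so poverty comparisons use per-capita values against the
per-capita poverty line `z`. Both poverty (`y < z`) and CHE ("share
*exceeds* threshold") use strict inequalities; the boundary cases have
measure zero in continuous data but the convention is fixed and tested.

The threshold for a region is the unweighted mean of the health-spending
share over the region's *qualifying* households — those non-poor on total
expenditure but poor once health spending is netted out. Two readings of
the averaging count are possible (qualifying households vs all households
in the region); the construction's verbal definition ("for the households
satisfying P = 0 and P′ = 1") forces the qualifying-set mean, and that is
what `region_threshold()` computes. Every qualifying household necessarily
has strictly positive health spending, which is asserted at run time.

A region with no qualifying household has an *undefined* threshold — `NA`,
never zero, since zero would label every household with any health spending
as CHE. `national_average()` skips undefined strata and reports the skip
count. The national average is unweighted across strata: the published
national values for the 2016 Bangladesh survey equal the unweighted mean of
the 16 regional rows (shipped in `published_region_thresholds()`), so no
household-count weighting is applied.

`run_pipeline()` additionally substitutes the national average for
undefined strata (`fill_undefined_thresholds()`) before labelling, with the
affected strata recorded. This is a pipeline-level convenience for
desk-scale runs, where a small rich stratum can easily have no qualifying
household; the low-level functions keep the strict error behaviour so the
substitution is always explicit.

## The wealth index

Asset indicators (any `asset_*` columns; the catalogue is not hard-coded)
are standardized to mean 0 and sample SD 1 (n−1 denominator; the
convention matters for reproducing scores and is therefore documented).
Zero-variance assets are dropped with a warning. The index is the first
principal component, computed by singular value decomposition; the loading
vector has unit norm and its sign is oriented so the loading sum is
positive (tie: first nonzero loading positive), making scores reproducible.
Quintiles are rank-based: rank `r` of `n` goes to group `ceiling(5r/n)`,
i.e. group `k` receives ranks in `((k−1)n/5, kn/5]`, with ties broken by
stable record order. Rank-based cuts guarantee near-equal group sizes even
with heavily tied binary-asset scores, which value-based quantile cuts do
not.

## Fixed and random-intercept logistic models

All model terms are indicator-coded categorical variables with fixed
reference levels (No / Poorest / City Corporation / Barisal / Female /
under-60), so the usual grand-mean-centering step for multilevel predictors
is a no-op for interpretation and is skipped. The fixed-effects model is
fitted by iteratively reweighted least squares with convergence declared at
score norm `1e-8` or relative log-likelihood change `1e-10` (maximum 200
iterations); coefficients diverging past ±30 raise an explicit separation
error rather than returning garbage.

The random-intercept model maximises the marginal likelihood

$$L(\beta, \sigma_u) = \prod_j \int \prod_i
  \mathrm{Bern}\!\left(y_{ij};\, \mathrm{logit}^{-1}(x_{ij}\beta + u)\right)
  \phi(u; 0, \sigma_u^2)\, du$$

with each cluster integral approximated by *adaptive* Gauss–Hermite
quadrature: nodes are recentred at the cluster's posterior mode (found by a
damped Newton iteration, vectorised over clusters) and rescaled by the
curvature there. Non-adaptive quadrature is inaccurate at cluster sizes
around 20 because the integrand concentrates away from zero. The default
is 15 nodes; the test suite checks that moving to 25 nodes changes the
log-likelihood by less than `1e-6` and that the approximation matches a
10,000-point trapezoid integration on small instances.

Optimisation is quasi-Newton (L-BFGS-B) over `(β, log σ_u)`, with
`log σ_u` bounded in `[−8, 3]` so a vanishing variance component terminates
cleanly: fits with `σ_u < 10⁻³` are reported as `σ_u = 0` with a `boundary`
flag. Standard errors come from the numerically differentiated Hessian at
the optimum; at a boundary fit the variance direction is flat and the
fixed-effect block of the information is used instead. Note that the
maximum-likelihood estimate of a truly zero variance component lands on the
boundary in only about half of finite samples — a positive estimate from
null data is estimator behaviour, not a defect.

The intraclass correlation is reported on the latent-logistic scale,
`ICC = σ_u²/(σ_u² + π²/3)`. The empty (intercept-only) model and the final
covariate model generally give different ICCs — omitting household-level
covariates changes the implicit level-1 variance — so the pipeline reports
both explicitly rather than leaving it ambiguous which model an ICC refers
to. The likelihood-ratio test for the variance component reports both the
naive chi-square(1) p-value and the 50:50 chi-square(0)/chi-square(1)
boundary-mixture p-value (half the naive one for positive statistics),
since published analyses rarely say which convention they used.

Generalized variance inflation factors use the determinant formula on the
correlation matrix `R` of the non-intercept design columns:
`GVIF = det(R_AA)·det(R_BB)/det(R)` for a term with column block `A`, with
`adjusted GVIF = GVIF^(1/(2·df))`. This is the design-correlation (linear
model) form; it reduces to the classical VIF for single-column terms.

## ROC evaluation

AUC is Mann–Whitney concordance computed from mid-ranks, with ties counted
one half; the suite verifies exact equality with pairwise enumeration. ROC
curves have one point per distinct score threshold plus the origin.
Evaluation is in-sample. Mixed-model scores use the cluster-specific linear
predictor including the empirical-Bayes mode of the cluster intercept; with
population-averaged scores (fixed part only) a mixed model could never
out-discriminate the fixed model in-sample, so the cluster-specific choice
is the one under which the fixed-vs-mixed AUC comparison is informative,
and it is documented as such. In `threshold_sensitivity()` a policy whose
labels defeat a model fit (e.g. quasi-complete separation under a very rare
label) yields `NA` AUCs with a warning instead of aborting the run.

## What the synthetic generator emulates — and what it does not

`generate_expenditure_survey()` reproduces the *structure* the analysis
relies on: 16 division-by-residence strata, districts and PSUs nested
within them, a fixed number of households per PSU (20 by default, as in the
emulated two-stage design), lognormal per-capita total expenditure with a
residence-specific level, a Beta-distributed food share (defaults centred
near 55% food, as is typical for Bangladesh), a two-part health-spending
model (logistic any-spending part, lognormal amount part) driven by chronic
disease, old age and latent wealth with a PSU-level normal random effect in
both parts, and binary assets from a one-factor model so the first
principal component is a meaningful wealth signal.

Default parameter choices, made once for realism: expenditure means
(2,600 / 2,900 / 3,200 currency units per person per month for rural /
urban / city corporation) with log-SD 0.4 against a poverty line `z =
2,200`, giving roughly a quarter of households below the line; health
amount intercept `log(50)` with log-SD 0.6, so 3–5% of households are
pushed below the line by health spending (the order of magnitude reported
for Bangladesh); and `psu_sigma = 0.3` on the latent health-spending scale,
which induces an empty-model cluster SD near 0.9 and a label-scale ICC
around 0.2 — the clustering magnitude national expenditure surveys show.
Covariate prevalences (chronic disease 0.35, old-age presence 0.18, child
presence 0.55, educated head 0.5, male head 0.87, head over 60 0.2) are
plausible household-survey rates.

The generator does **not** calibrate to the source survey's marginals, does
not model survey weights, non-response, informative cluster sizes,
measurement error in expenditure recall, or spatial correlation between
neighbouring districts. Passing tests on synthetic data therefore
demonstrate that the *algorithms* are correct under the assumed data law,
not that any particular published estimate is reproducible — the restricted
microdata would be needed for that.

A second generator, `generate_logit_outcome()`, simulates exactly the
random-intercept logistic law. Estimator recovery must be validated against
the law the estimator assumes, not against the structural expenditure model
(whose label process is not exactly a logit), which is why both exist.

## Problem sizes and tolerances used in the test suite

The suite validates at desk scale, chosen so a full run stays comfortable
on one CPU: the default synthetic design is 16 strata × 2 districts × 4
PSUs × 20 households = 2,560 households; oracle equivalence for the
threshold pipeline uses 100 random tables of at most 500 households at
`1e-12`; quadrature accuracy uses 20 instances of 10 clusters × 5
observations at `1e-6`; parameter recovery uses 25 replicates of 200
clusters × 20 households at the generating values `β_chronic = ln 5.45`,
`σ_u = 0.72` (mean bias below 0.05 on the log-odds scale, 95% CI coverage
within [0.88, 0.99], empty-model ICC within ±0.03 of the implied value).
Cross-checks against independent implementations (`stats::glm`,
`lme4::glmer` at matched quadrature, `car::vif` on a linear model,
`stats::chisq.test`) guard the self-implemented routines.

## Known limitations

- Models are two-level (household within PSU); the district and stratum
  levels are design variables, not variance components.
- No survey-weighted estimation; the determinant models are unweighted, as
  is common when weights are not available at the cluster level.
- Wald confidence intervals for odds ratios; profile intervals are not
  implemented.
- In-sample AUC only in the pipeline (no cross-validation).
- The subsistence-adjusted (capacity-to-pay) threshold family with
  food-need deductions is out of scope; the package implements the
  impoverishment-anchored construction and the two fixed conventional
  cutoffs.
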