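---
title: "Methods: latent personality profiles and long-term illness course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent personality profiles and long-term illness course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lpacourse)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters, the synthetic
cohort that stands in for non-shareable patient data, and the numerical and
design choices that were genuinely open.

## The latent profile model

The indicator vector is the five NEO-FFI scale scores per patient
(neuroticism, extraversion, openness, agreeableness, conscientiousness),
each the mean of 12 items on a 0–4 response scale. `lpa_fit()` estimates a
K-component Gaussian mixture under the classical latent-profile constraints:

* class-specific means `mu[k, j]`,
* indicator variances `sigma2[j]` **shared across classes**,
* zero covariance between indicators within class.

These constraints mean classes differ only in profile location, not spread
or shape; they keep the model identified in small clinical samples (the
free-parameter count is `5K + 5 + (K - 1)`, i.e. 10, 16, 22, ... for
K = 1, 2, 3, ...). The cost is well known: if real within-class
correlations are nonzero, the model can compensate with extra classes.
Class-varying variances and within-class covariances are deliberately out
of scope.

### Estimation

The EM iteration is standard — E-step responsibilities proportional to
`pi[k] * prod_j N(x[i,j]; mu[k,j], sigma2[j])`, M-step weighted means and a
variance pooled over classes — and is implemented in C++ with log-space
density accumulation and a row-wise log-sum-exp, so responsibilities never
underflow even for far-outlying patients. The log-likelihood is
non-decreasing by construction and is asserted as such in the tests.

Mixture likelihoods are multimodal, so `lpa_fit()` uses a multi-start
scheme: `n_starts = 500` random initialisations, each run for
`burn_iters = 50` EM iterations, after which the `n_survivors = 50` best by
log-likelihood are run to convergence and the best final solution wins.
Random starts draw class means uniformly within each indicator's observed
range, weights uniformly on the simplex, and set variances to the pooled
data variances — scale-free and bounded. All randomness comes from a user
seed; the same seed reproduces the fit exactly.

Numerical guards (none of which a well-posed fit ever touches):

* convergence when the absolute log-likelihood gain drops below `1e-6`,
  with a 1000-iteration cap;
* a variance floor of `1e-6` (clamped and flagged);
* a run whose smallest mixing weight falls below `1e-8` is declared
  degenerate and discarded by the multi-start scheme; if every start
  degenerates, fitting for that K fails loudly.

The K = 1 fit bypasses EM entirely: the closed-form MLE (column means,
divide-by-n variances) is exact and the tests verify EM cannot improve it.

### Model selection

`lpa_select()` tabulates, per K: free parameters, log-likelihood, relative
entropy (undefined at K = 1 and left `NA`), `AIC = -2LL + 2FP`,
`BIC = -2LL + FP log n`, and the sample-size-adjusted BIC, which replaces
`n` in the penalty with the conventional effective sample size
`(n + 2) / 24`. BIC is the primary selector; entropy and the bootstrap LRT
are reported alongside so the choice can be "empirically and conceptually
driven" rather than mechanical.

The parametric bootstrap likelihood ratio test (`bootstrap_lrt()`) compares
K vs K − 1: simulate B data sets from the fitted (K−1)-class model, fit both
models to each replicate, and rank the observed `2 * dLL` within the
replicate statistics, `p = (1 + #{LR_b >= LR_obs}) / (B + 1)`. The add-one
estimator bounds p below by `1/(B+1)`. Replicate fits use a lighter
multi-start (20 starts, 5 survivors) than the observed-data fit; failed
replicates are redrawn and counted, and more than 20% failures aborts. The
default is B = 99 inside tests and B = 999 for reported runs. The analytic
Vuong–Lo–Mendell–Rubin test is intentionally not implemented: its
approximation is proprietary to one software ecosystem and the bootstrap
test answers the same question.

Classes are relabelled after fitting (`canonicalize_classes()`) in
ascending order of the neuroticism mean — class 1 is the resilient profile,
class K the most vulnerable — with exact ties broken by descending
conscientiousness. The likelihood is invariant under this permutation.
Patients are assigned by modal posterior probability, ties toward the lower
class index.

## NEO-FFI scoring and the euthymia gate

`score_scales()` maps reverse-keyed items `x -> min + max - x` and scores
each scale as the mean of its valid items, which is algebraically identical
to ipsative mean imputation (each missing item replaced by the person's mean
of the scale's valid items). A scale with fewer than `min_valid_items = 6`
of 12 valid items fails to score; mean imputation is defensible only at the
low missingness rates this design expects (below 1%), so the threshold is
exposed rather than buried.

Two scoring decisions deserve a note. First, the internal response coding
defaults to 0–4 (the published German NEO-FFI item coding) rather than 1–5;
with 1–5 coding, observed class means near 1.0 on extraversion would be
impossible. The range is configurable and recorded in the scoring key.
Second, the proprietary NEO-FFI item key is not shipped: `score_*` functions
require a `scoring_key` (JSON-serialisable), and the synthetic generator
emits its own synthetic key (items interleaved across scales, a fixed third
reverse-keyed).

Personality assessment is only meaningful in euthymia, so the pipeline
excludes patients with HDRS-21 > 9 or YMRS > 12 (`euthymia_gate()`,
thresholds inclusive) before scoring and profiling.

## The Morbidity Index

`assign_degree()` grades each visit: hospitalization dominates (degree 3),
then treatment escalation (2), then syndromal symptoms by rating (HDRS-21 ≥
10 or YMRS ≥ 12 → 1), then the subthreshold band (HDRS-21 4–9 or YMRS 3–11
→ 0.5), else 0. When depression and mania imply different degrees the
maximum applies. Degree 1 is operationalised purely by the rating cutoffs:
the flags, not scores, decide degrees 2–3, since "needs more treatment" is a
clinician action, not a scale value.

`compute_mi()` divides the degree-weighted time by the observation span.
Attribution of a rating to time is configurable:

* `backward` (default): a visit's rating summarises the interval since the
  previous visit — follow-up ratings are retrospective by design;
* `forward` and `midpoint` are available for sensitivity analyses, since
  longitudinal studies differ on this convention and it is rarely stated.

The observation span is the time between first and last visit actually
attended, not the nominal study length. Eligibility requires no inter-visit
gap above 20 weeks and at least 8 weeks of observation; exclusions carry
their reason (`gap_too_long`, `observation_too_short`) into the pipeline's
accounting table. The index lives in [0, 3]; empirical cohort values rarely
exceed 1.5.

## Class validation and the missing-data check

`validate_classes()` runs the per-variable omnibus battery across classes.
Which variables are "parametric" (ANOVA with omega-squared) versus ranked
(Kruskal–Wallis with eta-squared) is a configuration mapping, not
hard-coded, because that judgement is data-dependent. Conventions worth
stating:

* `omega^2 = (SS_b - (k-1) MS_w) / (SS_t + MS_w)`; it is negative whenever
  F < 1, and is reported as such. If the within-group variance is zero
  everywhere the effect size is undefined and reported as 0 with a flag.
* The Kruskal–Wallis effect size is the H-based
  `eta^2 = (H - k + 1) / (n - k)`, floored at zero for reporting (the raw
  value is kept); the literature uses several formulas, so the choice is
  recorded in the result object.
* Mann–Whitney post hocs report `U`, the tie-corrected normal Z, Bonferroni
  adjusted p (multiplied and capped at 1), and `r = |Z| / sqrt(n1 + n2)`.
* The Freeman–Halton exact r×c test delegates to the exact conditional
  hypergeometric computation in `stats::fisher.test`; tables with totals
  above 200 use its Monte-Carlo estimate (1e5 tables, seeded) with the
  simulation SE reported. On 2×2 tables it coincides with the classical
  two-sided Fisher test.

Little's MCAR test is implemented in the package (no installed R package
provides it): the grand mean and covariance are estimated by EM over
missingness patterns under multivariate normality, then
`d^2 = sum_j n_j (xbar_j - mu_j)' Sigma_j^{-1} (xbar_j - mu_j)` accumulates
pattern-wise observed-mean distances, with `df = sum_j p_j - p`. Patterns
with a singular restricted covariance are dropped with a warning. Complete
data give statistic 0 with df 0 (p = 1). Calibration under genuinely MCAR
missingness is verified by simulation in the tests.

## The course regression

Predictor screening follows the parsimony rule: a candidate enters if its
Spearman correlation with the outcome, or with an already-selected
predictor, is significant at `alpha = 0.05` (pairwise-complete cases,
minimum 10 pairs). The candidate list is the a-priori clinical set —
co-morbidity count, age at onset, past episodes, rapid cycling — not a
data-dredged one.

`hierarchical_fit()` runs OLS on listwise-complete cases (so both steps use
the same sample; the screening stage is the only pairwise one, and both
sample sizes are logged). Step 2 adds class dummies with the resilient
class as reference. Reported per step: B, SE, standardized beta
(`B * sd(x) / sd(y)`), t, p, 95% CI, R², ΔR², the step-change F
`((dR2/q) / ((1 - R2_full) / (n - k_full - 1)))` and the omnibus F from its
R²-based closed form. Count predictors are entered untransformed; this is
recorded here rather than silently assumed. Generalisability uses Stein's
formula

```
R2_stein = 1 - [(n-1)/(n-k-1)] [(n-2)/(n-k-2)] [(n+1)/n] (1 - R2).
```

Diagnostics: externally studentized residuals (count beyond ±1.96), Cook's
distance, standardized DFBetas, the Durbin–Watson ratio, a
Lilliefors-corrected Kolmogorov–Smirnov test of the standardized residuals
(the plain KS null distribution is wrong when mean and variance are
estimated), and tolerance/VIF from `car::vif` with `tolerance = 1/VIF`.

## The synthetic cohort

The generator (`cohort_config()`, `simulate_cohort()`) emulates the study
design the package targets: 134 euthymic bipolar patients, a 3-class
structure over the five scales with weights 0.51/0.41/0.08, class-by-scale
means such as neuroticism 1.44/2.39/3.10 and conscientiousness
2.85/2.31/1.55, shared within-class SDs (0.430, 0.493, 0.537, 0.397,
0.395 — pooled from the per-class SDs), 0.8% MCAR item missingness, and
follow-up visits nominally every 8 weeks over a truncated-normal horizon
(mean 54.7, SD 34.9, range 1–122 weeks). Horizons below 8 weeks and
randomly missed visits (6% per visit) are allowed on purpose, so the
eligibility filter has realistic rejects of both kinds.

Item responses are generated to be *consistent with* a target scale score —
12 integers whose sum is `round(12 * score)`, then reverse-keyed for
storage — rather than through a full item-response model, because the
analysis consumes scale means only. Scoring the generated items therefore
recovers the generating score to within 1/24.

Visit-level severity uses the simplest mechanism that produces episode-like
runs and a calibratable Morbidity Index: a per-patient two-state
(well/symptomatic) Markov chain with class-dependent entry and persistence
probabilities, started from its stationary distribution. Symptomatic visits
draw a degree from a class-specific distribution over {0.5, 1, 2, 3}; well
visits are subthreshold with a small class-dependent probability. Ratings
and flags are then generated consistent with the intended degree, so degree
assignment round-trips exactly. The entry probabilities (0.187, 0.311,
0.502) were calibrated once, by numerically integrating the stationary mean
degree over the frailty distribution, so the class-wise expected Morbidity
Index sits at 0.30 / 0.53 / 0.90; the calibration constants live in
`default_severity_params()`, not in code.

Two structural links make the regression stage realistic: a standard-normal
patient frailty (chronicity) multiplies the expected past-episode count and
shifts the symptomatic-entry logit by 0.3 per SD, so illness history
correlates with outcome beyond class; and rapid-cycling probability rises
with log past episodes. Class-linked covariates mirror the target cohort:
onset earliest in the vulnerable class (means 29.3/24.5/27.3), co-morbidity
highest in the highly vulnerable class (0.20/0.29/1.25), plus marginal
frequencies for the binary variables. One documented discrepancy in the
source material — a prospective-subsample count of 8 versus 11 for the
smallest class — is resolved in favour of the class-size table, which the
weights reproduce.

What the generator does **not** emulate: medication regimes, suicidality
dynamics, diagnostic-subtype effects beyond marginal frequencies, non-MCAR
missingness, within-class indicator correlations, or state-dependent bias of
self-reported personality. Passing tests on synthetic data therefore show
that the estimators recover the structure they assume — not that real
cohorts satisfy those assumptions.

## Problem sizes used by the test suite

Simulation sizes were chosen as the smallest that make the checks sharp:
distributional checks of the generator at n = 20000 (3-standard-error
bands), class-mean recovery at n = 5000 (tolerance 0.05), BIC model
selection at n = 1000 over 10 replicates, bootstrap-LRT type-I error and
MCAR calibration at 200 replicates against 99% binomial bands, and the
Morbidity Index calibration at n = 2000 (tolerance 0.08 around the class
targets). The oracle for the EM is a direct numeric maximisation of the
same likelihood on 8-point instances (agreement to 1e-4), plus the
equal-variance diagonal model of `mclust` on larger ones.

## Known limitations

* The equal-variance, zero-covariance mixture is a modelling convenience;
  violations inflate the class count.
* The BLRT p-value inherits Monte-Carlo granularity `1/(B+1)`.
* Scoring assumes items missing at random within scale; ipsative imputation
  with heavy structured missingness would bias scores.
* The Morbidity Index treats ratings as piecewise-constant between visits;
  short-lived episodes between visits are invisible.
* Screening-then-fitting does not propagate selection uncertainty into the
  regression inference, matching field practice rather than fixing it.
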