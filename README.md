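# lpacourse

Personality-based subtyping of bipolar disorder and its impact on long-term
illness severity.

`lpacourse` implements an analysis chain for prospective bipolar-disorder
cohorts in which euthymic patients complete the NEO Five-Factor Inventory
(NEO-FFI) at baseline and are then followed with regular clinician ratings
(HDRS-21 for depression, YMRS for mania). The package is aimed at clinical
researchers who want to (1) identify latent personality classes from Big Five
scale profiles, (2) summarise each patient's longitudinal illness burden in a
single Morbidity Index, and (3) test whether class membership predicts that
burden over and above established clinical risk factors. Because patient-level
data of this kind cannot usually be shared, the package also ships a synthetic
cohort generator with the same statistical structure, so every stage of the
pipeline is testable end to end.

## The models at the core

**Latent profile analysis.** The five scale scores
\(x_i \in \mathbb{R}^5\) are modelled as a \(K\)-component Gaussian mixture
under the usual latent-profile constraints: class-specific means
\(\mu_{kj}\), indicator variances \(\sigma^2_j\) shared across classes, and
zero covariance between indicators,

\[
f(x_i) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{5}
  \mathcal{N}(x_{ij};\, \mu_{kj},\, \sigma^2_j).
\]

Models are fitted by expectation-maximisation (log-space accumulation, in
C++) with a multi-start scheme: 500 random starting value sets, 50 burn-in
iterations each, the 50 best by log-likelihood optimised to convergence.
Model selection over \(K = 1,\dots,6\) uses AIC, BIC, the sample-size
adjusted BIC (effective sample size \((n+2)/24\)), relative entropy
\(1 - \sum_{ik}(-p_{ik}\log p_{ik}) / (n \log K)\), and a parametric
bootstrap likelihood ratio test of \(K\) vs \(K-1\) classes. Classes are
reported in ascending order of the neuroticism mean, so class 1 is the
low-neuroticism "resilient" profile.

**Morbidity Index.** Each follow-up visit is graded on a modified degree
scale — 0 none, 0.5 subthreshold (HDRS-21 4–9 or YMRS 3–11), 1 syndromal
(HDRS-21 ≥ 10 or YMRS ≥ 12), 2 treatment escalation, 3 hospitalization — and
the index is the time-weighted mean degree over the observation span:

\[
\mathrm{MI} = \frac{\sum_v d_v \, \Delta t_v}{t_\text{last} - t_\text{first}}
  \in [0, 3].
\]

Patients with an inter-visit gap above 20 weeks or less than 8 weeks of
observation are excluded, with the reason recorded.

**Course regression.** A two-step hierarchical OLS regresses the Morbidity
Index on clinical predictors (co-morbidity count, age at onset, past
episodes, rapid cycling; screened by Spearman correlation) and then adds
dummy-coded classes with the resilient class as reference, reporting
\(R^2\), \(\Delta R^2\) with its F test, Stein's adjusted \(R^2\), and a full
diagnostics block (studentized residuals, Cook's distance, DFBetas,
Durbin–Watson, Lilliefors KS, tolerance/VIF). Class validation against
baseline variables uses exact r×c contingency tests with Cramér's V, one-way
ANOVA with \(\omega^2\), Kruskal–Wallis with \(\eta^2\), Mann–Whitney post
hocs with Bonferroni correction, and Little's MCAR test for the missing-data
pattern.

## Worked example

```r
library(lpacourse)

cohort <- simulate_cohort(cohort_config(n_patients = 134, seed = 7))
cfg <- pipeline_config(k_range = 1:4,
                       lpa_control = lpa_control(n_starts = 200), seed = 7)
res <- run_pipeline(cohort$baseline, cohort$visits, cfg)
print(res)
```

```
Exclusion accounting:
                    stage   n
                    input 134
             not_euthymic   5
          scoring_failure   0
             analyzed_lpa 129
          mi_gap_too_long   2
 mi_observation_too_short   4
              analyzed_mi 123

Model selection (lowest BIC at K = 3 ):
   model K fp loglik entropy    aic    bic   abic blrt_p
 1-class 1 10 -556.0      NA 1131.9 1160.5 1128.9     NA
 2-class 2 16 -508.0   0.772 1048.0 1093.8 1043.2     NA
 3-class 3 22 -486.1   0.854 1016.1 1079.0 1009.5     NA
 4-class 4 28 -480.8   0.847 1017.6 1097.7 1009.1     NA
Lowest BIC at K = 3 

Per-class Morbidity Index means: 0.283, 0.479, 0.905
Regression: R2 step1 = 0.037, final = 0.273, Stein = 0.189
```

Five of the 134 simulated patients fail the euthymia gate (HDRS-21 ≤ 9 and
YMRS ≤ 12) and six more lack adequate follow-up. BIC favours three latent
classes; `res$model` shows the canonical profile shape (class 1: low
neuroticism, high extraversion/agreeableness/conscientiousness; class 3 the
mirror image, 7% of the sample). The per-class Morbidity Index means rise
with vulnerability, and adding the class dummies lifts the regression
\(R^2\) from 0.04 to 0.27. `plot_class_profiles(res$model)` draws the class
profile figure.

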