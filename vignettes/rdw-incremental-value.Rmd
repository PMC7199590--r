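---
title: "Assessing the incremental prognostic value of RDW in ARDS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the incremental prognostic value of RDW in ARDS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdwards)
```

## The scientific question

Red cell distribution width (RDW) is the coefficient of variation of red
blood cell volume, reported as a percentage on every complete blood count.
Elevated RDW tracks systemic inflammation, impaired erythropoiesis and
reduced physiological reserve, and has repeatedly been associated with poor
outcomes in critical illness. `rdwards` implements the analysis needed to
ask a sharper question than "is RDW associated with death?": *does RDW add
predictive information beyond a clinical base model* for mortality in acute
respiratory distress syndrome (ARDS), and *does the shape of a patient's RDW
time course during the stay carry prognostic information of its own?*

Because patient-level ICU datasets of this kind are access-restricted, the
package pairs the analysis pipeline with a synthetic cohort generator whose
defaults are calibrated to the published summary statistics of a 318-patient
ARDS cohort. Every stage of the pipeline can therefore be validated
end-to-end on data with known generating truth.

## Risk models

For each outcome (ICU, in-hospital, 90-day death — logically nested, and the
data model enforces the nesting) two logistic regressions are fitted by
maximum likelihood:

* **base**: age (years), sex (male indicator), comorbidity-count category
  (0 / 1 / 2 / ≥3 conditions, dummy-coded against "0"), SOFA score, and the
  first documented PaO~2~/FiO~2~ (per mmHg — note the odds ratio is reported
  per unit, so values like 0.996 are expected);
* **enhanced**: base plus baseline RDW (%, the measurement closest to ARDS
  diagnosis).

Fitting is IRLS (via `glm`) with a relative deviance tolerance of 1e-8 and a
50-iteration cap; a fit that hits the cap is flagged and `odds_ratios()`
refuses to report it. Separation is surfaced as non-convergence rather than
silently penalised. Confidence intervals are Wald
(`exp(b ± 1.96·SE)`); profile-likelihood intervals are out of scope.
Missingness is handled by refusal: any missing required field is a
validation error naming the row and field, because silent listwise deletion
changes the estimand without telling the analyst.

## Quantifying added value

`compare_models()` evaluates three complementary metrics on in-sample
(apparent) predicted probabilities, matching how incremental-biomarker
analyses of this size are conventionally reported:

* **Paired AUC difference (DeLong).** Mann–Whitney AUCs (ties count ½) and
  the nonparametric placement-value variance of the paired difference. When
  the two prediction vectors are identical the variance collapses; the
  difference is then reported as 0 with p = 1.
* **Continuous NRI.** Net proportion of events whose predicted risk rises
  plus net proportion of non-events whose risk falls. Exact ties count in
  neither direction (an explicit choice; with continuous predictors they
  occur only when the models coincide). The asymptotic SE is
  `sqrt(v_e/n_e + v_ne/n_ne)` with `v = p_up + p_down − (p_up − p_down)²`
  per outcome group. The *net* (category-free, both-directions) definition
  is the default; the one-directional *gross* variant — the sum of the raw
  proportion of events moving up and non-events moving down, which matches
  a common verbal description of the statistic — is available via
  `variant = "gross"` for comparison.
* **IDI.** Difference in mean risk change between events and non-events,
  reported with all four group means so the components can be recombined
  and checked against the total.

A stratified percentile bootstrap (resampling patients within outcome
groups, default 2,000 seeded replicates) is available as an alternative CI
method for NRI and IDI, since their small-sample distributions can be
noticeably non-normal.

**Known limitation — nested-model AUC testing.** When the added predictor
has *no* true effect and both models are refitted on the same data, the
in-sample AUC difference is of order 1/n rather than 1/√n, and the DeLong
z-statistic collapses toward zero: the test is strongly conservative for
nested model comparisons (rejection rate near 0 at nominal 5% in the
package's own null simulations). This degeneracy is a property of the
procedure as conventionally applied — and reported here exactly as
conventionally applied — not of the implementation; the bootstrap option
does not repair it. Interpret a *small* nested-model DeLong p-value as
strong evidence, and a large one as close to uninformative.
Apparent (in-sample) performance is likewise reported without optimism
correction, as is conventional for this design; no cross-validation is
attempted.

## Trajectory classification

Patients with at least `min_obs = 4` RDW measurements get an ordinary
least-squares fit `RDW = b₀ + b₁·t + b₂·t²` (t in days since diagnosis) with
two-sided t-tests on `b₁` and `b₂` (residual df = n − 3). The decision rule
is sequential, quadratic first:

1. `p(b₂) ≤ α` → **concave** (`b₂ < 0`, rises then falls → late-falling) or
   **convex** (`b₂ > 0`, falls then rises → late-rising);
2. otherwise `p(b₁) ≤ α` → **uptrending** / **downtrending**;
3. otherwise **no trend**.

with α = 0.05 two-sided. Numerical edge cases are handled explicitly: an
exact fit (zero residual variance) makes the t-tests undefined, so a
coefficient then counts as significant iff its magnitude exceeds 1e-10; a
patient with ≥ 4 measurements but fewer than 3 distinct times leaves the
quadratic unidentified and is excluded with a flag. Classification is
invariant to shifting all RDW values and to rescaling time (coefficients
transform as `b₁/c`, `b₂/c²`).

Per-patient classification deliberately uses independent per-patient OLS
fits rather than BLUPs from one mixed model: a per-patient significance test
is only fully specified in the former reading, and shrinkage of BLUPs toward
the population mean would make "significance of a patient's own quadratic
term" ill-defined. The mixed model (`fit_mixed_model`, ML via `lme4`, random
intercepts and slopes) is retained as the cohort-level description of the
RDW time course.

Two structural properties of the significance-rule classifier are worth
keeping in mind when reading class frequencies. First, a truly stable series
is classified as trending roughly α-often at each of the two sequential
tests, so with a dominant no-trend class (~64% in the calibration target)
the recovered no-trend share is biased a few percentage points low and the
trend classes correspondingly high, *even at high signal-to-noise*. Second,
at realistic measurement noise (σ ≈ 0.3% RDW) and ~5 measurements per
patient, most genuinely trending patients lack the power to reach
significance and fall into "no trend" — visible in the worked example in the
README. Class counts are therefore a function of measurement density as much
as of biology.

Association between class and in-hospital mortality is tested with the
uncorrected Pearson chi-square and with Fisher exact tests: 2×2 by direct
hypergeometric enumeration under the point-probability two-sided rule (sum
of tables as or less probable than the observed one — the dominant
convention), R×C by exact conditional enumeration where feasible and
otherwise by seeded Monte-Carlo sampling of same-margin tables (Patefield's
algorithm; p-value with the standard +1 pseudo-count). No Yates correction
is applied anywhere. On the published 5×2 trajectory–mortality counts the
uncorrected chi-square gives 4.63 (df 4, p = 0.327) and the exact test
p = 0.337; on the pooled late-rising vs late-falling 2×2 the chi-square
gives p = 0.044 and the exact test p = 0.065 — the package reports both and
takes no position on which a given historical p-value came from.

## The synthetic cohort generator

The generator's defaults *are* the study conditions; they are chosen once
from the published summary tables and are not tuned afterwards.

| quantity | default | source / rationale |
|---|---|---|
| n | 318 | published cohort size |
| age | N(58.6, 18.3²) trunc [18, 100] y | published mean (SD); adult ICU plausibility bounds |
| male | 51.9% | published |
| SOFA | round N(10.1, 4.6²) clip [0, 24] | published; score range |
| PaO₂/FiO₂ | N(140.8, 73.3²) trunc [40, 400] mmHg | published; physiologic range |
| baseline RDW | N(15.3, 2.3²) trunc [11, 30] % | published; assay range |
| comorbidity cat. | (0.30, 0.30, 0.20, 0.20) | joint count distribution unpublished; configurable |
| ICU-death ORs | 1.05, 1.53, 1.02, 0.88, 0.84, 1.08, 0.995, 1.22 | published enhanced model |
| intercept | bisected to 35.5% ICU mortality | published rate; tolerance 0.001 on a 10n-sized draw |
| q_hosp | 0.1318 | solves 0.355 + 0.645·q = 0.440 in-hospital rate |
| q_90 | 0.08 | 90-day marginal rate unpublished; plausible post-discharge attrition (~48.5% at 90 days) |
| trajectory mixture | 26/24/174/29/19 of 272 | published class counts |
| class mortality | 8/26, 8/24, 70/174, 14/29, 11/19 | published class-conditional in-hospital deaths |
| measurements | 2 + Poisson(3.42) | gives P(≥4) ≈ 0.855 = 272/318 |
| follow-up | 14 d, times uniform | typical ARDS ICU course |
| noise σ | 0.3% RDW | realistic analyzer + biologic variation |
| trend sizes | \|b₁\| ∈ [0.2, 0.4] %/d; \|b₂\| ∈ [0.02, 0.05] %/d², vertex 4–9 d | pre-specified power analysis: ≥ ~90% per-class recovery at σ = 0.1 with 10 measurements |

Covariates are generated independently (only marginals are published);
truncation is by inverse-CDF, which costs exactly one uniform per variate
and shifts the realised means slightly above the untruncated targets (about
+0.17% RDW, +12 mmHg PaO₂/FiO₂) — well inside the Monte-Carlo tolerances the
calibration is checked against. Each sampling block runs on its own
deterministic substream of the master seed, so a given configuration
reproduces bit-identical tables and enlarging `n` appends patients without
perturbing earlier draws.

Two mortality-generation modes exist because the cross-sectional outcome
model and the class-conditional trajectory mortality cannot both be exactly
generative at once. In the default `"model"` mode, ICU death follows the
logistic model and in-hospital/90-day deaths extend it with the conditional
probabilities above. In `"class-linked"` mode, in-hospital death is drawn
from the patient's trajectory-class rate and ICU death is a thinned subset
(probability 0.355 / 0.408, preserving the nesting and both targeted
marginals); use this mode to study the trajectory–mortality association
with known truth.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: covariate correlation (age–SOFA, severity–PF),
informative measurement timing (sicker patients are sampled more often),
death-truncated follow-up, secular assay drift, and any causal structure
linking the trajectory to the covariates. It validates the *statistical
machinery*, not the clinical claim.

## Validation design

The test suite checks every estimator against an independent route computed
at small scale: AUC against exhaustive pair counting; the 2×2 Fisher test
against direct binomial-coefficient enumeration; the chi-square statistic
against the textbook formula on random tables; per-patient quadratic fits
against an explicit normal-equations solve; DeLong variances against a
paired bootstrap and against an independent reference implementation; NRI
and IDI against hand-enumerated examples. Simulation-based checks use
pre-specified sizes: odds-ratio recovery over 100 cohorts of n = 5,000
(each generating OR inside its fitted 95% CI in ≥ 90% of replicates, with
the enhanced model beating the base AUC in ≥ 95%), test size under a null
RDW effect over 2,000 cohorts of n = 300, and per-class trajectory recovery
over 500 series per class at σ = 0.1. The nominal-size check documents the
nested-model conservatism discussed above.

## Known limitations

* Apparent (in-sample) performance only; expect optimism at n ≈ 318.
* The DeLong comparison of nested in-sample models is strongly conservative
  under the null (see above).
* The trajectory classifier's class shares carry a structural α-level bias
  and are power-limited at realistic measurement density.
* Restricted cubic spline linearity diagnostics for the continuous
  predictors are a recognised follow-up and are not implemented; linear
  terms are used throughout.
* The generator draws covariates independently and does not model
  informative observation processes.
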