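# rdwards

Does red cell distribution width (RDW) — the coefficient of variation of red
blood cell volume, printed on every complete blood count — add prognostic
value to a clinical mortality model for acute respiratory distress syndrome
(ARDS)? `rdwards` implements the full analysis a biostatistician would run to
answer that question, plus a calibrated synthetic ICU cohort generator so the
whole pipeline can be exercised, tested, and taught without access to
restricted patient-level ICU data.

It is aimed at clinical researchers and biostatisticians evaluating the
*incremental* value of a biomarker on top of an established risk model.

## What it computes

**Risk models.** For each of three nested mortality outcomes (ICU death ⇒
in-hospital death ⇒ 90-day death) it fits two logistic regressions by maximum
likelihood:

- *base*: `logit P(death) = β₀ + β₁·age + β₂·male + β₃..₅·comorbidity
  category + β₆·SOFA + β₇·PaO₂/FiO₂`
- *enhanced*: base + `β₈·RDW` (baseline RDW, % — the value closest to ARDS
  diagnosis)

reported as odds ratios `exp(β)` with Wald 95% CIs.

**Added value of RDW** (the core of the package), comparing the two nested
models on the same patients:

- paired AUC difference with the DeLong placement-value variance:
  `Var(ΔAUC) = Var(V₁₀ⁿᵉʷ − V₁₀ᵇᵃˢᵉ)/n₁ + Var(V₀₁ⁿᵉʷ − V₀₁ᵇᵃˢᵉ)/n₀`;
- continuous (category-free) net reclassification improvement,
  `NRI = [P(up|event) − P(down|event)] + [P(down|non-event) − P(up|non-event)]`,
  with its event/non-event components;
- integrated discrimination improvement,
  `IDI = Δmean p̂(events) − Δmean p̂(non-events)`,
  with the four group mean predictions.

**RDW trajectories.** Each patient with ≥ 4 longitudinal RDW measurements
gets a per-patient quadratic fit `RDW = b₀ + b₁t + b₂t²` over days since
diagnosis. A significant quadratic term classifies the series concave
(`b₂ < 0`) or convex (`b₂ > 0`); otherwise a significant linear term gives
uptrending/downtrending; otherwise no trend. Convex + uptrending form the
late-rising group, concave + downtrending the late-falling group, and
class–mortality association is tested with Pearson chi-square and Fisher
exact tests (2×2 by hypergeometric enumeration; R×C exact or seeded
Monte-Carlo via Patefield sampling). A cohort-level mixed model (random
intercepts and slopes) describes the average RDW time course.

**Synthetic cohorts.** `generate_cohort()` draws covariates from truncated
marginals matching the published ARDS cohort (age 58.6 ± 18.3 y, 51.9% male,
SOFA 10.1 ± 4.6, PaO₂/FiO₂ 140.8 ± 73.3 mmHg, RDW 15.3 ± 2.3%), ICU death
from the enhanced-model odds ratios with an intercept bisected to the 35.5%
target rate, nested secondary outcomes, and five-class RDW trajectory series.
Generation is deterministic per seed and prefix-stable in `n`.

## Worked example

```r
library(rdwards)

cfg <- default_config(n = 318, seed = 2020)
sim <- generate_cohort(cfg)

fit_logistic(sim$cohort, model_spec("icu", include_rdw = TRUE))
#> Logistic model for icu mortality (base + RDW)
#>   n = 318, events = 118, deviance = 359.09, converged = TRUE
#>   age                OR  1.06 (1.04, 1.07)
#>   male               OR  1.58 (0.95, 2.63)
#>   ...
#>   rdw_baseline       OR  1.12 (1.00, 1.26)

compare_models(sim$cohort, "icu")
#> Added value of RDW for icu mortality (n = 318, events = 118)
#>   AUC  base 0.745  +RDW 0.752  delta 0.006 (-0.009, 0.021)  p = 0.433
#>   NRI  0.254 (0.029, 0.479)  p = 0.0272  [events +0.034, non-events +0.220]
#>   IDI  0.012 (0.000, 0.023)  p = 0.0417

classify_cohort(sim$rdw_long)
#> RDW trajectory classification: 318 patients (46 excluded, < min measurements)
#>   concave    14 ( 5.1%)
#>   down        6 ( 2.2%)
#>   none      234 (86.0%)
#>   convex     14 ( 5.1%)
#>   up          4 ( 1.5%)
```

Read the output as a clinician would: each unit of baseline RDW multiplies
the odds of ICU death by ~1.12 after adjustment; the NRI of 0.25 says the
net proportion of patients moved in the correct risk direction by adding RDW
is 25%; at n = 318 a true RDW odds ratio of 1.22 yields a detectable but
modest AUC gain, which is exactly the situation the published analysis
describes. At this realistic measurement noise most trajectories are
classified "no trend"; `vignette` discusses why.

`run_pipeline()` chains every stage and writes `report.json` / `report.txt`
(plus the simulated CSVs and a provenance record), either from a
configuration (simulate mode) or from your own cohort and long-format RDW
CSVs (user mode). A thin CLI over the same functions ships in
`inst/cli/rdwprog`.

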