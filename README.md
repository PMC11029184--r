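# rsindex

Enhanced risk scoring for patients discharged from intensive care.

Patients who leave an intensive care unit (ICU) for a general ward remain at
elevated risk: some die in hospital, some are readmitted to the ICU. Ward
surveillance usually relies on generic Early Warning Scores (EWS) computed
from spot vital signs, which ignore everything known about the patient at
ICU discharge. `rsindex` implements a two-component alternative, the **Risk
Score Index (RSI)**, together with four published EWS baselines, an
observation-level evaluation framework, and a seeded synthetic cohort
generator for end-to-end verification.

## The model

Two scores on [0, 1] are blended with a weight that hands over from the
static to the dynamic component during the first days on the ward:

```
RSI(t) = beta * (1 - tau(t)) * RS1  +  tau(t) * RS2(t),
tau(t) = min(t, T_max) / T_max
```

with `t` hours since ICU discharge. At `t = 0` the index is `beta * RS1`
exactly; from `T_max` onwards it is `RS2(t)` exactly.

- **RS1** — static risk of the compound outcome (in-hospital death or ICU
  readmission), an L1-regularised logistic regression over ~150 summaries of
  the ICU stay (`fit_rs1()`, penalty chosen by stratified cross-validated
  AUROC; the lasso performs the feature selection).
- **RS2** — dynamic vital-sign novelty: a product-Gaussian kernel density
  model of *normal* post-ICU physiology fitted to discharge-day observations
  of event-free admissions (`fit_normality_model()`); novelty (−log density)
  is mapped to [0, 1] through the training ECDF (`rs2_score()`). Missing
  vitals are marginalised exactly.
- **Baselines** — table-driven MEWS, SEWS, NEWS and CEWS
  (`load_scoring_table()`, `score_ews_cohort()`), with band files validated
  for full coverage, no gaps and no overlaps.
- **Evaluation** — time-window observation labelling
  (`label_observations()`), midrank AUROC with admission-grouped percentile
  bootstrap (`auroc()`, `bootstrap_ci()`), Hosmer–Lemeshow / Brier / Cox
  calibration (`calibration_report()`), trigger-burden curves
  (`trigger_burden()`), and like-for-like system comparison
  (`compare_systems()`).

## Worked example

Generate a synthetic post-ICU cohort at study conditions (6.6 % ICU
readmission and 2.2 % in-hospital death among included admissions, ward
observations every 4–6 h for up to 14 days), then run the full
development/validation pipeline:

```r
library(rsindex)

gen <- generate_cohort(synthetic_config(n_admissions = 2000, seed = 7))
gen$cohort
#> cohort_tables: 2000 admissions, 550824 channel rows, 64525 observation sets, 1794 outcomes

res <- run_rsi_pipeline(gen$cohort, seed = 7, horizons = c(24, 48), B = 0)
res$fusion
#> fusion_parameters: beta = 2, t_max = 336 h
print(res$comparison, digits = 3)
#>    system horizon endpoint auroc ci_low ci_high n_obs n_pos
#> 1    MEWS      24 compound 0.860     NA      NA 32160   308
#> 2    SEWS      24 compound 0.854     NA      NA 32160   308
#> 3    NEWS      24 compound 0.899     NA      NA 32160   308
#> 4    CEWS      24 compound 0.804     NA      NA 32160   308
#> 5     RS2      24 compound 0.761     NA      NA 32160   308
#> 6     RS1      24 compound 0.724     NA      NA 32160   308
#> 7     RSI      24 compound 0.815     NA      NA 32160   308
#> 8    MEWS      48 compound 0.725     NA      NA 32160   587
#> 9    SEWS      48 compound 0.713     NA      NA 32160   587
#> 10   NEWS      48 compound 0.749     NA      NA 32160   587
#> 11   CEWS      48 compound 0.676     NA      NA 32160   587
#> 12    RS2      48 compound 0.642     NA      NA 32160   587
#> 13    RS1      48 compound 0.722     NA      NA 32160   587
#> 14    RSI      48 compound 0.744     NA      NA 32160   587
```

Every system is scored on the identical labelled validation observations
(the audit of shared label counts is in `attr(res$comparison, "audit")`).
Individual pieces are usable on their own:

```r
news <- load_scoring_table("NEWS")
score_ews(news, list(heart_rate = 115, systolic_bp = 120, resp_rate = 16,
                     temperature = 37, spo2 = 98, supplemental_o2 = FALSE,
                     avpu = "A"))$score
#> [1] 2
```

Cohorts round-trip through plain CSV directories (`write_cohort()` /
`read_cohort()`, ISO-8601 timestamps) and fitted models through JSON
(`write_model()` / `read_model()`).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model, the
parameters and their defaults, the evaluation framework, and the design and
limits of the synthetic generator.
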