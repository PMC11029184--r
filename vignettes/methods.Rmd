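---
title: "Methods: a continuously updated risk score for post-ICU ward patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a continuously updated risk score for post-ICU ward patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Patients discharged from an intensive care unit (ICU) to a general ward
remain at elevated risk of deterioration: a fraction die in hospital or are
readmitted to the ICU. Ward surveillance is usually driven by generic Early
Warning Scores (EWS) computed from spot vital-sign observations. Those
scores ignore everything known about the patient at the moment of ICU
discharge. `rsindex` implements and evaluates a two-component alternative.

## The model

Two scores, both on $[0, 1]$, are blended with a weight that shifts from the
static to the dynamic component over the first days on the ward:

$$
\mathrm{RSI}(t) \;=\; \beta\,\bigl(1 - \tau(t)\bigr)\,\mathrm{RS}_1
\;+\; \tau(t)\,\mathrm{RS}_2(t),
\qquad
\tau(t) = \frac{\min(t, T_{\max})}{T_{\max}},
$$

where $t$ is the time in hours since ICU discharge. At $t = 0$ the index is
$\beta\,\mathrm{RS}_1$ exactly; for $t \ge T_{\max}$ it is
$\mathrm{RS}_2(t)$ exactly. These two identities are enforced at machine
precision in the test suite. Defaults: $\beta = 1$, $T_{\max} = 72$ h when
not tuned; `run_rsi_pipeline()` tunes both on development data by
patient-grouped cross-validation at the 24 h horizon over
$\beta \in \{0.25, 0.5, \dots, 2\}$ and
$T_{\max} \in \{24, 48, 72, 96, 120, 168, 336\}$ h, breaking ties toward
smaller $\beta$, then smaller $T_{\max}$.

### RS1 — static risk at ICU discharge

An L1-regularised logistic regression on summaries of the ICU stay
(`default_feature_spec()`: last/min/max/mean/slope and related summaries of
20 routinely charted ICU channels, plus age, sex, ICU length of stay, and
recent intervention indicators such as ventilation in the last 24 h;
about 150 candidate features). Preprocessing (median imputation and
z-scoring) is fitted on the training admissions only and stored inside the
model. The regularisation path starts at
$\lambda_{\max} = \max_j |Z_j^\top (y - \bar y)| / n$ — the smallest
$\lambda$ giving the null model — and descends over 30 log-spaced values;
$\lambda$ is selected by stratified 5-fold cross-validated AUROC. The L1
penalty performs the feature selection: typically a few dozen features are
retained. Outputs are probabilities, used directly as $\mathrm{RS}_1$.

### RS2 — dynamic vital-sign novelty

A one-class model of "normal" post-ICU physiology: a product-Gaussian
kernel density estimate over the five ward vital signs (heart rate,
systolic blood pressure, respiratory rate, temperature, SpO2), z-normalised
and fitted to discharge-day observations of event-free admissions (capped
at 10,000 points by seeded subsampling). Per-channel bandwidths follow
Silverman's multivariate rule
$h_j = \sigma_j \{4 / ((d+2)n)\}^{1/(d+4)}$. Novelty is the negative log
density, computed blockwise with log-sum-exp for stability. Missing
channels are handled by exact marginalisation (a product kernel
marginalises by dropping factors) or rejected under `strict` policy.
Because the fusion needs a bounded score, $\mathrm{RS}_2$ is the training
ECDF of self-novelty (midpoint tie convention): 0.95 means "more novel than
95 % of normal discharge-day observations". The ECDF is rank-preserving, so
discrimination is unchanged.

## EWS baselines

Four published systems — MEWS, SEWS, NEWS, CEWS — are implemented as
table-driven band scorers from CSV charts in `inst/extdata/ews/`. Bands are
closed intervals on the measurement precision grid (integer vitals, 0.1 °C
temperature), so full coverage, no gaps and no overlaps are validated
exactly at load time. The CEWS chart is published as a centile scheme; the
bundled transcription is approximate and user-replaceable (pass a file path
to `load_scoring_table()`). Missing components score 0 under the default
`zero` policy or raise an error under `strict`.

## Evaluation framework

Evaluation is at the observation level. `label_observations()` labels each
ward observation positive if the admission's first event (death or ICU
readmission) occurs in $(0, N]$ hours after it, censors observations at or
after the first event, and labels the rest negative; labels therefore nest
across horizons and partition each cohort exactly. Discrimination is
midrank (Mann–Whitney) AUROC, with confidence intervals from an
admission-grouped percentile bootstrap ($B = 500$ by default) so repeated
observations of one patient are never split across resamples. Calibration
reporting includes the Hosmer–Lemeshow C statistic over equal-count
deciles, the Brier score, and Cox's intercept/slope recalibration
(`glm(y ~ qlogis(p))`). `trigger_burden()` reports, per threshold, the
number of triggers per true positive — the workload a ward team pays per
caught deterioration. `compare_systems()` scores every system on the
identical labelled observation set and attaches an audit of the shared
label counts.

## Synthetic cohort generator

Real post-ICU cohorts are not publicly deposited, so the package ships a
seeded generator whose defaults mirror the study conditions the package is
designed for: 5000 ICU admissions; among those discharged alive and
included, 6.6 % ICU readmission and 2.2 % in-hospital death; ward
observations every 4–6 h for up to 14 days (truncated at hospital
discharge or death); exclusions for ICU death, palliative discharge,
inter-hospital transfer and unknown outcome.

Realism choices and their limits:

- **Between/within-patient structure.** Each admission draws per-channel
  baselines from population distributions, then ICU charts and ward vitals
  add AR(1) noise around them, so patients are internally consistent —
  necessary for a one-class normality model to be learnable.
- **Planted risk.** A latent risk score with fixed weights on standardised
  ICU summaries (e.g. lactate +0.7, age +0.5, systolic BP −0.35,
  ventilation in last 24 h −0.6) feeds a logistic link whose intercept is
  solved numerically so the mean event probability among included
  admissions hits the target 8.8 %. The negative ventilation weight
  reproduces a counterintuitive but reported clinical association and gives
  the sign-recovery tests a non-trivial target.
- **Deterioration signature.** Admissions destined for an event receive a
  deterministic vital-sign ramp over the 24 h before it (HR +25, RR +8,
  SBP −25, SpO2 −6, Temp +0.8, with AVPU and supplemental-O2 escalation
  late in the ramp). Determinism makes the counterfactual identity testable:
  with zero effect sizes and a common seed, trajectories are bit-identical.
- **Limits.** Vitals are conditionally Gaussian with linear ramps; there
  are no circadian cycles, medication effects, or measurement artefacts,
  and missingness is completely at random at configurable rates. The
  generator is an instrument for verifying the scoring and evaluation
  machinery at study scale, not a clinical simulator.

## Numerical choices

- Timestamps are integer-valued minutes since the Unix epoch internally
  (exact arithmetic at chart resolution); CSVs use ISO-8601; elapsed times
  are hours at the API surface.
- KDE densities use blocked matrix computation (4096 probes per block) with
  the log-sum-exp trick; memory stays below ~100 MB for the default
  10,000-point model.
- Band lookup snaps values to the chart precision grid with a 1e-9
  tolerance before `findInterval`, so 36.999999 °C and 37.0 °C score
  identically.
- Problem sizes in the test suite (n = 5000 cohort, 100,000-point EWS
  oracle grid, 200-replication bootstrap coverage study) are the package's
  own verification choices, sized to finish comfortably on one CPU.

## Reproducing the headline run

```{r}
library(rsindex)
gen <- generate_cohort(synthetic_config(seed = 1))
res <- run_rsi_pipeline(gen$cohort, seed = 1, horizons = c(12, 24, 48), B = 0)
res$comparison
```

or, from the shell, against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
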