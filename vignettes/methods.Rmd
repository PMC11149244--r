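---
title: "Methods: models, calibration and design choices in ckdlabscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in ckdlabscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdlabscan)
```

## The problem and the estimands

Laboratory databases record kidney-function testing as it actually happens:
serum creatinine ordered by many specialties, urinary proteinuria tests
ordered far less often, and in three incompatible modalities (quantitative
albumin-to-creatinine ratio, quantitative protein-to-creatinine ratio, and
semi-quantitative dipstick). `ckdlabscan` turns such a table into
patient-level estimands:

* the proportion of indexed patients whose creatinine was *paired* with a
  urinary result within 12 months;
* the KDIGO classification (G stage × A category → CKD flag and prognosis
  risk) of the classifiable population;
* the stage-stratified cumulative incidence of a *repeat* creatinine test.

The unit of analysis is the patient, anchored at the **index creatinine**:
the chronologically first creatinine in the study window. A per-test mode
is deliberately out of scope.

## Models and conversions

**eGFR.** The 2021 race-free CKD-EPI creatinine refit, adults only:
$\mathrm{eGFR} = 142 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
\max(S_{cr}/\kappa, 1)^{-1.200} \cdot 0.9938^{\mathrm{age}} \cdot
1.012[\mathrm{female}]$, with $\kappa = 0.7/0.9$ and
$\alpha = -0.241/-0.302$ (female/male). The coefficients are fixed
constants in `R/kidney_markers.R` (Inker et al., NEJM 2021). Creatinine is
handled in mg/dL; µmol/L inputs are divided by 88.42 on ingestion.

**pACR crosswalks.** Both conversion equations use the *natural*
logarithm — the exp/log pairing in the printed forms only makes sense that
way, and the source crosswalk method is natural-log based. The PCR map is
continuous and strictly increasing (clamp knots at PCR = 50 and 500 mg/g,
verified to 1e-8 relative in tests); the dipstick map is strictly
increasing across the five ordinal grades. Dipstick spellings from
different laboratories are normalised (`neg`, `-`, `1+`, `2+`, `3+`,
`+++`, … — everything above `++` falls into the `>++` bin). Quantitative
urinary albumin *concentration* (mg/L) without a urine creatinine cannot be
converted to a ratio; such records are counted as unusable rather than
guessed.

**KDIGO boundaries.** Published tabulations rarely state boundary
conventions, so they are declared once as constants: G bands are half-open
with the lower bound included (G1 ≥ 90, …, G5 < 15); A2 is the closed
interval [30, 300] mg/g. The 18-cell prognosis heatmap is transcribed and
unit-tested cell by cell. The CKD flag is single-assessment (no ≥90-day
chronicity requirement), matching the source analysis' stated assumption of
no false positives from single measurements; `require_chronicity = TRUE`
restores a confirmatory-eGFR rule for reuse, but no reported quantity uses
it.

## Tunable parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `pairing_window_days` | 365 | days | "12 months" read as 365 actual days, no month arithmetic |
| `pairing_direction` | both | – | the source text says "within 12 months" without direction; symmetric maximises test use |
| `hba1c_threshold` | 6.5 | % | diabetes if *strictly* above, per the lab-based definition |
| `glucose_threshold` | 200 | mg/dL | same, strictly above |
| `study_start`/`study_end` | 2018-06-01 / 2021-05-31 | – | study window; also the administrative censoring date |
| `condition_on_retest` | FALSE | – | KM on all indexed patients (censored) vs. only patients with ≥2 tests |

Pairing tie-breaks (equal day-distance): prefer the later record, then
quantitative ACR over PCR over dipstick, then the smallest `record_id`.
Index ties on the same date break by smallest `record_id` (assigned from
row order on read when the input carries none); all tie-breaks are
deterministic, so the pipeline is idempotent and row-order invariant.

## The synthetic generator: a stated world

The source database is proprietary, so validation is by **parameter
recovery** on a synthetic cohort whose latent structure *is* the published
composition: the analysis pipeline must independently re-derive eGFR from
creatinine (by numerical inversion in the generator, forward evaluation in
the pipeline), pACR from raw urinary values, stages from thresholds,
pairing from dates, and KM curves from event/censor times — and land back
on the configured proportions.

Calibrated defaults (all overridable in `generator_config()`): CKD
fraction 0.108 among paired patients with stage shares
(6.8, 8.3, 54.1, 22.1, 6.1, 2.6) % for G1…G5; per-stage pairing
probabilities (54.9, 61.2, 66.7, 70.7, 70.2, 46.7) %; per-stage A3
probabilities (0.3, 0.4, 1.2, 2.5, 7.3, 28.4) %; ages normal(69, 15.2) for
latent-CKD and normal(47.2, 15.4) otherwise, truncated at 18; diabetes
prevalence 22 %/8 % by latent CKD; 60 % female; specialty mix with
nephrology at 1.1 %. Retest processes are exponential per stage with
monthly hazards (0.1407, 0.1407, 0.15, 0.1527, 0.2524, 0.40) — the G1/G2,
G3b and G4 values are −ln(1−CI₆)/6 for the published 6-month incidences
(57 %, 60 %, 78 %); G3a interpolates its neighbours and G5 encodes
"highest"; a month is 365/12 days.

Where the source reports nothing, a value was chosen once and documented:

* **non-CKD G1:G2 split 55:45** — the marginal stage distribution over all
  tested patients is never reported; it is reconstructed from the paired
  composition plus per-stage pairing odds, and this split is the one free
  knob.
* **urinary modality mix (0.5, 0.3, 0.2)** for ACR/PCR/dipstick — not
  reported; every recovered proportion is insensitive to it because values
  are drawn *category-consistently* within each modality (ACR log-uniform
  in the category band; PCR inside the band mapped through the inverse
  crosswalk; dipstick from category-compatible tokens).
* **A1:A2 = 55:45 of the non-A3 mass in G3a–G5** — the cross-tabulation's
  interior is not fully constrained by the headline numbers.
* **true eGFR uniform within each stage band** (G1 truncated at 120, G5 at
  4, with a 1e-6 boundary margin) — the simplest distribution that makes
  stage recovery exact.
* **repeat creatinine records re-report the index value** — within-patient
  trajectories are a non-goal; retest *timing*, not value, is the estimand.

**Unpaired patients are added, not configured away:** for each stage,
`N_paired(G)·(1−p_G)/p_G` patients without urinary records join the
cohort, so `n_patients` counts *paired* patients and the overall unpaired
fraction (≈41.7 % at the defaults) is an emergent composite of the stage
mixture and pairing odds — recovering it end-to-end is one of the
acceptance checks precisely because no single parameter encodes it.

**Balanced sampling.** With `balanced_sampling = TRUE` (default), discrete
latent structure (stage cells, A categories, sex, diabetes, specialty,
modality, region) is allocated by largest-remainder rounding of expected
counts and then randomly assigned to patients; continuous quantities
(ages, dates, eGFR values, retest gaps) remain random. This is a
variance-reduction choice made a priori: the finite cohort realises the
stated proportions exactly up to rounding, so recovery failures indicate
pipeline defects, not sampling noise. `balanced_sampling = FALSE` gives
plain i.i.d. draws.

**What a green test does not establish.** The generator has no assay
noise, no creatinine trajectories, no seasonality, no regional structure,
no correlation between specialty and stage (per-stage specialty mixes are
supported but not defaulted), and exactly one urinary and one glycemic
record per patient on the happy path (multiplicity is exercised only in
unit fixtures). Recovery therefore validates the *logic* of the pipeline —
equations, thresholds, windows, estimators — not its robustness to
messiness a real extract would add, beyond what the filter tests cover.

## Numerical choices

* eGFR inversion: bisection on [0.05, 25] mg/dL to |ΔeGFR| < 1e-8, checked
  in tests against the closed-form piecewise inverse.
* KM ties: events precede censorings at the same time (standard
  product-limit convention; subjects censored at *t* remain at risk at
  *t*). Greenwood standard errors are computed in double precision — the
  at-risk counts of a population-scale cohort overflow 32-bit squares.
* All-censored strata return an identically-zero incidence with a warning;
  empty strata are omitted with a message; strata under `min_stratum_n`
  are flagged.
* Event times are integer days; gaps of an exponential draw are rounded up
  (`ceiling`), so a cumulative incidence evaluated at an integer day is
  unbiased for the continuous-time model at that day.
* JSON outputs are serialised with alphabetical keys at 6 significant
  digits, making re-runs byte-identical.

## Known limitations

Specialty attribution trusts the requisition field; the pACR panel uses
the urinary record's own specialty, the creatinine panels the index
record's. Calendar age is year-based (birth year only), so ages can be off
by up to one year relative to exact birthdates. The per-test analysis
mode, competing-risk estimators, Greenwood confidence *bands*, cystatin-C
equations and the 2009 race-coefficient CKD-EPI are out of scope.
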