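# ambuvalid

Validation of ambulatory wearable heart-rate monitors — wrist
photoplethysmography (PPG) bands, ECG shirts — against a criterion Holter ECG
worn simultaneously by children during 24-hour free living.

Validating a wearable in this setting is a pipeline, not a single statistic.
The devices run on unsynchronized clocks, report at different (and sometimes
irregular) rates, hide missing data behind zeros or constant fill values, and
degrade under bodily movement. `ambuvalid` implements every stage for
pediatric cardiology cohorts:

* **Criterion HR from R-R intervals** — trailing 16-beat moving average:
  `HR_k = 60000 / mean(rr_{k-15..k})`.
* **Clock synchronization** — the inter-device offset is the integer lag in
  ±60 s maximizing the Pearson cross-correlation on a common 1 s grid.
* **Pairing** — wearable BPM linearly interpolated onto criterion timestamps;
  zeros treated as missing; gaps > 60 s not bridged.
* **Missing-data classification** — *underdetected* (wearable-side missing or
  zero readings, counted against the nominal expected sample count) vs
  *erroneous* (criterion-side missing, excluded from all statistics), plus a
  sample-rate anomaly flag for streams that silently degrade to one sample
  per minute.
* **Agreement statistics** — within-10% (AAMI-style) accuracy, MAE, MAPE,
  Bland-Altman bias with 95% limits of agreement `bias ± 1.96·sd(d)`, and
  Lin's concordance correlation coefficient
  `ρ_c = 2·s_wc / (s_w² + s_c² + (w̄ − c̄)²)`, per participant and pooled.
* **Movement stratification** — intensity as the norm of first-differenced
  triaxial acceleration (gravity-insensitive), per-participant quantile bins,
  accuracy per bin, and an age-group × movement interaction regression.
* **Subgroup analysis** — between-participant (sex, age, BMI, wrist
  circumference, skin type, diagnosis) and within-participant (HR above/below
  own median, sleep/wake with a ±30 min diary guard, first/second 12 h)
  schemes with Shapiro-Wilk-gated parametric/nonparametric tests.
* **Comfort scores** — Likert composites, medians (IQR), paired Wilcoxon
  device comparisons.
* **A synthetic cohort generator** — seeded 24-hour pediatric recordings with
  circadian heart-rate structure, activity bouts, motion-coupled wearable
  error, dropout/zero-fill, clock offsets and an optional nighttime
  sample-rate defect, all traced in a ledger so every pipeline stage can be
  verified against known truth.

## Worked example

Simulate a small cohort with the default error model (clock offsets, −1.4 BPM
bias, motion-coupled noise, 2.5% zero-fill dropout), then run the full
pipeline on one participant and on the cohort:

```r
library(ambuvalid)

dir <- file.path(tempdir(), "demo-cohort")
gen_cohort(4, cohort_scenario(duration_s = 43200), seed = 42, out_dir = dir)

res <- validate_participant(read_participant(file.path(dir, "P01")))
res$sync
#> <sync_result> offset -18 s, peak correlation 0.9054 over 43182 samples
res$missingness
#> <missingness_report> underdetected 2.53% (zeros 1093, NA 0, absent 0 of 43188 expected), erroneous 0.00%
res$fit
#> Heart-rate agreement: P01 / wearable (63215 pairs)
#>   accuracy within 10%: 84.7%
#>   MAE 5.18 BPM, MAPE 5.62%
#>   Bland-Altman bias -0.72 BPM, 95% LoA [-14.87, 13.43]
#>   Lin CCC 0.941 (strong)

rep <- build_report(dir, config = list(boot = 500))
rep$cohort
#> Cohort agreement over 4 participants
#>   accuracy 79.9% (SD 4.2)   MAE 5.71 (SD 0.50) BPM   MAPE 6.41% (SD 0.68)
#>   pooled Bland-Altman bias -1.15 BPM, 95% LoA [-16.66, 14.36]
#>   mean CCC 0.919 (95% CI 0.904-0.934, participant_bootstrap) -> strong
rep$quantile_table
#>  quantile n mean_accuracy_pct sd_accuracy_pct
#>         1 4          87.23420        4.384717
#>         2 4          84.12592        4.007514
#>         3 4          80.00210        4.053642
#>         4 4          70.75336        5.941341
```

Reading the output: the recovered clock offset (−18 s here) is removed before
pairing; 2.53% of wearable samples were missing or zero (the injected dropout
rate was 2.5%); the per-participant panel shows the wearable reading within
10% of the Holter value 84.7% of the time with a small negative bias; and
cohort accuracy declines monotonically from the stillest to the most active
movement quartile — the motion-artifact signature these devices show in real
cohorts. `plot(res$fit)` draws the Bland-Altman plot;
`build_report(dir, out_dir = ...)` additionally writes `report.json`,
`participants.csv` and `report.md`.

Data on disk are plain CSV/YAML, one directory per participant; see
`inst/extdata/SCHEMAS.md` and the example files next to it.

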