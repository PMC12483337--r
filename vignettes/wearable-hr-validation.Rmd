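---
title: "Validating wearable heart-rate monitors against Holter ECG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable heart-rate monitors against Holter ECG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wrist photoplethysmography (PPG) bands and ECG shirts promise comfortable,
long-duration heart-rate monitoring for children seen in pediatric cardiology,
but their readings must first be validated against the clinical gold standard,
a Holter ECG, worn simultaneously during free living. That validation is a
pipeline, not a single statistic: the devices run on unsynchronized clocks,
report at different and sometimes irregular rates, hide missing data behind
zeros or constant fill values, and degrade under bodily movement. `ambuvalid`
implements every stage of that pipeline — and a synthetic cohort generator
with known ground truth, so each stage can be verified quantitatively rather
than by inspection.

## The measurement model

For participant $i$, the criterion device provides beat-to-beat R-R intervals
$rr_1, rr_2, \dots$ (ms). The criterion heart rate at beat $k$ is the trailing
moving average

$$\mathrm{HR}_k = \frac{60000}{\tfrac{1}{16}\sum_{j=k-15}^{k} rr_j},$$

timestamped at beat $k$. The 16-beat window damps beat-level artifacts in
ambulatory ECG. Note a consequence of the trailing convention: the derived
series lags the instantaneous heart rate by about half a window (≈5 s at
pediatric rates). The clock-offset estimate below absorbs that group delay, so
the aligned pair is internally consistent; only when an offset estimate is
compared against an externally known clock shift (as in simulation studies)
should the criterion be supplied as an instantaneous 1 Hz stream.

**Clock synchronization.** Both series are resampled to a common 1 s grid and
the offset is the integer lag in $[-60, 60]$ s that maximizes the Pearson
correlation over overlapping non-missing samples (ties: smallest $|$lag$|$,
then the negative lag; at least 300 s of overlap is required at every
searched lag). One-second granularity matches the ~1 Hz reporting of the
devices. Identifiability at 1 s precision comes from heart-rate structure
faster than the circadian trend — respiratory sinus arrhythmia and the slow
heart-rate-variability wander — not from the smooth baseline.

**Pairing.** After shifting the wearable clock back by the offset, wearable
BPM is linearly interpolated onto each criterion timestamp. Zeros are treated
as missing *before* interpolation: a true heart rate of 0 is outside
physiological range, and wrist devices are known to emit zeros for undetected
beats. Gaps longer than 60 s are not bridged; criterion rows inside them are
marked `underdetected`. Rows with missing criterion values are marked
`erroneous` (a failure of the reference, not the wearable) and are excluded
from every statistic. The permissive 60 s bridge deliberately retains data
recorded at a degraded one-per-minute rate for the accuracy analyses while the
sample-rate anomaly flag excludes those participants from the accelerometry
analysis — reproducing the inclusion/exclusion split such a firmware defect
forces in practice.

**Agreement statistics.** On the usable pairs $(w_t, c_t)$:

* accuracy: $100 \cdot \Pr(|w_t - c_t|/c_t \le 0.10)$, the within-10% rule of
  the AAMI guidance (the boundary is inclusive; "within 10%" is ambiguous
  there, so the choice is documented rather than silent);
* MAE $= \overline{|w - c|}$ and MAPE $= 100\cdot\overline{|w - c|/c}$;
* Bland-Altman: bias $=\bar d$, limits of agreement $\bar d \pm 1.96\,s_d$
  with the sample (n−1) standard deviation;
* Lin's concordance correlation coefficient
  $\rho_c = 2 s_{wc} / (s_w^2 + s_c^2 + (\bar w - \bar c)^2)$ with population
  (n) moments, labelled weak ($<0.5$), moderate ($0.5$–$0.7$) or strong
  ($>0.7$).

Per-participant values are averaged unweighted across participants (each
child is one experimental unit). The Bland-Altman limits are additionally
pooled over all samples, because sample-level limits — not the spread of
participant means — describe how far an individual reading can stray. The
mean CCC gets a percentile bootstrap CI over participants (2000 resamples,
seeded), which is honest for clustered data; a pooled asymptotic CI is
available via `ci_method = "pooled"` for comparability with analyses that
treat all samples as independent.

**Movement stratification.** Movement intensity is the Euclidean norm of the
first difference of the triaxial acceleration (axes divided by the
counts-per-g divisor first, 512 for raw count exports). First differencing
removes gravity and any constant offset. Quantile bins (default quartiles,
type-7 linear-interpolation quantiles) are computed per participant from that
participant's own data: there is no accepted set of activity thresholds in g
for children, and wrist- and torso-worn sensors see different movements.
Movement is matched to paired rows by nearest neighbour within 2 s.

**Subgroup testing.** Between-participant schemes (sex, age ≤12/>12 y, BMI
≤19/>19 kg/m², wrist circumference ≤15.5/>15.5 cm, Fitzpatrick group,
diagnosis) compare one overall accuracy value per participant.
Within-participant schemes (above/below own median HR, sleep/wake, first vs
second 12 h) recompute each participant's accuracy within the stratum and
compare paired values — the dispatcher structurally cannot send a
within-participant scheme to an independent-samples test. Shapiro-Wilk at
$\alpha = 0.05$ per group gates t/paired-t/ANOVA against
Mann-Whitney/Wilcoxon/Kruskal-Wallis; all tests are two-sided at 0.05 with no
multiplicity correction by default (a deliberate mirror of common practice in
device-validation studies; apply `p.adjust` downstream if desired). The
median, not the mean, splits heart rate because the mean is pulled by
outliers. Sleep/wake labelling excludes a 60-minute guard window — read as
±30 min — around each diary transition, where the child's true state is
ill-defined. Two Fitzpatrick groupings circulate for pediatric PPG analyses
({I,II}/{III}/{IV,V,VI} and {I,II}/{III,IV}/{V,VI}); the first is the default
and the second is available via `fitz_grouping = "table"`.

**Interaction regression.** The age-group × movement analysis is ordinary
least squares on one observation per participant × quantile bin (outcome:
accuracy in the bin; predictors: age group, the participant's mean intensity
in the bin, and their interaction). A per-sample regression was rejected as
pseudo-replicated: errors within a participant are strongly dependent.

**Comfort scores.** The composite per respondent and device is the mean of
the 1–5 Likert items (the construction is stated because summaries of a
"composite comfort score" are otherwise ambiguous); cohort summaries are
medians with IQR, and each wearable is compared with the criterion by a
paired two-sided Wilcoxon signed-rank test — Likert data are ordinal, so no
parametric alternative is offered.

## The synthetic cohort

Ground truth for each simulated child is an instantaneous 1 Hz heart rate

$$\mathrm{HR}(t) = \text{circadian}(t) + \text{bout}(t) +
A\sin(2\pi t/T) + W(t),$$

with a smooth wake/sleep baseline (sleep below wake, 10-min logistic
transitions), activity bouts (overlaps combine by maximum — exertion
saturates), respiratory sinus arrhythmia ($A = 3$ BPM, $T = 4$ s, a
breathing-band oscillation), and a slow Ornstein-Uhlenbeck wander ($\sigma =
5$ BPM, $\tau = 30$ s) representing baroreflex-band heart-rate variability.
The wander matters methodologically: it is the only component that survives
the 16-beat criterion smoothing, and without it the cross-correlation peak is
too flat for 1-second offset recovery. Beats are drawn sequentially with
interval $60/\mathrm{HR}(t)$ s times a 2% log-normal jitter — small enough
that the 16-beat mean tracks the instantaneous rate.

The accelerometer writes gravity on one axis plus Gaussian axis noise whose
SD has three parts: a stillness floor (0.003 g, reached in sleep), daytime
fidget (default 0.075 g of mean intensity while awake — children move even
"at rest", and this micro-movement is precisely what degrades optical
sensing during the day relative to sleep), and bout-specific boosts sharing
the same windows as the heart-rate boosts, so movement and exertion co-occur.
A slow log-normal modulation makes micro-movement continuously heterogeneous,
which keeps per-participant intensity quantiles well defined. Counts are
stored at full precision rather than quantized to integers: integer rounding
at the stillness floor (~1.5 counts) would create massive ties and
ill-defined quantile bins. This is one explicit divergence from real exports.

The wearable observes the truth through an error model: an integer clock
offset in $[-60, 60]$ s (integer because the offset search runs at 1 s
granularity), additive bias, Gaussian noise $\sigma(t) = \sigma_\mathrm{rest}
+ \kappa\, g(t)$ coupled to measured movement $g(t)$, dropout emitted as
`NA`, literal zeros, or last-known-value/constant fill, optional late-half
noise inflation (drying electrode gel on ECG shirts), and an optional
sample-rate defect that thins the stream to one sample per minute from sleep
onset (a firmware regression of exactly this shape is documented for wrist
devices). Default cohort parameters — ages ~13.2 (SD 3.6) y truncated to
[6, 18], 45% female, BMI ~19.9 (SD 3.7), wrist ~15.4 (SD 1.7) cm, bias
−1.4 BPM, 2.5% rest dropout emitted as zeros, $\sigma_\mathrm{rest} =
3.5$ BPM, $\kappa = 30$ BPM/g — are calibrated so that the simulated cohort
reproduces the qualitative structure such validation studies report: overall
accuracy in the mid-80s, higher accuracy in sleep than wake and below the
participant's median heart rate than above it, and a monotone accuracy
decline across movement quantiles. The motion-noise coupling is a free
scenario parameter, not a claim about any specific device.

All randomness flows from one master seed through fixed per-participant,
per-stream substreams, so the same seed regenerates a byte-identical cohort
and adding a participant never perturbs the others.

### What the generator does not emulate

PPG waveform physics, ECG morphology and arrhythmia events, autocorrelated
(bursty) sensor error, posture effects, and skin-tone- or BMI-dependent error
are all absent: metadata fields like Fitzpatrick type are sampled for
realism, but the error model is independent of them. Passing tests therefore
demonstrate that the *pipeline* recovers what was injected under a plausible
error structure — they are not evidence about any real device, and subgroup
contrasts on default synthetic cohorts are null by construction except where
the error model creates them (movement, heart-rate level, time of day,
decay).

## Numerical choices and degenerate inputs

* Offset search: Pearson correlation on overlapping non-missing pairs —
  normalized, so lags with different overlap lengths are comparable; constant
  overlap segments are an error (correlation undefined).
* Interpolation never invents values: every bridged sample lies between its
  bracketing observations; exact timestamp hits pass through unchanged
  (tolerance $10^{-9}$ s).
* Quantile bins are half-open $[\mathrm{low}, \mathrm{high})$ with the last
  bin closed; an all-equal movement distribution raises an error naming the
  participant.
* Zero criterion values in a MAPE pair are excluded with a warning (division
  undefined); they normally never reach that point, being flagged erroneous.
* Constant groups in the normality gate count as non-normal (assumptions
  unverifiable → nonparametric branch); identical groups report a degenerate
  test with $p = 1$.
* Accuracy in a stratum is `NA` below 10 usable pairs, and subgroup tests
  refuse groups with fewer than 3 participants, naming the scheme.

## Problem sizes

The shipped simulation studies use desk-scale versions of the full design:
24-hour cohorts of 8 participants for the headline tables, 2-hour recordings
for the 100-replicate offset-recovery study, 12-hour cohorts for missingness
calibration, and 6-hour awake-only cohorts of 6 participants × 20 seeds for
the movement-monotonicity study. These sizes were chosen so the full suite
runs in about a minute while every Monte-Carlo band stays informative; all
scale linearly if larger studies are wanted.

## Known limitations

The offset is assumed constant over the recording (no clock drift); the
criterion's beat-level artifact handling is out of scope (assumed done
upstream by the Holter reader); repeated-measures corrections for pooled
limits of agreement are not applied by default; and the comfort-questionnaire
generator models only a device-level shift, not item-level structure.
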