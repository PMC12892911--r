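---
title: "Methods: behavioral and bioenergetic phenotyping of larval zebrafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral and bioenergetic phenotyping of larval zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebraphen)
```

zebraphen implements the quantitative layer of a larval-zebrafish
phenotyping workflow built around models of mitochondrial disease: a
noninvasive redox-dye genotype sorter, light-flash-response (LFR)
locomotion metrics from a plate-based activity camera, prey-capture
hunting-event analysis from tracking outputs, tail-bout kinematics,
Seahorse-style oxygen-consumption decomposition, and the statistical and
survival procedures these assays report. Every input modality has a
synthetic generator with machine-readable ground truth, so each detector
is validated end to end without rig hardware. This vignette explains the
procedures, the tunable parameters, the numerical conventions, and what
the synthetic validation does and does not establish about real data.

## Redox-fluorescence genotype sorting

Larvae from a heterozygous in-cross are incubated overnight with
resazurin, a weakly fluorescent redox dye that viable cells reduce to the
strongly fluorescent resorufin. Animals with perturbed mitochondrial
oxidative flux reduce more dye, so homozygous mutants fluoresce brighter.
`classify_plate()` sorts a 96-well plate by its own fluorescence
quartiles: wells strictly above the 75th percentile (Q3) are predicted
homozygous mutants, wells strictly below the 25th percentile (Q1)
predicted wild type, and the interquartile middle is left unassigned
(it is an unresolvable mix of wild-type and heterozygous animals).

Conventions, each isolated behind one function and pinned by a
brute-force order-statistic oracle in the tests:

* **Percentile definition.** Linear interpolation between the closest
  order statistics (R's type-7 quantile), the common default in
  scientific software.
* **Ties at a threshold are unassigned.** The sorting rule reads
  "above"/"under" the percentiles; strict inequalities are the
  conservative reading and avoid asymmetric tie-breaking. A fully tied
  plate therefore assigns nothing.
* **Per-plate quartiles.** Thresholds are computed within each plate,
  never pooled across plates, since dye batch and incubation time shift
  absolute fluorescence plate-wide.

`confusion_metrics()` scores an assignment against known genotypes. The
false-positive rate is the *contamination of the selected pool*: the
percentage of predicted mutants whose true genotype is wild type or
heterozygous. With no predicted mutants the rate is undefined (`NA`),
never 0.

One structural property is worth knowing before trusting a pooled
false-positive estimate: the strict top-quartile rule on a plate of
n wells with all-distinct values always selects a fixed number of wells
(24 of 94), while the homozygote count fluctuates binomially around
n/4. Whenever a plate draws fewer homozygotes than the quartile size,
the shortfall is filled by non-mutants no matter how well the
fluorescence distributions separate. Pooled over many plates this puts a
floor of `E[(24 − H)⁺]/24` ≈ 8% (H ~ Binomial(94, 0.25)) under the
expected false-positive rate. A single validated plate can do much
better — one contaminant among 24 calls is 4.2% — but the sorter's
long-run contamination under Mendelian sampling cannot be driven to zero
by assay quality alone. `sorting_power_curve()` maps contamination
against separation and spread, and the degenerate limits (no separation
→ 75%; perfect separation → the Mendelian floor) anchor its tests.

## Light-flash-response metrics

The activity camera reports one "actinteg" value per well per time
slice: the summed pixel change during the slice. The slice duration is
exactly 1/15 s and is stored as a rational (1, 15), never a rounded
float, so converting protocol seconds to slice indices stays exact
across a 17,100-slice recording.

Two protocols are built in (`lfr_protocol()`):

* **simple** — 300 s dark acclimatization, then 10 s light.
  `lfr_simple()` scores exactly the first 4 s of light (60 slices):
  after that the larvae freeze with movements near zero, so later slices
  only dilute the response. `max_activity` is the maximum slice value in
  the window (actinteg is already a per-slice aggregate, so no envelope
  smoothing is applied), and `n_events` counts maximal runs of slices at
  or above a threshold (`detect_events()`), optionally merging runs
  separated by a short sub-threshold gap.
* **extended** — 300 s dark adaptation, a 600 s dark window scored by
  `spontaneous_activity()` (mean actinteg per second; the adaptation
  window is excluded), then 8 cycles of 1 s light + 29 s dark.
  `triggered_average()` computes, per flash, V1 = mean actinteg/s over
  [onset, onset + 2 s) — light-on slices included — and V2 over the
  following 28 s, then averages the 8 per-flash values with equal
  weight. Averaging per flash first and across individuals at the
  reporting layer is a fixed convention; for equal window lengths it is
  algebraically identical to pooling the concatenated windows, which the
  tests assert.

**The event threshold is an analysis parameter, not a rig constant.**
Commercial tracking software applies an internal movement threshold that
is not portable across rigs; the package therefore exposes `threshold`
explicitly and documents a data-driven default of 3× the median nonzero
dark-epoch slice value (`default_event_threshold()`). Behavior is pinned
by ground-truth recovery tests — on noiseless synthetic traces the event
count equals the number of connected components of the union of the
injected pulse intervals — rather than by a magic constant. Counting is
run-based (a maximal supra-threshold run is one event). Note that run
counting is *not* monotone in the threshold in general: raising the
threshold can split one run over a multi-pulse pile-up into two. It is
monotone for isolated plateau pulses, and monotone in the merge gap
always; the property tests encode exactly these statements.

## Prey capture

The assay films a larva hunting live rotifers. The pipeline starts from
derived traces: per-frame rotifer counts, a summed eye-convergence angle,
and swim-bout intervals (all intervals half-open `[start, end)` in
seconds).

* `rolling_median()` applies a centered 10-s median filter with
  truncated (never padded) edge windows, so early depletion is not
  biased by padding. The filter exists to remove single-frame count
  dropouts from transient occlusions, which are far narrower than half
  the window; a brute-force per-window oracle pins it exactly. Truncated
  edges mean idempotence on monotone series holds one window-width into
  the series, not at the edges.
* `proportion_consumed()` normalizes to the mean filtered count over the
  first minute and subtracts from 1. Values below 0 (noise above
  baseline) are reported with a QC warning, never clamped. The group
  comparison point is 15 minutes (`proportion_at()`), where wild-type
  capture slows from satiation; comparisons use the two-tailed
  Mann-Whitney U test.
* `detect_hunting_events()` implements the bout-aligned semantics:
  hunting larvae converge both eyes on the prey, so a bout is
  *converging* if convergence is at or below the 60° criterion at the
  bout's onset sample and crosses above it within the bout, and
  *still-converged* if its onset sample is already above. An event runs
  from a converging bout through the maximal run of immediately
  following still-converged bouts, ending at that last bout's end.
  "Converged at onset" operationalizes "the end of the last bout before
  which the eyes are still converged"; the rule is pinned by tests.
  Events are non-overlapping and bout-boundary-aligned by construction,
  and both properties are asserted on every run. The event count is not
  monotone in the threshold in general (thresholds below the baseline
  convergence ceiling merge neighboring events; thresholds inside the
  high plateau can split one) — the tests instead assert stability of
  the detected events for any threshold in the gap between baseline and
  hunting convergence.
* `interval_summary()` bins events into 5-minute intervals by event
  start; empty bins report an undefined (`NA`) mean duration.

## Tail-bout kinematics

`segment_bouts()` segments a tail-angle trace (default 700 frames/s;
the rig frame rate is configurable because it varies between setups) by
hysteresis thresholding of the smoothed absolute angular speed: smooth
|dθ/dt| with a 15-ms centered moving average, open a bout above
`on_thresh`, close below `off_thresh`, drop bouts shorter than 40 ms,
merge bouts separated by less than 20 ms. Default thresholds are
data-driven: the smoothed absolute speed of a noisy baseline has a
*nonzero median* (for Gaussian angle noise the median and the MAD both
scale with the noise level), so thresholds centered at zero would sit in
the noise floor at any noise level. The defaults are therefore
median + 5×MAD (on) and median + 2×MAD (off) of the smoothed speed,
falling back to 5%/2% of the peak for silent baselines.

**Vigor** is the RMS angular velocity within the bout. The kinematic
literature defers bout-intensity definitions to classifier-specific
features; RMS velocity is the simplest monotone proxy, is swappable
behind one function, and is pinned by the closed form for a sinusoid:
the RMS derivative of A·sin(2πft) is A·2πf/√2, which the segmentation
recovers within 1% at 700 frames/s. The 10-category movement
classification of bouts (approach swim, J turn, C starts, ...) is a
prior published method and out of scope; a label column can be carried
through unchanged.

Cohort summaries:

* `bout_frequency()` — bouts per minute.
* `vigor_density()` — Gaussian KDE of pooled per-bout vigors on a fixed
  grid with a pointwise 95% percentile-bootstrap band. Resampling is
  **always at the individual level** (larvae, never bouts): bouts within
  a larva are correlated, and per-bout resampling would understate the
  uncertainty. The KDE is evaluated as an explicit normal mixture so the
  trapezoid integral over a sufficiently wide grid is 1 to 1e-6. The
  empirical mode of a KDE wobbles at the pointwise-noise scale because
  the normal peak is nearly flat; the tests check consistency (the mode
  error contracts with sample size), not a fixed small error at a
  moderate n.
* `mobility_timecourse()` — mobility of a larva in a time bin is its
  bout-occupancy fraction (the fraction of the bin spent in bouts; the
  source figure's "average mobility" unit is not defined in text, so
  occupancy is adopted as the documented convention). Each group's mean
  gets a pointwise 99% percentile-bootstrap CI over larvae, and the
  divergence mask marks bins where the two groups' intervals are
  disjoint. Under matched groups of 10 larvae the mask is empty in at
  least 95% of runs; the percentile bootstrap undercovers slightly for
  much smaller groups, which is a known small-sample property, not a
  defect of the masking rule.

## Oxygen-consumption decomposition

A Seahorse-style run measures OCR every 5 minutes through two
injections: FCCP (a protonophore uncoupler driving the electron
transport chain to its maximal rate), then rotenone + antimycin A
(blocking complexes I and III to reveal nonmitochondrial oxygen
consumption). `summarize_ocr()` computes:

* basal (raw) = mean of the **last 3 points** before the FCCP injection;
* maximal (raw) = **maximum** over the window between the injections
  (the source convention says only "maximal value after FCCP"; the
  maximum over the inter-injection window is implemented, since the
  FCCP response peaks at different points in different wells);
* nonmitochondrial = mean of the post-R+AA points, dropping the first
  (transient) post-injection point when at least 3 are available — a
  plateau mean is less noisy than any single point;
* basal and maximal are reported after subtracting the
  nonmitochondrial rate.

Negative corrected values are reported with a QC warning, never clamped:
clamping would hide failed injections. The summary is equivariant under
unit rescaling, and adding a constant to every point moves only the
nonmitochondrial estimate — both asserted as properties.

## Statistics and survival

The statistical layer mirrors the procedures the assays report, each
delegated to the standard routine where one exists and cross-checked
against an independent enumeration oracle in the tests:

* `kruskal_dunn()` — Kruskal-Wallis H with midrank tie correction, plus
  Dunn's pairwise z tests (hand-implemented; base R has none) with
  Bonferroni adjustment by default. For combined samples of at most 8
  observations the omnibus p comes from the **exact permutation null**
  of H (full enumeration): the chi-square approximation is off by up to
  ~0.07 at that size. In the two-group case the chi-square branch is
  algebraically identical to the two-sided Mann-Whitney normal
  approximation without continuity correction, which the tests verify to
  1e-6.
* `anova_tukey()` — one-way ANOVA with Tukey HSD; for two equal groups F
  equals the squared pooled t.
* `fisher_exact_2x2()` — conditional odds ratio and two-sided p (sum of
  hypergeometric probabilities no larger than the observed table's);
  degenerate margins return p = 1.
* `mann_whitney_u()` — exact null up to combined n = 20 without ties,
  otherwise the normal approximation with tie and continuity
  corrections; the switch point is documented and both branches are
  oracle-pinned. Fully tied samples return p = 1 (the approximation
  degenerates to zero variance).
* `km_logrank()` — Kaplan-Meier product-limit curves per group, pairwise
  log-rank chi-square tests with Bonferroni over the number of pairs,
  and the proportion alive at a reporting horizon. With zero events the
  curves are identically 1 and p is `NA`, never fabricated.
* `box_stats()` — the figure convention: median center line, quartile
  box limits, whiskers at the most extreme points within 1.5×IQR.

Survival observation in the tank assay happens twice a day;
`simulate_survival()` reproduces that by rounding exponential event
times up to a 0.5-day grid (deaths are treated as exact at the
observation time; no interval-censoring model, matching the assay's
own convention). The grid introduces heavy ties that make the log-rank
test mildly conservative; the null-calibration test therefore draws
exact event times (`grid_interval = 0`), since it checks the testing
machinery rather than the observation scheme.

## The synthetic generators

All generators are pure functions of (parameters, seed); a single seed
drives named child streams (`child_seed()`) so adding one generator
never perturbs another's draws. Each returns ground truth sufficient to
score the downstream detector without re-deriving it.

* **Plates** (`simulate_plate()`): genotypes multinomial 1:2:1
  (wt:het:hom), fluorescence normal per genotype. The default mixture —
  wt/het N(1.0, 0.15), hom N(1.8, 0.25) on a normalized scale — models
  a clear but imperfect separation: about a 3-SD gap, with occasional
  boundary overlap, which is the regime the dye assay operates in.
* **Activity** (`simulate_actinteg()`): spontaneous bouts as a
  homogeneous Poisson process; flash k elicits one response with
  probability p·fatigue^(k−1) at a latency uniform in [0, 4) s; each
  bout deposits a rectangular pulse (2–5 slices, truncated-normal
  amplitude), overlaps summing. Rectangular pulses rather than realistic
  kinematics are deliberate: the LFR metrics depend only on amplitude
  and occupancy, so simple pulses make the ground truth exact.
* **Prey sessions** (`simulate_prey_session()`): Poisson hunting events
  of 1–6 bouts; convergence crosses the 60° criterion right after the
  first bout's onset sample and releases after the last bout, matching
  the detector's bout-aligned semantics so clean recovery is exact *by
  construction* — this validates the detector's bookkeeping, not its
  robustness to convergence jitter near threshold. Count dropouts are
  single-frame only (width 1 ≪ the 10-s window), which is precisely the
  disturbance the median filter exists to remove. Convergence is
  sampled at 25 Hz and counts at 5 Hz; bout edges snap to the
  convergence grid.
* **Tail traces** (`simulate_tail_trace()`): bouts are 25-Hz
  oscillations under an envelope with a fast (10 ms) onset ramp and an
  exponential decay over the final third, on Gaussian angle noise.
  Defaults (30° amplitude, 200 ms duration, 0.5° noise at 700 frames/s)
  are chosen as typical larval routine-swim values. The faint decay tail
  is invisible to any threshold detector, which bounds the achievable
  interval IoU at roughly 0.85–0.9; the recovery tests require > 0.8
  per bout.
* **OCR** (`simulate_ocr()`): three phases — plateau at
  basal + nonmito, a ramp peaking exactly at max + nonmito, plateau at
  nonmito — plus additive Gaussian noise; with zero noise the summary
  recovers the generator parameters exactly, and 3-point basal averaging
  shrinks noise by √3 (both asserted).
* **Survival** (`simulate_survival()`): exponential hazards per group,
  administrative censoring, twice-daily observation grid as above.

What the generators do **not** emulate: pixel-level video artifacts,
habituation beyond geometric fatigue, circadian drift, correlated
within-plate effects (edge wells, temperature gradients), rotifer
behavior, instrument drift in OCR, or non-proportional hazards. Passing
the recovery tests therefore demonstrates that the estimators implement
their definitions correctly and are calibrated under their stated
models — not that those models capture every failure mode of real rig
data.

## Problem sizes and reproducibility

The validation suite uses cohorts of 100–500 larvae for moment checks,
100 seeds for recovery sweeps, 200 plates × 94 wells for the pooled
sorting contamination, 500 replicates for null-calibration of the
log-rank test, and 100 null runs for the divergence mask — sizes at
which Monte-Carlo standard errors are small relative to the asserted
tolerances (3 SE bounds throughout). `scripts/acceptance.R` recomputes
the pooled sorting contamination from scratch for any `--seed`, and the
command-line driver writes provenance (seed, parameters, input
checksums) into every JSON summary; repeated runs with the same seed are
byte-identical.
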