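---
title: "Methods: spatiotemporal dynamics of self-paced decision fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal dynamics of self-paced decision fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodyn)
```

## The analysis problem

In a self-paced decision experiment each trial lasts exactly as long as the
subject takes to decide — here, whether to download a mobile app — and the
next stimulus appears at the button press, with no inter-stimulus interval.
This design is deliberately neither a block design nor a classic
event-related design: trial durations vary from roughly ten to forty-five
seconds within and across subjects, so fixed-latency averaging is
impossible. `neurodyn` implements the analysis strategy built for this
situation:

1. **Windowed dynamic functional connectivity (dFC)** with a fixed 10-s
   window anchored at trial start or trial end, so windows are comparable
   across trials of different lengths.
2. **Trial-length normalization**: every trial's regional time series is
   resampled to the subject's mean decision length, a finite-impulse-response
   (FIR) model estimates the trial-locked response, and that response is
   mapped onto a normalized 0–100% decision-time axis (0% = stimulus onset,
   100% = button press).
3. **Cross-subject consensus**: sliding windows on the normalized axis
   collect each subject's top-amplitude response peaks; cells supported by a
   majority of subjects form the spatiotemporal consensus map, computed for
   all trials and separately for yes- and no-answered trials.
4. **Decoding**: pairwise correlations of selected regional time courses
   within each trial are used as features to predict the trial's yes/no
   response under stratified fivefold cross-validation.

Because the original scan data are not publicly deposited, the package ships
a synthetic-data generator that emulates the study conditions with known
ground truth, and every stage is validated against that truth.

## The synthetic generator

`study_design()` fixes the task parameters; `app_study_design()` is the preset
for the emulated protocol: 20 subjects, 25 self-paced trials, TR = 0.545 s
(multiband EPI), a 10-s blank lead-in before the first trial, and
consecutive trials with no gaps. Response times are truncated-normal with a
per-subject mean, reflecting the observation that between-subject
variability in decision time exceeds within-subject variability.

The preset's subject means are spread over 14–30 s for fourteen subjects
and 4.5–6.5 s for six. This reproduces a key feature of the study: a fixed
10-s window only makes sense for trials longer than 10 s, and the emulated study's
inclusion rule (more than 10 s on at least 13 of 25 trials) removed six of
twenty subjects, leaving fourteen. With means at least 2.5 standard
deviations clear of the cut on either side, the preset yields exactly
fourteen included subjects for essentially every seed. The nominal
response-time range of the emulated experiment is 10–45 s for analysable
subjects; the generator's lower bound is 3 s precisely so that the excluded
subjects exist.

Neural activity is modelled as **stages** (`stage_spec()`): boxcars on a
band of *fractional* decision time (e.g. visual regions on 0–20%, evaluative
cingulate/orbitofrontal regions on 35–70%, prefrontal regions on 80–100%),
with amplitudes that may differ between yes- and no-trials — that is how
condition effects are planted. Stage boxcars are convolved with the same
canonical double-gamma HRF the GLM uses. Noise (`noise_spec()`) is white
Gaussian, optionally correlated inside disjoint region blocks via a Cholesky
factor of the equicorrelation matrix — so the planted population correlation
is exact, and recovery tests are analytic rather than calibrated. Blocks may
be restricted to an anchored window of each trial (epoch-specific coupling),
which is how end-of-trial-only connectivity is planted without hemodynamic
carry-over. Drift is one slow sinusoid plus a linear term — enough for the
detrending stage to have something real to remove.

The default universe of `app_study_truth()` has 120 regions, matching the atlas
ROI count of the emulated analysis; most are pure-noise background regions,
which is what makes a top-20 peak ranking selective.

What the generator does **not** emulate: head motion, physiological noise,
autocorrelated (1/f) BOLD noise, spatial anatomy, or realistic
region-to-region covariance beyond the planted blocks. Passing recovery
tests therefore demonstrate the correctness of the estimators under the
stated model, not robustness to every artifact of real data.

## Signal preparation

**Drift removal.** The referenced detrending algorithm's internals live in
an external citation; `detrend_timeseries()` implements the equivalent
contract as a projection onto an intercept-plus-orthogonal-polynomial slow
subspace (default order 3). The projection is idempotent, removes the mean,
and leaves task-band fluctuations essentially untouched (correlation with
input > 0.99 for white noise).

**Smoothing.** `smooth_volume()` applies a separable Gaussian with
sigma = FWHM / (2 sqrt(2 ln 2)) per axis in voxel units (the study used an
8-mm FWHM on 3.3-mm voxels, sigma of about 1.03 voxels). Kernel tails are
renormalized at volume boundaries, so constant volumes pass through
unchanged; frame sums are preserved up to that boundary handling.

**fALFF filtering.** `compute_falff()` scores each component or region by
the ratio of low-band to high-band periodogram power; components scoring
below 1 are discarded as noise, mirroring the emulated analysis's discard rule for
ICA-derived components. The emulated analysis does not fix the band edges in its
description, so the package defaults to the common practice low = 0.01–0.08 Hz
and high = (0.08 Hz, Nyquist], both configurable. A plain untapered FFT
periodogram is used deliberately: downstream windows hold ~18 samples, so
spectral sophistication would be false precision. In the pipeline the fALFF
mask is applied to the connectivity branch only — the spatiotemporal branch
operates on the full atlas universe, as in the emulated analysis. Note that
on purely synthetic white-noise regions fALFF sits near the band-width
ratio (about 0.08), so background regions are *expected* to be discarded by
this filter; that is its job.

**Inclusion rule.** `select_subjects()` keeps a subject when more than
`min_trials` (default 13) trials exceed `min_rt` (default 10 s).

## GLM

`double_gamma_hrf()` is the canonical difference of two gamma densities
(peak delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio
1/6; the emulated analysis names only a canonical double gamma, so the
conventional parameter values are used), normalized to unit peak; at
TR = 0.545 s the sampled kernel peaks near 4.9 s, consistent with the 4–6-s
hemodynamic delay the analysis assumes. `build_design()` models each trial
as a 1-s boxcar ending at the button press (the stated event convention;
the 1-s event length is an acknowledged-arbitrary convention and is
configurable), one regressor per response class plus an intercept, with
events snapped to the TR grid by rounding toward the earlier sample.
`fit_glm()` is ordinary least squares per region; `contrast_map()` computes
`c'beta` and its t-statistic for the three standard contrasts (yes > no,
no > yes, both > baseline). Fitting is single-level with a fixed-effects
group summary (mean effect, median t); random-effects inference and
cluster-extent correction are out of scope.

## Dynamic functional connectivity

Per subject and per trial, `subject_connectivity()` correlates every region
pair inside the anchored window (18 samples at the default 10 s / 0.545 s)
and computes a two-sided p-value by the t-transform
`t = r sqrt((n-2)/(1-r^2))` on n−2 degrees of freedom — the standard
parametric choice, cross-checked in the tests against a 100,000-draw
permutation null (agreement to better than 0.01). Trials with p > 0.05 are
discarded for that pair; the subject-level edge value is the mean r over
retained trials.

Two decisions the emulated analysis leaves open:

* **Averaging denominator.** Whether thresholded correlations were averaged
  over retained trials or all 25 is ambiguous there; retained-trials
  is the default, `average = "all"` is available.
* **Per-subject significance.** The subject-level binary mask is defined
  here as "significant in more than half of the eligible trials", the most
  direct reading of averaging thresholded trials; it is exposed as a knob
  via the alpha and averaging arguments.

Trials shorter than the window are skipped, never padded — padding would
fabricate samples, and the inclusion rule already guarantees at least 13
eligible trials per retained subject.

`group_consistency()` retains edges significant in at least 8 of 14
subjects (the more-than-half rule), signs them by the mean of
subject means, and `connectivity_difference()` classifies edges as
start-only / end-only / both / neither between the two epochs. Edges are
undirected throughout; no directionality is inferred.

Under planted conditions (independent noise, 14 subjects, 25 trials,
18-sample windows) the group threshold drives the spurious-edge rate far
below 1%, while equicorrelated blocks at r = 0.6 are recovered essentially
always — both rates are recomputed by `scripts/acceptance.R`.

## Spatiotemporal consensus mapping

`normalize_trials()` resamples each trial segment to
`L = round(mean RT / TR)` samples by linear interpolation (Fourier
resampling was rejected: segments are short and non-periodic), concatenates
them, and `fit_fir()` estimates the trial-locked response with one impulse
regressor per lag. With non-overlapping equal-length resampled trials the
FIR design is orthogonal and the least-squares weights equal the per-lag
across-trial mean; the solver is nevertheless a genuine regression, and the
equality is asserted against the averaging oracle in the tests (agreement
to 1e-10). `normalize_response()` then resamples the L weights to exactly
100 points: the percent decision-time axis.

`consensus_map()` slides a 20%-wide window in 5% steps (17 windows), finds
strict local maxima of every region's normalized response (a "peak" is a
sample strictly greater than both neighbors; endpoint samples are never
peaks — peak detection is otherwise unspecified, so the strictest
convention is used), pools all (region, peak) candidates in the window,
ranks them by amplitude with ties broken by earlier time then lower region
index (deterministic output), and lets the regions owning the top 20 peaks
increment their bin — once per subject-window, the package's resolution of
whether one region may occupy several top slots. Cells with at least 8 of
14 subjects form the thresholded map. The source states the consensus
threshold as "bin value ≥ 8" in its methods but "thresholded at 7" in a
figure caption; 8 is the default here and the threshold is an argument.

**Hemodynamic delay is deliberately not corrected**, matching the emulated
analysis. Consequences, visible in synthetic maps and documented rather
than suppressed: a stage planted at 0–20% of decision time is observed
roughly one HRF peak delay later (about 25% for a 20-s trial), and a stage
ending at the button press peaks *after* the trial ends, carrying over into
the early bins of the next trial. `expected_stage_peak_pct()` predicts,
from ground truth, where a planted stage should appear on the uncorrected
axis, and `stage_order_recovery()` checks planted stage ordering after
subtracting the known delay modulo 100 — which also unwraps carried-over
late stages. With three stages planted at 0–20%, 35–70% and 80–100% in
disjoint sets among 120 regions (moderate noise, sd 1 against unit-ish
stage amplitudes), the ordering is recovered in ≥ 95% of seeds.

`condition_difference()` subtracts the no-map from the yes-map per cell and
retains `|N_yes − N_no| ≥ 7` (more than half the subjects), labelling each
retained cell by its dominant condition. One behaviour worth knowing: with
a top-k ranking, a strong condition-specific response *displaces* other
regions from the top slots, so background cells can show mild negative
differences around a planted effect; only the planted regions reach the
±7 retention threshold in the shipped tests.

## Decoding

`trial_features()` computes, per trial, the upper triangle of the pairwise
correlation matrix of the selected regions over that trial's resampled
segment, in fixed lexicographic pair order — 10 regions give 45 features.
The features are computed on the normalized segments so trials of different
lengths are comparable (the correlation support window is otherwise unspecified).
The classifier is a ridge-regularized logistic regression (`glmnet`,
alpha = 0, small fixed penalty): the emulated analysis does not specify its
classifier, so the minimal linear family consistent with 45 features and
~350 trials is used, and the elastic-net mixing is an argument. Folds are
stratified at the trial level by default; `group_by_subject = TRUE` assigns
whole subjects to folds for the reader worried about subject-identity
leakage (a documented caveat of trial-level cross-validation).
`permutation_chance()` supplies the empirical null. Accuracies obtained on
the original (undeposited) data are not reproducible targets; on synthetic
cohorts the reported quantities are relative to planted truth.

## Pipeline, artifacts, determinism

`run_pipeline()` executes preparation → GLM → dFC → spatiotemporal →
decoding on a synthetic study-like cohort (or a supplied one), writing
per-stage TSV/JSON artifacts, two figure types (connectogram with
width-by-count and blue/red sign coding; consensus heatmaps with a
diverging yes/no difference palette), a parameter manifest sufficient to
reproduce the run bit-for-bit given the seed, and a timing log. All
randomness flows from the single seed through fixed offsets, so two runs
with the same seed produce byte-identical text artifacts — verified by
checksum in the acceptance suite. The decoding stage selects its 10 regions
as those with the largest absolute yes/no count difference (deterministic
tie-break by region order), mirroring the "dominant difference regions"
selection of the emulated analysis.

Problem sizes used by the shipped tests and the acceptance script — 14
subjects, 25 trials, 120 regions for mapping, 20 regions for connectivity
nulls, 20 seeds for the recovery rates, 100,000 permutation draws for the
p-value oracle, 200 label permutations for the decoding null — were chosen
as the smallest sizes at which the binomial consensus arithmetic of the
method is exercised at study scale.

## Known limitations

* White (uncorrelated-in-time) noise makes parametric correlation p-values
  exact; real BOLD noise is autocorrelated, and the 18-sample window
  p-values would be anti-conservative there. The consensus thresholds, not
  the per-trial p-values, carry the inferential weight, as in the emulated
  analysis.
* fALFF on synthetic white-noise regions is simply the band-width ratio;
  the filter's behaviour on real ICA components (the original use) is not
  testable from synthetic data.
* Group ICA parcellation, motion correction, coregistration and MNI
  normalization are out of scope: the pipeline consumes registered volumes
  or precomputed regional time series.
* The voxelwise path (`smooth_volume()` + `extract_roi_timeseries()`) is
  exercised at toy scale only.
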