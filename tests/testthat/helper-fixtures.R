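# Shared synthetic fixtures. Everything is generated in code; the study-like
# conditions (14 analysable subjects, 25 self-paced trials, TR 0.545 s,
# 120-region universe, unit-sd noise) are fixed here once and reused by the
# module and acceptance tests.

TR <- 0.545

# Cohort with three stages planted in disjoint region sets at 0-20%, 35-70%
# and 80-100% of decision time, among a 120-region universe.
recovery_sets <- list(
  early = sprintf("EARLY%02d", 1:6),
  mid   = sprintf("MID%02d", 1:6),
  late  = sprintf("LATE%02d", 1:6)
)

recovery_cohort <- function(seed) {
  sets <- recovery_sets
  stages <- list(
    stage_spec(sets$early, 0.00, 0.20, amplitude_yes = 1),
    stage_spec(sets$mid,   0.35, 0.70, amplitude_yes = 1),
    stage_spec(sets$late,  0.80, 1.00, amplitude_yes = 1)
  )
  rois <- c(unlist(sets, use.names = FALSE), sprintf("BG%03d", 1:102))
  design <- study_design(14, 25, TR, rt_min = 10, rt_max = 45,
                         rt_mean_by_subject = seq(16, 28, length.out = 14),
                         rt_sd = 3, seed = seed)
  synthesize_cohort(design, stages,
                    noise_spec(white_sd = 1, drift_amplitude = 0.5),
                    roi_ids = rois)
}

# Cohort for connectivity nulls and power: no task signal, 20 regions of
# which three share a planted correlation block at r = 0.6.
dfc_cohort <- function(seed, r = 0.6) {
  rois <- sprintf("R%02d", 1:20)
  blocks <- if (r != 0)
    list(list(roi_ids = rois[1:3], r = r)) else list()
  design <- study_design(14, 25, TR, rt_min = 10, rt_max = 45,
                         rt_mean_by_subject = seq(14, 26, length.out = 14),
                         rt_sd = 2, seed = seed)
  synthesize_cohort(design, list(), noise_spec(white_sd = 1,
                                               correlation_blocks = blocks),
                    roi_ids = rois)
}

# Ten-region cohort with a separable condition effect: three regions share an
# early yes-only stage, so yes-trials carry high mutual correlation that
# no-trials lack. The stage sits early in long trials so its haemodynamic
# response decays within the trial instead of bleeding into the next one.
decoding_cohort <- function(seed, yes_effect = 0.8) {
  rois <- c(sprintf("SIG%d", 1:3), sprintf("BG%02d", 1:7))
  stages <- list(stage_spec(rois[1:3], 0.05, 0.35,
                            amplitude_yes = yes_effect, amplitude_no = 0))
  design <- study_design(14, 25, TR, rt_min = 15, rt_max = 45,
                         rt_mean_by_subject = seq(24, 34, length.out = 14),
                         rt_sd = 2, seed = seed)
  synthesize_cohort(design, stages, noise_spec(white_sd = 1), roi_ids = rois)
}

# Pooled feature table for the separable cohort.
decoding_features <- function(cohort, rois = NULL) {
  rois <- rois %||% cohort$series[[1]]$roi_ids
  pool_features(lapply(names(cohort$series), function(s)
    trial_features(normalize_trials(cohort$series[[s]], cohort$trials[[s]]),
                   rois)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hemodynamic delay (HRF peak time) in percent of a cohort's mean decision
# time; used to compare uncorrected maps against planted neural timing.
cohort_delay_pct <- function(cohort) {
  h <- double_gamma_hrf(tr = cohort$design$tr)
  peak_s <- (which.max(h) - 1) * cohort$design$tr
  100 * peak_s / mean(unlist(lapply(cohort$trials, `[[`, "duration")))
}

# All-subject spatiotemporal consensus map of a cohort.
cohort_consensus <- function(cohort, condition = "all", ...) {
  resp <- lapply(names(cohort$series), function(s)
    normalize_response(fit_fir(normalize_trials(
      detrend_timeseries(cohort$series[[s]]), cohort$trials[[s]],
      condition = condition))))
  consensus_map(resp, condition = condition, ...)
}
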