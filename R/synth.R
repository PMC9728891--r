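#' Describe a self-paced event-related study design
#'
#' A study design fixes the scanner and task parameters of a self-paced
#' decision experiment: every trial lasts exactly as long as the subject takes
#' to answer, the next stimulus appears immediately at the button press, and a
#' blank lead-in precedes the first trial so the haemodynamic baseline is
#' representable.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Number of self-paced trials per subject.
#' @param tr Repetition time (sampling interval) in seconds.
#' @param rt_min,rt_max Bounds of the response-time distribution in seconds.
#' @param rt_mean_by_subject Vector of per-subject mean response times in
#'   seconds (length `n_subjects`); each must lie inside `[rt_min, rt_max]`.
#' @param rt_sd Standard deviation of the (truncated normal) response-time
#'   distribution, in seconds, before truncation.
#' @param yes_probability Probability that a trial is answered "yes".
#' @param seed Integer seed making every draw from this design reproducible.
#' @param lead_in Blank-screen baseline before the first trial, seconds.
#' @return An object of class `study_design`.
#' @seealso [app_study_design()] for the preset matching the emulated protocol.
#' @export
study_design <- function(n_subjects, n_trials, tr,
                         rt_min, rt_max, rt_mean_by_subject,
                         rt_sd = 3, yes_probability = 0.5,
                         seed = 1L, lead_in = 10) {
  stopifnot(n_subjects >= 1, n_trials >= 1, tr > 0,
            rt_min > 0, rt_min <= rt_max,
            yes_probability >= 0, yes_probability <= 1,
            rt_sd >= 0, lead_in >= 0)
  rt_mean_by_subject <- rep_len(rt_mean_by_subject, n_subjects)
  if (any(rt_mean_by_subject < rt_min | rt_mean_by_subject > rt_max))
    stop2("every subject mean response time must lie in [rt_min, rt_max]")
  structure(list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    tr = tr, rt_min = rt_min, rt_max = rt_max,
    rt_mean_by_subject = rt_mean_by_subject, rt_sd = rt_sd,
    yes_probability = yes_probability, seed = as.integer(seed),
    lead_in = lead_in
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Self-paced study design: %d subjects x %d trials, TR %.3f s\n",
    x$n_subjects, x$n_trials, x$tr))
  cat(sprintf("  response times: truncated normal on [%g, %g] s, sd %g s\n",
              x$rt_min, x$rt_max, x$rt_sd))
  cat(sprintf("  subject mean RT range: %.1f-%.1f s; P(yes) = %g; seed %d\n",
              min(x$rt_mean_by_subject), max(x$rt_mean_by_subject),
              x$yes_probability, x$seed))
  invisible(x)
}

#' Preset design for the emulated app-adoption protocol
#'
#' Twenty subjects, 25 self-paced trials, multiband TR of 0.545 s, a 10-s
#' blank lead-in, and subject mean decision times chosen so that six of the
#' twenty subjects answer most trials in under 10 s (and are therefore removed
#' by the standard inclusion rule of [select_subjects()], leaving 14).
#'
#' @param seed Integer seed.
#' @return A `study_design`.
#' @export
app_study_design <- function(seed = 1L) {
  study_design(
    n_subjects = 20L, n_trials = 25L, tr = 0.545,
    rt_min = 3, rt_max = 45,
    rt_mean_by_subject = c(seq(14, 30, length.out = 14),
                           c(4.5, 5, 5.5, 6, 6, 6.5)),
    rt_sd = 3, yes_probability = 0.5, seed = seed, lead_in = 10
  )
}

#' Define an activation stage on the normalized decision-time axis
#'
#' A stage is a set of regions that switch on together during a fixed fraction
#' of every trial's decision time: e.g. visual regions early (0-20%),
#' evaluative regions mid-trial, prefrontal regions just before the button
#' press. Amplitudes may differ between yes- and no-answered trials, which is
#' how condition-specific activation is planted.
#'
#' @param roi_ids Character vector of region identifiers carrying this stage.
#' @param start_frac,end_frac Stage onset/offset as fractions of the trial's
#'   decision time, `0 <= start_frac < end_frac <= 1`.
#' @param amplitude_yes,amplitude_no Neural amplitude (percent signal change)
#'   on trials answered yes / no.
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(roi_ids, start_frac, end_frac,
                       amplitude_yes = 1, amplitude_no = amplitude_yes) {
  stopifnot(length(roi_ids) >= 1, start_frac >= 0, end_frac <= 1,
            start_frac < end_frac,
            is.finite(amplitude_yes), is.finite(amplitude_no))
  structure(list(roi_ids = as.character(roi_ids),
                 start_frac = start_frac, end_frac = end_frac,
                 amplitude_yes = amplitude_yes, amplitude_no = amplitude_no),
            class = "stage_spec")
}

#' Define the noise model of a synthetic cohort
#'
#' White Gaussian noise, optionally correlated within disjoint region blocks
#' (exact population correlation, via a Cholesky factor of the block
#' equicorrelation matrix), plus a slow drift made of one sinusoid and a
#' linear term.
#'
#' @param white_sd Standard deviation of the white-noise component.
#' @param drift_amplitude Amplitude of the sinusoidal drift and of the total
#'   linear drift excursion, in signal units.
#' @param drift_period Period of the sinusoidal drift, seconds.
#' @param correlation_blocks List of `list(roi_ids =, r =)` entries; blocks
#'   must be disjoint and `|r| < 1`. A block may additionally carry
#'   `anchor = "trial_start"` or `"trial_end"` with a `window` in seconds, in
#'   which case its noise correlation is active only inside that window of
#'   every trial (epoch-specific coupling); the default couples the whole
#'   run.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 1, drift_amplitude = 0, drift_period = 128,
                       correlation_blocks = list()) {
  stopifnot(white_sd >= 0, drift_amplitude >= 0, drift_period > 0)
  all_ids <- character(0)
  for (b in correlation_blocks) {
    stopifnot(is.list(b), length(b$roi_ids) >= 2, abs(b$r) < 1)
    if (!is.null(b$anchor))
      stopifnot(b$anchor %in% c("all", "trial_start", "trial_end"),
                is.numeric(b$window), b$window > 0)
    if (any(b$roi_ids %in% all_ids))
      stop2("correlation blocks must use disjoint ROI sets")
    all_ids <- c(all_ids, b$roi_ids)
  }
  structure(list(white_sd = white_sd, drift_amplitude = drift_amplitude,
                 drift_period = drift_period,
                 correlation_blocks = correlation_blocks),
            class = "noise_spec")
}

# Truncated-normal draws by inverse-CDF; exact for the bounded RT sampler.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(runif(n, pl, pu), mean, sd)
}

#' Sample per-subject trial timings
#'
#' Trials are strictly consecutive: trial k+1 begins at the button press of
#' trial k, with no inter-stimulus interval, and the first trial begins after
#' the blank lead-in. Response times are truncated-normal around each
#' subject's mean; yes/no labels are Bernoulli draws.
#'
#' @param design A [study_design()].
#' @return A named list (one element per subject) of data frames with columns
#'   `onset`, `duration` and `response` (seconds; `response` is "yes"/"no").
#' @export
sample_trial_timings <- function(design) {
  stopifnot(inherits(design, "study_design"))
  with_seed(design$seed, {
    out <- vector("list", design$n_subjects)
    names(out) <- sprintf("sub-%02d", seq_len(design$n_subjects))
    for (s in seq_len(design$n_subjects)) {
      rt <- rtruncnorm(design$n_trials, design$rt_mean_by_subject[s],
                       design$rt_sd, design$rt_min, design$rt_max)
      onset <- design$lead_in + c(0, cumsum(rt[-design$n_trials]))
      resp <- ifelse(runif(design$n_trials) < design$yes_probability,
                     "yes", "no")
      out[[s]] <- data.frame(onset = onset, duration = rt, response = resp,
                             stringsAsFactors = FALSE)
    }
    out
  })
}

#' Trial-local neural time course of one stage
#'
#' Boxcar on `[start_frac * rt, end_frac * rt)` sampled on the TR grid
#' (sample i sits at time `(i-1) * tr` from trial onset), at the stage's
#' amplitude for the given response.
#'
#' @param stage A [stage_spec()].
#' @param rt Trial response time, seconds.
#' @param tr Repetition time, seconds.
#' @param response Trial label, "yes" or "no"; selects the amplitude.
#' @return Numeric vector of length `ceiling(rt / tr)`.
#' @export
make_stage_template <- function(stage, rt, tr, response = "yes") {
  stopifnot(inherits(stage, "stage_spec"), rt > 0, tr > 0)
  n <- ceiling(rt / tr)
  t <- (seq_len(n) - 1) * tr
  amp <- if (identical(response, "yes")) stage$amplitude_yes else stage$amplitude_no
  amp * as.numeric(t >= stage$start_frac * rt & t < stage$end_frac * rt)
}

# Correlate rows of iid-normal matrix z within disjoint equicorrelation
# blocks. Blocks with an anchor are mixed only on the columns inside the
# anchored window of each trial; the mixing preserves the marginal N(0,1).
apply_correlation_blocks <- function(z, roi_ids, blocks, trials = NULL,
                                     tr = NULL) {
  for (b in blocks) {
    idx <- match(b$roi_ids, roi_ids)
    if (anyNA(idx)) stop2("correlation block names unknown ROI ids")
    m <- length(idx)
    sigma <- matrix(b$r, m, m); diag(sigma) <- 1
    anchor <- b$anchor %||% "all"
    cols <- if (anchor == "all" || is.null(trials)) {
      seq_len(ncol(z))
    } else {
      n_samp <- floor(b$window / tr)
      unlist(lapply(which(trials$duration >= b$window), function(k) {
        if (anchor == "trial_start") {
          i0 <- floor(trials$onset[k] / tr) + 1L
          i0:(i0 + n_samp - 1L)
        } else {
          i1 <- floor((trials$onset[k] + trials$duration[k]) / tr)
          (i1 - n_samp + 1L):i1
        }
      }), use.names = FALSE)
    }
    cols <- cols[cols <= ncol(z)]
    z[idx, cols] <- t(chol(sigma)) %*% z[idx, cols, drop = FALSE]
  }
  z
}

#' Synthesize one subject's ROI time series
#'
#' Each region's series is the sum of every trial's stage boxcars placed at
#' the trial onset and convolved with the canonical double-gamma HRF, plus
#' block-correlated white noise and slow drift.
#'
#' @param trials Trial table for the subject (`onset`, `duration`, `response`).
#' @param stages List of [stage_spec()] objects.
#' @param noise A [noise_spec()].
#' @param tr Repetition time, seconds.
#' @param seed Integer seed for the noise draws.
#' @param roi_ids Character vector naming all regions to simulate; defaults to
#'   the union of stage and noise-block regions.
#' @param subject_id Identifier stored with the series.
#' @param tail Extra scan time after the last button press, seconds, so the
#'   final trial's haemodynamic response is captured.
#' @param hrf Sampled HRF kernel; defaults to [double_gamma_hrf()] at `tr`.
#' @return A `roi_series` object: list with `subject_id`, `roi_ids`,
#'   `data` (region-by-time matrix) and `tr`.
#' @export
synthesize_subject <- function(trials, stages, noise, tr, seed,
                               roi_ids = NULL, subject_id = "sub-01",
                               tail = 20, hrf = NULL) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1, tr > 0)
  if (is.null(roi_ids)) {
    roi_ids <- unique(c(unlist(lapply(stages, `[[`, "roi_ids")),
                        unlist(lapply(noise$correlation_blocks, `[[`, "roi_ids"))))
  }
  n_roi <- length(roi_ids)
  t_end <- trials$onset[nrow(trials)] + trials$duration[nrow(trials)] + tail
  n_time <- ceiling(t_end / tr)
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr = tr)

  neural <- matrix(0, n_roi, n_time, dimnames = list(roi_ids, NULL))
  for (k in seq_len(nrow(trials))) {
    i0 <- floor(trials$onset[k] / tr) + 1L
    for (st in stages) {
      tmpl <- make_stage_template(st, trials$duration[k], tr,
                                  response = trials$response[k])
      idx <- i0:(i0 + length(tmpl) - 1L)
      keep <- idx <= n_time
      rows <- match(st$roi_ids, roi_ids)
      neural[rows, idx[keep]] <- neural[rows, idx[keep], drop = FALSE] +
        rep(tmpl[keep], each = length(rows))
    }
  }
  # trial-locked BOLD: convolve active regions with the HRF, truncate to run
  bold <- neural
  active <- which(rowSums(abs(neural)) > 0)
  for (i in active) bold[i, ] <- convolve_truncate(neural[i, ], hrf)

  with_seed(seed, {
    z <- matrix(rnorm(n_roi * n_time), n_roi, n_time)
    z <- apply_correlation_blocks(z, roi_ids, noise$correlation_blocks,
                                  trials = trials, tr = tr)
    series <- bold + noise$white_sd * z
    if (noise$drift_amplitude > 0) {
      tt <- (seq_len(n_time) - 1) * tr
      phase <- runif(n_roi, 0, 2 * pi)
      for (i in seq_len(n_roi)) {
        series[i, ] <- series[i, ] +
          noise$drift_amplitude * sin(2 * pi * tt / noise$drift_period + phase[i]) +
          noise$drift_amplitude * (tt / max(tt) - 0.5)
      }
    }
    roi_series(series, roi_ids = roi_ids, tr = tr, subject_id = subject_id)
  })
}

# Linear convolution truncated to the length of x.
convolve_truncate <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(kernel))), rev(kernel),
                         type = "open")
  out[seq_len(n)]
}

#' Construct a region-by-time series container
#'
#' @param data Numeric matrix, one row per region.
#' @param roi_ids Character identifiers, one per row.
#' @param tr Sampling interval, seconds.
#' @param subject_id Subject identifier.
#' @return An object of class `roi_series`.
#' @export
roi_series <- function(data, roi_ids, tr, subject_id = "sub-01") {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(roi_ids), tr > 0)
  rownames(data) <- roi_ids
  structure(list(subject_id = subject_id, roi_ids = as.character(roi_ids),
                 data = data, tr = tr),
            class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("ROI time series [%s]: %d regions x %d samples, TR %.3f s (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr,
              ncol(x$data) * x$tr))
  invisible(x)
}

#' Synthesize a multi-subject cohort with known ground truth
#'
#' Applies [sample_trial_timings()] and [synthesize_subject()] across the
#' design, recording the planted stages, noise specification and trial labels
#' as ground truth.
#'
#' @param design A [study_design()].
#' @param stages List of [stage_spec()] objects.
#' @param noise A [noise_spec()].
#' @param roi_ids Regions to simulate (default: union of stage/noise regions).
#' @return An object of class `bold_cohort`: `design`, `trials` (list of trial
#'   tables), `series` (list of `roi_series`), `truth`.
#' @export
synthesize_cohort <- function(design, stages, noise, roi_ids = NULL) {
  trials <- sample_trial_timings(design)
  if (is.null(roi_ids)) {
    roi_ids <- unique(c(unlist(lapply(stages, `[[`, "roi_ids")),
                        unlist(lapply(noise$correlation_blocks, `[[`, "roi_ids"))))
  }
  series <- vector("list", design$n_subjects)
  names(series) <- names(trials)
  for (s in seq_len(design$n_subjects)) {
    series[[s]] <- synthesize_subject(
      trials[[s]], stages, noise, design$tr,
      seed = design$seed + 1000L + s, roi_ids = roi_ids,
      subject_id = names(trials)[s])
  }
  structure(list(design = design, trials = trials, series = series,
                 truth = list(stages = stages, noise = noise,
                              labels = lapply(trials, `[[`, "response"))),
            class = "bold_cohort")
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf("Synthetic BOLD cohort: %d subjects, %d trials each, %d regions\n",
              x$design$n_subjects, x$design$n_trials,
              length(x$series[[1]]$roi_ids)))
  cat(sprintf("  TR %.3f s; %d planted stages; %d correlated noise blocks\n",
              x$design$tr, length(x$truth$stages),
              length(x$truth$noise$correlation_blocks)))
  invisible(x)
}

#' Stage set emulating the staged decision process
#'
#' Early visual activation, mid-trial evaluative (cingulate/orbitofrontal and
#' amygdala) activation, late prefrontal activation ending at the button
#' press, a motor burst at the press, and a condition-dependent stage in the
#' second half of the trial (stronger on yes-trials) carrying the plantable
#' yes/no difference. Background regions bring the universe to 120 regions,
#' the atlas ROI count of the emulated analysis; three of them share a
#' correlated noise block.
#'
#' @param yes_effect Amplitude of the yes-only stage; 0 removes the condition
#'   difference.
#' @return Named list with `stages`, `noise` and `roi_ids` ready for
#'   [synthesize_cohort()].
#' @export
app_study_truth <- function(yes_effect = 1.5) {
  visual <- c("V1", "V2_L", "V2_R", "V3")
  mid    <- c("ACC", "OFC_L", "OFC_R", "AMY")
  late   <- c("DLPFC", "VLPFC", "VMPFC")
  motor  <- "M1_L"
  backgr <- sprintf("BG%03d", seq_len(120 - 12))
  stages <- list(
    stage_spec(visual, 0.00, 0.20, amplitude_yes = 1.2, amplitude_no = 1.2),
    stage_spec(mid,    0.35, 0.70, amplitude_yes = 1.0, amplitude_no = 1.0),
    stage_spec(late,   0.80, 1.00, amplitude_yes = 1.0, amplitude_no = 1.0),
    stage_spec(motor,  0.90, 1.00, amplitude_yes = 1.5, amplitude_no = 1.5),
    stage_spec(c("VMPFC", "AMY", "ACC"), 0.50, 0.80,
               amplitude_yes = yes_effect, amplitude_no = 0)
  )
  noise <- noise_spec(
    white_sd = 1, drift_amplitude = 0.5, drift_period = 128,
    correlation_blocks = list(list(roi_ids = c("BG001", "BG002", "BG003"),
                                   r = 0.6)))
  list(stages = stages, noise = noise,
       roi_ids = c(visual, mid, late, motor, backgr))
}

#' Predicted BOLD peak position of a planted stage, percent of decision time
#'
#' Convolves the stage boxcar (at the given trial length) with the canonical
#' HRF over two consecutive identical trials and locates the response peak
#' modulo the trial length. Because the hemodynamic delay is never corrected
#' downstream, a stage ending at the button press peaks after the trial ends
#' and is observed carried over into the early percent bins of the next
#' trial; this helper gives the position where the map should show it.
#'
#' @param stage A [stage_spec()].
#' @param rt Trial length (subject mean response time), seconds.
#' @param tr Repetition time, seconds.
#' @param hrf Optional kernel; defaults to [double_gamma_hrf()] at `tr`.
#' @return Peak position in percent of decision time, in `[0, 100)`.
#' @export
expected_stage_peak_pct <- function(stage, rt, tr, hrf = NULL) {
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr = tr)
  tmpl <- make_stage_template(stage, rt, tr, response = "yes")
  two <- convolve_truncate(c(tmpl, tmpl), hrf)
  L <- length(tmpl)
  peak <- which.max(two) - 1L          # 0-based lag from first trial onset
  100 * (peak %% L) / L
}

#' Paper-like synthetic cohort in one call
#'
#' @param seed Integer seed.
#' @param yes_effect Passed to [app_study_truth()].
#' @return A `bold_cohort`.
#' @export
app_study_cohort <- function(seed = 1L, yes_effect = 1.5) {
  tru <- app_study_truth(yes_effect = yes_effect)
  synthesize_cohort(app_study_design(seed = seed), tru$stages, tru$noise,
                    roi_ids = tru$roi_ids)
}

#' Write a synthetic cohort to disk
#'
#' Writes one events TSV (`onset`, `duration`, `response`) and one
#' region-by-time series TSV per subject; optionally also renders each subject
#' as a small 4-D NIfTI volume plus a 3-D integer atlas (each region painted
#' into a group of voxels), for exercising the volume path.
#'
#' @param dataset A `bold_cohort`.
#' @param dir Output directory (created if absent).
#' @param nifti If `TRUE`, also write `sub-XX_bold.nii.gz`-style volumes and a
#'   shared `atlas.nii.gz` (uncompressed `.nii` is used so outputs stay text
#'   tooling-friendly; see Details).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, nifti = FALSE) {
  stopifnot(inherits(dataset, "bold_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in names(dataset$trials)) {
    write.table(dataset$trials[[s]],
                file.path(dir, paste0(s, "_events.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ser <- dataset$series[[s]]
    df <- data.frame(roi = ser$roi_ids, ser$data, check.names = FALSE)
    colnames(df) <- c("roi", sprintf("t%04d", seq_len(ncol(ser$data))))
    write.table(df, file.path(dir, paste0(s, "_series.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(c(sprintf("tr\t%.10g", dataset$design$tr),
               sprintf("n_subjects\t%d", dataset$design$n_subjects),
               sprintf("n_trials\t%d", dataset$design$n_trials)),
             file.path(dir, "dataset_info.tsv"))
  if (nifti) {
    atlas <- make_toy_atlas(dataset$series[[1]]$roi_ids)
    atlas_img <- RNifti::asNifti(atlas$volume)
    RNifti::pixdim(atlas_img) <- c(3, 3, 3)
    RNifti::writeNifti(atlas_img, file.path(dir, "atlas.nii"))
    writeLines(paste(seq_along(atlas$roi_ids), atlas$roi_ids, sep = "\t"),
               file.path(dir, "atlas_labels.tsv"))
    for (s in names(dataset$series)) {
      img <- RNifti::asNifti(paint_series_volume(dataset$series[[s]], atlas))
      RNifti::pixdim(img) <- c(3, 3, 3, dataset$design$tr)
      RNifti::writeNifti(img, file.path(dir, paste0(s, "_bold.nii")))
    }
  }
  invisible(dir)
}

# Small 3-D integer atlas: each region gets a 2x2x1 voxel patch on a grid.
make_toy_atlas <- function(roi_ids) {
  n <- length(roi_ids)
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  vol <- array(0L, dim = c(2L * nrow_grid, 2L * ncol_grid, 2L))
  for (k in seq_len(n)) {
    r <- (k - 1L) %/% ncol_grid
    c <- (k - 1L) %% ncol_grid
    vol[2L * r + 1:2, 2L * c + 1:2, 1L] <- k
  }
  list(volume = vol, roi_ids = roi_ids)
}

# 4-D volume whose voxels carry the series of their atlas label (0 elsewhere).
paint_series_volume <- function(series, atlas) {
  d <- dim(atlas$volume)
  n_time <- ncol(series$data)
  vol <- array(0, dim = c(d, n_time))
  flat <- matrix(vol, prod(d), n_time)
  lab <- as.vector(atlas$volume)
  for (k in seq_along(atlas$roi_ids)) {
    flat[lab == k, ] <- rep(series$data[k, ], each = sum(lab == k))
  }
  array(flat, dim = c(d, n_time))
}

#' Read a cohort written by [write_dataset()]
#'
#' @param dir Directory produced by [write_dataset()].
#' @return A list with `trials` (list of trial tables), `series` (list of
#'   `roi_series`) and `tr`.
#' @export
read_dataset <- function(dir) {
  info <- read.delim(file.path(dir, "dataset_info.tsv"), header = FALSE,
                     row.names = 1)
  tr <- as.numeric(info["tr", 1])
  ev_files <- sort(list.files(dir, "_events\\.tsv$", full.names = TRUE))
  subjects <- sub("_events\\.tsv$", "", basename(ev_files))
  trials <- series <- setNames(vector("list", length(subjects)), subjects)
  for (s in subjects) {
    trials[[s]] <- read.delim(file.path(dir, paste0(s, "_events.tsv")),
                              stringsAsFactors = FALSE)
    df <- read.delim(file.path(dir, paste0(s, "_series.tsv")),
                     check.names = FALSE)
    series[[s]] <- roi_series(as.matrix(df[, -1, drop = FALSE]),
                              roi_ids = df$roi, tr = tr, subject_id = s)
  }
  list(trials = trials, series = series, tr = tr)
}
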