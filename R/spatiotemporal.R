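#' Resample every trial to the subject's mean decision length
#'
#' Self-paced trials have different durations, so each trial's segment is
#' linearly resampled to a common per-subject length
#' `L = round(mean(RT) / tr)` samples (inter-subject variability in decision
#' time exceeds intra-subject variability, so a subject-specific target length
#' minimizes stretching error). Segments are concatenated in trial order.
#'
#' @param series A `roi_series`.
#' @param trials Trial table for the subject.
#' @param condition `"all"`, `"yes"` or `"no"`: which trials to keep.
#' @return An object of class `normalized_trials`: `subject_id`, `roi_ids`,
#'   `data` (region x (n_trials * L)), `L`, `n_trials`, `labels`, `tr`,
#'   `mean_rt`.
#' @export
normalize_trials <- function(series, trials, condition = c("all", "yes", "no")) {
  condition <- match.arg(condition)
  stopifnot(inherits(series, "roi_series"))
  sel <- if (condition == "all") seq_len(nrow(trials))
         else which(trials$response == condition)
  if (length(sel) < 1) stop2("no trials selected for condition ", condition)
  tr <- series$tr
  mean_rt <- mean(trials$duration[sel])
  L <- max(2L, round(mean_rt / tr))
  n_time <- ncol(series$data)
  segs <- vector("list", length(sel))
  for (m in seq_along(sel)) {
    k <- sel[m]
    i0 <- floor(trials$onset[k] / tr) + 1L
    i1 <- floor((trials$onset[k] + trials$duration[k]) / tr)
    i1 <- min(i1, n_time)
    if (i1 - i0 + 1L < 2L) stop2("trial ", k, " has fewer than 2 samples")
    segs[[m]] <- resample_rows(series$data[, i0:i1, drop = FALSE], L)
  }
  structure(list(subject_id = series$subject_id, roi_ids = series$roi_ids,
                 data = do.call(cbind, segs), L = L,
                 n_trials = length(sel),
                 labels = trials$response[sel], tr = tr, mean_rt = mean_rt),
            class = "normalized_trials")
}

# Linearly resample each row of a matrix to `L` columns, endpoints preserved.
resample_rows <- function(mat, L) {
  n <- ncol(mat)
  if (n == L) return(mat)
  xout <- seq(0, 1, length.out = L)
  x <- seq(0, 1, length.out = n)
  t(apply(mat, 1L, function(v) approx(x, v, xout = xout)$y))
}

#' @export
print.normalized_trials <- function(x, ...) {
  cat(sprintf(
    "Normalized trials [%s]: %d regions, %d trials x %d samples (mean RT %.2f s)\n",
    x$subject_id, length(x$roi_ids), x$n_trials, x$L, x$mean_rt))
  invisible(x)
}

#' FIR estimate of the trial-locked response
#'
#' A finite-impulse-response model with one impulse regressor per post-onset
#' lag (L regressors, each carrying a 1 at lag l after every trial onset)
#' fitted by least squares per region. With non-overlapping equal-length
#' trials this design is orthogonal and the weights equal the per-lag mean
#' across trials; the model is nevertheless solved as a regression so the
#' estimator is well-defined for any design.
#'
#' @param norm A `normalized_trials` object with at least 2 trials.
#' @return An object of class `fir_response`: `subject_id`, `roi_ids`,
#'   `weights` (region x L), `L`, `tr`, `mean_rt`; `normalized` is `NULL`
#'   until [normalize_response()] is applied.
#' @export
fit_fir <- function(norm) {
  stopifnot(inherits(norm, "normalized_trials"))
  if (norm$n_trials < 2) stop2("FIR estimation needs at least 2 trials")
  L <- norm$L
  n_row <- norm$n_trials * L
  X <- matrix(0, n_row, L)
  for (l in seq_len(L)) X[(seq_len(norm$n_trials) - 1L) * L + l, l] <- 1
  qx <- qr(X)
  if (qx$rank < L) stop2("FIR design is rank deficient")
  W <- t(qr.coef(qx, t(norm$data)))
  dimnames(W) <- list(norm$roi_ids, NULL)
  structure(list(subject_id = norm$subject_id, roi_ids = norm$roi_ids,
                 weights = W, L = L, tr = norm$tr, mean_rt = norm$mean_rt,
                 normalized = NULL),
            class = "fir_response")
}

#' @export
print.fir_response <- function(x, ...) {
  cat(sprintf("FIR response [%s]: %d regions x %d lags (TR %.3f s)%s\n",
              x$subject_id, nrow(x$weights), x$L, x$tr,
              if (is.null(x$normalized)) "" else "; normalized to 100 points"))
  invisible(x)
}

#' Normalize a FIR response to the 0-100% decision-time axis
#'
#' Resamples each region's L-lag weight vector to a fixed 100 points, mapping
#' trial start to 0% and the button press to 100%, so subjects with different
#' decision lengths become comparable.
#'
#' @param fir A `fir_response`.
#' @return The same object with `normalized` set (region x 100 matrix).
#' @export
normalize_response <- function(fir) {
  stopifnot(inherits(fir, "fir_response"), fir$L >= 2)
  fir$normalized <- resample_rows(fir$weights, 100L)
  dimnames(fir$normalized) <- list(fir$roi_ids, NULL)
  fir
}

# Strict local maxima of v (both neighbors lower); first/last samples excluded.
find_peaks <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- 2:(n - 1)
  idx[v[idx] > v[idx - 1] & v[idx] > v[idx + 1]]
}

#' Cross-subject spatiotemporal consensus map
#'
#' A window of `window_pct` percent of decision time slides in steps of
#' `step_pct`. Within each window and subject, strict local maxima of every
#' region's normalized response are pooled and ranked by amplitude (ties
#' broken by earlier time, then lower region index); the regions owning the
#' `top_k` peaks each increment their bin for that window (once per
#' subject-window). Cells reaching `min_subjects` form the thresholded map.
#'
#' @param responses List of `fir_response` objects with normalized axes, one
#'   per subject, over the same region universe.
#' @param window_pct Window length in percent of decision time (default 20).
#' @param step_pct Step between window starts (default 5).
#' @param top_k Number of top peaks pooled per subject-window (default 20).
#' @param min_subjects Consensus threshold on the bin counts (default 8).
#' @param condition Label stored with the map (`"all"`, `"yes"`, `"no"`).
#' @return An object of class `spatiotemporal_map`: `bins` (region x window
#'   subject counts), `window_starts` (percent), `window_pct`, `min_subjects`,
#'   `thresholded` (logical matrix), `condition`, `n_subjects`.
#' @export
consensus_map <- function(responses, window_pct = 20, step_pct = 5,
                          top_k = 20L, min_subjects = 8L,
                          condition = "all") {
  stopifnot(length(responses) >= 1, top_k >= 1,
            window_pct > 0, step_pct > 0, window_pct <= 100)
  roi_ids <- responses[[1]]$roi_ids
  n_roi <- length(roi_ids)
  for (r in responses) {
    if (!identical(r$roi_ids, roi_ids)) stop2("subjects use different ROI sets")
    if (is.null(r$normalized)) stop2("apply normalize_response() first")
  }
  starts <- seq(0, 100 - window_pct, by = step_pct)
  pct <- seq(0, 100, length.out = 100L)   # percent position of each sample
  bins <- matrix(0L, n_roi, length(starts),
                 dimnames = list(roi_ids, sprintf("w%02d", seq_along(starts))))
  for (resp in responses) {
    # all strict local maxima per region, found once on the full response
    peaks <- lapply(seq_len(n_roi), function(i) {
      idx <- find_peaks(resp$normalized[i, ])
      if (length(idx))
        data.frame(roi = i, at = idx, amp = resp$normalized[i, idx])
      else NULL
    })
    peaks <- do.call(rbind, peaks)
    if (is.null(peaks)) next
    for (w in seq_along(starts)) {
      inw <- peaks[pct[peaks$at] >= starts[w] &
                   pct[peaks$at] <= starts[w] + window_pct, , drop = FALSE]
      if (!nrow(inw)) next
      ord <- order(-inw$amp, inw$at, inw$roi)
      top <- inw[ord[seq_len(min(top_k, nrow(inw)))], ]
      rois <- unique(top$roi)
      bins[rois, w] <- bins[rois, w] + 1L
    }
  }
  structure(list(bins = bins, window_starts = starts,
                 window_pct = window_pct, step_pct = step_pct,
                 top_k = as.integer(top_k),
                 min_subjects = as.integer(min_subjects),
                 thresholded = bins >= min_subjects,
                 condition = condition, n_subjects = length(responses),
                 roi_ids = roi_ids),
            class = "spatiotemporal_map")
}

#' @export
print.spatiotemporal_map <- function(x, ...) {
  cat(sprintf(
    "Spatiotemporal consensus map [%s]: %d regions x %d windows (%g%% / step %g%%)\n",
    x$condition, nrow(x$bins), ncol(x$bins), x$window_pct, x$step_pct))
  cat(sprintf("  %d subjects; %d cells at or above threshold %d\n",
              x$n_subjects, sum(x$thresholded), x$min_subjects))
  invisible(x)
}

#' @export
as.data.frame.spatiotemporal_map <- function(x, ...) {
  data.frame(roi = rep(x$roi_ids, times = ncol(x$bins)),
             window_start_pct = rep(x$window_starts, each = nrow(x$bins)),
             count = as.vector(x$bins),
             condition = x$condition, stringsAsFactors = FALSE)
}

#' Convert a normalized decision-time position back to seconds
#'
#' The normalized axis maps 0% to stimulus onset and 100% to the button
#' press, so a position in percent corresponds to `pct / 100 * rt` seconds
#' for a trial of decision time `rt`: 10% of a 45-s decision is 4.5 s, while
#' 40% of a 10-s decision is 4 s — the same window of the normalized axis
#' spans different absolute durations across trials.
#'
#' @param pct Position(s) on the normalized axis, percent.
#' @param rt Decision time(s), seconds.
#' @return Seconds from stimulus onset.
#' @export
decision_time_seconds <- function(pct, rt) {
  stopifnot(all(pct >= 0), all(pct <= 100), all(rt > 0))
  pct / 100 * rt
}

#' Check recovery of a planted stage ordering from a consensus map
#'
#' For each region set, the observed position is the center of the window
#' with the highest summed bin count among cells above the consensus
#' threshold. Because maps are deliberately not corrected for the
#' hemodynamic delay, positions are compared after subtracting `delay_pct`
#' (the HRF peak time as a percent of the mean decision time) modulo 100 —
#' this also unwraps responses of press-locked stages that carry over into
#' the next trial's early bins. Recovery means the corrected positions are
#' strictly increasing in the order the sets are given.
#'
#' @param map A `spatiotemporal_map`.
#' @param stage_sets List of character vectors of region ids, in planted
#'   temporal order.
#' @param delay_pct Hemodynamic delay in percent of decision time (e.g.
#'   `100 * 4.9 / mean_rt` for the canonical HRF).
#' @return List with `observed_pct`, `corrected_pct` and `ordered` (logical;
#'   `NA` positions make it `FALSE`).
#' @export
stage_order_recovery <- function(map, stage_sets, delay_pct) {
  stopifnot(inherits(map, "spatiotemporal_map"))
  pos <- vapply(stage_sets, function(set) {
    rows <- match(set, map$roi_ids)
    if (anyNA(rows)) stop2("unknown ROI ids in stage set")
    counts <- colSums(map$bins[rows, , drop = FALSE] *
                        map$thresholded[rows, , drop = FALSE])
    if (all(counts == 0)) return(NA_real_)
    map$window_starts[which.max(counts)] + map$window_pct / 2
  }, numeric(1))
  corrected <- (pos - delay_pct) %% 100
  list(observed_pct = pos, corrected_pct = corrected,
       ordered = !anyNA(corrected) && all(diff(corrected) > 0))
}

#' Yes-versus-no difference of spatiotemporal maps
#'
#' Per cell, the signed difference in subject counts `N_yes - N_no`; cells
#' with `|difference| >= min_diff` (default 7, more than half the subjects)
#' are retained and labelled by the dominant condition.
#'
#' @param map_yes,map_no `spatiotemporal_map` objects on identical grids.
#' @param min_diff Retention threshold on the absolute count difference.
#' @return An object of class `spatiotemporal_difference`: `difference`
#'   (signed matrix), `retained`, `dominant` ("yes"/"no" character matrix,
#'   `NA` where not retained), grid metadata.
#' @export
condition_difference <- function(map_yes, map_no, min_diff = 7L) {
  if (!identical(map_yes$window_starts, map_no$window_starts) ||
      !identical(map_yes$roi_ids, map_no$roi_ids))
    stop2("maps are on different grids")
  d <- map_yes$bins - map_no$bins
  retained <- abs(d) >= min_diff
  dominant <- matrix(NA_character_, nrow(d), ncol(d), dimnames = dimnames(d))
  dominant[retained & d > 0] <- "yes"
  dominant[retained & d < 0] <- "no"
  structure(list(difference = d, retained = retained, dominant = dominant,
                 min_diff = as.integer(min_diff),
                 window_starts = map_yes$window_starts,
                 window_pct = map_yes$window_pct, roi_ids = map_yes$roi_ids),
            class = "spatiotemporal_difference")
}

#' @export
print.spatiotemporal_difference <- function(x, ...) {
  cat(sprintf(
    "Condition difference map: %d cells retained at |N_yes - N_no| >= %d (%d yes-dominant, %d no-dominant)\n",
    sum(x$retained), x$min_diff,
    sum(x$dominant == "yes", na.rm = TRUE),
    sum(x$dominant == "no", na.rm = TRUE)))
  invisible(x)
}
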