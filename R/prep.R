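#' Remove slow temporal drift from ROI time series
#'
#' Projects each region's series onto the complement of a slow-trend subspace
#' (intercept + orthogonal polynomials up to `basis_order`) and returns the
#' residual. This removes scanner drift and the series mean while leaving
#' task-band fluctuations essentially untouched; applying it twice changes
#' nothing.
#'
#' @param series A `roi_series`.
#' @param basis_order Polynomial order of the trend subspace (default 3).
#' @return A detrended `roi_series` with zero mean per region.
#' @export
detrend_timeseries <- function(series, basis_order = 3L) {
  stopifnot(inherits(series, "roi_series"), basis_order >= 1)
  n <- ncol(series$data)
  if (basis_order >= n) stop2("basis_order must be smaller than series length")
  B <- cbind(1, stats::poly(seq_len(n), degree = basis_order))
  qb <- qr(B)
  resid <- t(qr.resid(qb, t(series$data)))
  roi_series(resid, series$roi_ids, series$tr, series$subject_id)
}

#' Smooth a 4-D volume with an isotropic Gaussian kernel
#'
#' Separable 1-D Gaussian convolution along each spatial axis of every time
#' frame, with `sigma = fwhm / (2 sqrt(2 log 2))` converted to voxel units per
#' axis. Kernel tails are renormalized at the boundary, so constant volumes
#' pass through unchanged.
#'
#' @param volume 4-D numeric array (x, y, z, time) or 3-D array (one frame).
#' @param fwhm_mm Full width at half maximum, millimetres; 0 is the identity.
#' @param voxel_mm Voxel size per spatial axis, millimetres (recycled to 3).
#' @return Array of the same shape.
#' @export
smooth_volume <- function(volume, fwhm_mm, voxel_mm) {
  stopifnot(fwhm_mm >= 0, all(voxel_mm > 0))
  voxel_mm <- rep_len(voxel_mm, 3L)
  if (fwhm_mm == 0) return(volume)
  d <- dim(volume)
  stopifnot(length(d) %in% c(3L, 4L))
  squeeze <- length(d) == 3L
  if (squeeze) { volume <- array(volume, c(d, 1L)); d <- dim(volume) }
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  out <- volume
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    half <- max(1L, ceiling(4 * s))
    k <- exp(-((-half):half)^2 / (2 * s^2))
    out <- convolve_axis(out, k / sum(k), axis)
  }
  if (squeeze) out <- array(out, d[1:3])
  out
}

# Convolve a 4-D array along one spatial axis with boundary renormalization.
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  half <- (length(kernel) - 1L) %/% 2L
  n <- d[axis]
  # dense n x n banded operator with renormalized rows; n is small here
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1L & j <= n
    w <- kernel[ok]
    W[i, j[ok]] <- w / sum(w)
  }
  perm <- c(axis, setdiff(1:4, axis))
  x <- aperm(arr, perm)
  dx <- dim(x)
  x <- W %*% matrix(x, nrow = n)
  aperm(array(x, dx), order(perm))
}

#' Extract mean ROI time series from a 4-D volume
#'
#' One row per requested label: the unweighted mean over all voxels carrying
#' that label in the atlas, per time frame. The atlas grid must match the
#' functional grid exactly; registration and resampling are upstream concerns.
#'
#' @param volume 4-D numeric array (x, y, z, time).
#' @param atlas 3-D integer label array with the same spatial dimensions.
#' @param roi_ids Integer labels to extract, or a named integer vector whose
#'   names become the region identifiers.
#' @param tr Repetition time, seconds.
#' @param subject_id Stored identifier.
#' @return A `roi_series`.
#' @export
extract_roi_timeseries <- function(volume, atlas, roi_ids, tr,
                                   subject_id = "sub-01") {
  d <- dim(volume)
  stopifnot(length(d) == 4L)
  if (!identical(dim(atlas), d[1:3]))
    stop2("atlas grid ", paste(dim(atlas), collapse = "x"),
          " does not match volume grid ", paste(d[1:3], collapse = "x"))
  labels <- as.integer(roi_ids)
  nm <- names(roi_ids) %||% as.character(labels)
  lab <- as.integer(atlas)
  missing <- labels[!labels %in% lab]
  if (length(missing))
    stop2("labels absent from atlas: ", paste(missing, collapse = ", "))
  flat <- matrix(volume, prod(d[1:3]), d[4])
  data <- t(vapply(labels, function(l) colMeans(flat[lab == l, , drop = FALSE]),
                   numeric(d[4])))
  roi_series(data, nm, tr, subject_id)
}

#' Fractional amplitude of low-frequency fluctuation per region
#'
#' fALFF is the ratio of spectral power in a low-frequency band to power in a
#' high-frequency band, computed from a plain FFT periodogram of the detrended
#' series. Components dominated by physiological or scanner noise score low
#' and are discarded; the conventional discard rule is fALFF < 1.
#'
#' @param series A `roi_series`.
#' @param low_band,high_band Frequency intervals in Hz; defaults
#'   `c(0.01, 0.08)` and `(0.08, Nyquist]`.
#' @param threshold Keep regions with fALFF at or above this value (default 1).
#' @return An object of class `falff_report`: data frame-like list with
#'   `falff` per region, the bands, and `keep_mask`. Zero high-band power
#'   yields `Inf` (kept, with a warning).
#' @export
compute_falff <- function(series, low_band = c(0.01, 0.08),
                          high_band = NULL, threshold = 1) {
  stopifnot(inherits(series, "roi_series"))
  nyquist <- 1 / (2 * series$tr)
  if (is.null(high_band)) high_band <- c(low_band[2], nyquist)
  stopifnot(low_band[1] > 0, low_band[1] < low_band[2],
            high_band[1] < high_band[2], high_band[2] <= nyquist + 1e-12)
  x <- detrend_timeseries(series, basis_order = 1L)$data
  n <- ncol(x)
  freq <- (seq_len(n) - 1) / (n * series$tr)
  keep_half <- freq > 0 & freq <= nyquist + 1e-12
  pow <- t(apply(x, 1L, function(v) Mod(fft(v))^2))[, keep_half, drop = FALSE]
  f <- freq[keep_half]
  in_low <- f >= low_band[1] & f <= low_band[2]
  in_high <- f > high_band[1] & f <= high_band[2]
  lowp <- rowSums(pow[, in_low, drop = FALSE])
  highp <- rowSums(pow[, in_high, drop = FALSE])
  falff <- ifelse(highp > 0, lowp / highp, Inf)
  if (any(!is.finite(falff)))
    warning("zero high-band power for some regions; fALFF reported as Inf")
  structure(list(roi_ids = series$roi_ids, falff = falff,
                 low_band = low_band, high_band = high_band,
                 threshold = threshold,
                 keep_mask = falff >= threshold),
            class = "falff_report")
}

#' @export
print.falff_report <- function(x, ...) {
  cat(sprintf(
    "fALFF report: low [%g, %g] Hz / high (%g, %g] Hz, threshold %g\n",
    x$low_band[1], x$low_band[2], x$high_band[1], x$high_band[2], x$threshold))
  cat(sprintf("  %d of %d regions kept\n", sum(x$keep_mask), length(x$falff)))
  invisible(x)
}

#' Subject inclusion by response-time criterion
#'
#' A fixed analysis window of `min_rt` seconds only makes sense for trials at
#' least that long, so subjects are kept only if at least `min_trials` of
#' their trials exceed `min_rt`. The rule used throughout is more than 10 s on at
#' least 13 of 25 trials (a majority), which removed 6 of 20 subjects.
#'
#' @param trial_tables Named list of trial tables.
#' @param min_rt Response-time cut, seconds (default 10).
#' @param min_trials Minimum number of qualifying trials (default 13).
#' @return Character vector of included subject ids.
#' @export
select_subjects <- function(trial_tables, min_rt = 10, min_trials = 13L) {
  keep <- vapply(names(trial_tables), function(s) {
    tab <- trial_tables[[s]]
    if (is.null(tab) || nrow(tab) == 0) {
      warning("subject ", s, " has an empty trial table; excluded")
      return(FALSE)
    }
    sum(tab$duration > min_rt) >= min_trials
  }, logical(1))
  names(trial_tables)[keep]
}
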