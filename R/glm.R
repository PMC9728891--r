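#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities — a positive response peaking a few
#' seconds after the neural event minus a scaled late undershoot — sampled on
#' the TR grid and normalized to unit peak. Defaults are the canonical values
#' (peak delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio
#' 1/6), for which the sampled kernel peaks near 5 s.
#'
#' @param peak_delay,undershoot_delay Delays of the response peak and the
#'   undershoot, seconds (gamma mean = delay).
#' @param peak_disp,undershoot_disp Dispersions (gamma scale), seconds.
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @param duration Kernel support, seconds.
#' @param tr Sampling interval, seconds.
#' @return Numeric vector sampled at `0, tr, 2 tr, ...` up to `duration`,
#'   with `max(h) == 1`.
#' @export
double_gamma_hrf <- function(peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             undershoot_ratio = 1 / 6,
                             duration = 32, tr = 0.545) {
  stopifnot(tr > 0, peak_delay > 0, undershoot_delay > 0,
            peak_disp > 0, undershoot_disp > 0, duration >= undershoot_delay)
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    undershoot_ratio *
      stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                    scale = undershoot_disp)
  h / max(h)
}

#' Build an event-related design matrix
#'
#' One regressor per response class ("yes", "no"): a boxcar of
#' `event_duration` seconds ending at each button press (the press time is
#' `onset + duration` of the trial), convolved with the canonical HRF, plus an
#' intercept. Events are placed on the TR grid by rounding toward the earlier
#' sample.
#'
#' @param trials Trial table (`onset`, `duration`, `response`).
#' @param series_len Number of time samples in the series to model.
#' @param tr Repetition time, seconds.
#' @param event_duration Modelled event length, seconds (default 1 s, ending
#'   at the press).
#' @param hrf Optional kernel; defaults to [double_gamma_hrf()] at `tr`.
#' @return An object of class `design_matrix`: list with `X` (time x
#'   regressor matrix, columns `yes`, `no`, `intercept`), `tr`, `trials`.
#' @export
build_design <- function(trials, series_len, tr, event_duration = 1,
                         hrf = NULL) {
  stopifnot(is.data.frame(trials), series_len > 0, tr > 0, event_duration > 0)
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr = tr)
  press <- trials$onset + trials$duration
  start <- press - event_duration
  if (any(start < 0)) stop2("event begins before the series start")
  if (any(press / tr > series_len))
    stop2("event extends past the end of the series")
  stick <- function(rows) {
    x <- numeric(series_len)
    for (k in rows) {
      i0 <- floor(start[k] / tr) + 1L
      i1 <- max(i0, floor(press[k] / tr))   # >= 1 sample per event
      x[i0:min(i1, series_len)] <- 1
    }
    convolve_truncate(x, hrf)
  }
  X <- cbind(yes = stick(which(trials$response == "yes")),
             no = stick(which(trials$response == "no")),
             intercept = 1)
  structure(list(X = X, tr = tr, trials = trials), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Event-related design: %d samples x %d regressors (%s)\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Fit an ordinary least-squares GLM to every region
#'
#' @param series A `roi_series`.
#' @param design A `design_matrix` with as many rows as the series has
#'   samples.
#' @return An object of class `glm_fit`: `beta` (regressor x region),
#'   `sigma2` (residual variance per region), `dof`, `xtx_inv`, `design`.
#' @export
fit_glm <- function(series, design) {
  stopifnot(inherits(series, "roi_series"), inherits(design, "design_matrix"))
  X <- design$X
  Y <- t(series$data)                       # time x region
  if (nrow(X) != nrow(Y))
    stop2("design has ", nrow(X), " rows but series has ", nrow(Y), " samples")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop2("design is rank deficient; collinear columns: ",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, Y)
  resid <- Y - X %*% beta
  dof <- nrow(X) - qx$rank
  sigma2 <- colSums(resid^2) / dof
  structure(list(beta = beta, sigma2 = sigma2, dof = dof,
                 xtx_inv = chol2inv(chol(crossprod(X))),
                 regressors = colnames(X), roi_ids = series$roi_ids,
                 subject_id = series$subject_id),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("GLM fit [%s]: %d regions, regressors %s, dof %d\n",
              x$subject_id, length(x$roi_ids),
              paste(x$regressors, collapse = "/"), x$dof))
  invisible(x)
}

#' Contrast estimates and t-statistics per region
#'
#' Effect is `c'beta`; its t-statistic uses the OLS variance
#' `sigma2 * c'(X'X)^-1 c`. The three standard contrasts of a yes/no design
#' are `c(1, -1, 0)` (yes > no), `c(-1, 1, 0)` (no > yes) and `c(1, 1, 0)`
#' (both > baseline).
#'
#' @param fit A `glm_fit`.
#' @param contrast Numeric weight per regressor.
#' @return Data frame with one row per region: `roi`, `effect`, `t`, `dof`.
#'   Regions with zero residual variance get `t = NA` (flagged with a
#'   warning).
#' @export
contrast_map <- function(fit, contrast) {
  stopifnot(inherits(fit, "glm_fit"),
            length(contrast) == length(fit$regressors))
  effect <- as.numeric(crossprod(contrast, fit$beta))
  cvc <- as.numeric(t(contrast) %*% fit$xtx_inv %*% contrast)
  se <- sqrt(fit$sigma2 * cvc)
  t <- ifelse(se > 0, effect / se, NA_real_)
  if (anyNA(t)) warning("zero-variance regions: t undefined, reported as NA")
  data.frame(roi = fit$roi_ids, effect = effect, t = t, dof = fit$dof,
             row.names = NULL, stringsAsFactors = FALSE)
}
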