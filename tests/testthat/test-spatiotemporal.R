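# Build a normalized_trials object directly from per-trial segments.
make_norm <- function(segs, labels = rep("yes", length(segs)), tr = 0.545) {
  L <- ncol(segs[[1]])
  structure(list(subject_id = "sub-01", roi_ids = rownames(segs[[1]]),
                 data = do.call(cbind, segs), L = L,
                 n_trials = length(segs), labels = labels, tr = tr,
                 mean_rt = L * tr),
            class = "normalized_trials")
}

# fir_response with a prescribed normalized (100-point) response matrix.
make_resp <- function(normalized, id = "sub-01") {
  structure(list(subject_id = id, roi_ids = rownames(normalized),
                 weights = normalized, L = ncol(normalized), tr = 0.545,
                 mean_rt = 20, normalized = normalized),
            class = "fir_response")
}

test_that("trial normalization resamples to the subject mean length in TR units", {
  tr <- 0.545
  # round(16.35 / 0.545) = 30 samples
  trials <- data.frame(onset = c(10, 26.35, 42.7),
                       duration = c(16.35, 16.35, 16.35),
                       response = c("yes", "no", "yes"))
  ser <- roi_series(matrix(stats::rnorm(2 * 140), 2), c("A", "B"), tr)
  norm <- normalize_trials(ser, trials)
  expect_equal(norm$L, 30)
  expect_equal(ncol(norm$data), 90)
  expect_equal(norm$labels, c("yes", "no", "yes"))

  # already-equal-length trials pass through as identity
  i0 <- floor(10 / tr) + 1
  expect_equal(norm$data[, 1:30], ser$data[, i0:(i0 + 29)])

  # a linear ramp stays linear with preserved endpoints under resampling
  ramp <- matrix(seq(0, 1, length.out = 20), 1, dimnames = list("A", NULL))
  rs <- neurodyn:::resample_rows(ramp, 50)
  expect_equal(unname(rs[1, 1]), 0); expect_equal(unname(rs[1, 50]), 1)
  expect_equal(max(abs(diff(diff(rs[1, ])))), 0, tolerance = 1e-12)

  # condition filter selects the labelled trials only
  yes_only <- normalize_trials(ser, trials, condition = "yes")
  expect_equal(yes_only$n_trials, 2)
  expect_error(normalize_trials(ser, trials[trials$response == "yes", ],
                                condition = "no"), "no trials")
})

test_that("FIR weights equal the per-lag trial mean for concatenated equal-length trials", {
  set.seed(12)
  segs <- lapply(1:3, function(m)
    matrix(stats::rnorm(2 * 12), 2, dimnames = list(c("A", "B"), NULL)))
  norm <- make_norm(segs)
  fir <- fit_fir(norm)
  oracle <- Reduce(`+`, segs) / 3
  expect_equal(fir$weights, oracle, tolerance = 1e-10, ignore_attr = TRUE)

  # identical noise-free segments are recovered exactly
  one <- matrix(sin(seq(0, 3, length.out = 15)), 1,
                dimnames = list("A", NULL))
  fir2 <- fit_fir(make_norm(list(one, one, one)))
  expect_equal(fir2$weights, one, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(fit_fir(make_norm(list(one))), "at least 2")
})

test_that("FIR recovers a planted HRF-convolved bump at the right lag", {
  tr <- 0.545
  stage <- stage_spec("A", 0.3, 0.5, amplitude_yes = 1)
  design <- study_design(1, 12, tr, rt_min = 16, rt_max = 16,
                         rt_mean_by_subject = 16, rt_sd = 0, seed = 5)
  coh <- synthesize_cohort(design, list(stage), noise_spec(white_sd = 0.2),
                           roi_ids = c("A", "B"))
  norm <- normalize_trials(coh$series[[1]], coh$trials[[1]])
  fir <- fit_fir(norm)
  tmpl <- make_stage_template(stage, 16, tr)
  expected <- neurodyn:::convolve_truncate(c(tmpl, numeric(norm$L)),
                                           double_gamma_hrf(tr = tr))[1:norm$L]
  expect_lt(abs(which.max(fir$weights["A", ]) - which.max(expected)), 2)
})

test_that("response normalization maps lags onto the percent axis, preserving peaks", {
  # L = 100 is the identity
  w <- matrix(stats::rnorm(100), 1, dimnames = list("A", NULL))
  fir <- make_resp(w)
  fir$normalized <- NULL; fir$L <- 100; fir$weights <- w
  expect_equal(normalize_response(fir)$normalized, w, ignore_attr = TRUE)

  # constant stays constant
  cw <- matrix(2, 1, 30, dimnames = list("A", NULL))
  firc <- make_resp(cw); firc$normalized <- NULL; firc$L <- 30
  expect_equal(unname(normalize_response(firc)$normalized[1, ]), rep(2, 100))

  # a tent peak at sample 15 of 30 lands at midpoint of the percent axis
  tent <- matrix(pmax(0, 1 - abs(seq_len(30) - 15) / 5), 1,
                 dimnames = list("A", NULL))
  firt <- make_resp(tent); firt$normalized <- NULL; firt$L <- 30
  peak_idx <- which.max(normalize_response(firt)$normalized[1, ])
  expect_lte(abs(peak_idx - 50), 1)
})

test_that("consensus windows follow the default analysis grid and count unique region peaks", {
  # 17 windows at 20% length and 5% step
  flat <- matrix(0, 3, 100, dimnames = list(c("A", "B", "C"), NULL))
  bump <- flat
  bump["A", ] <- stats::dnorm(seq(0, 100, length.out = 100), 30.2, 4)
  resp <- lapply(1:5, function(s) make_resp(bump, sprintf("sub-%02d", s)))
  m <- consensus_map(resp, min_subjects = 4)
  expect_equal(m$window_starts, seq(0, 80, by = 5))
  expect_equal(ncol(m$bins), 17)

  # the single planted bump fills exactly the windows covering its peak
  peak_pct <- (which.max(bump["A", ]) - 1) / 99 * 100
  covering <- m$window_starts <= peak_pct & m$window_starts + 20 >= peak_pct
  expect_true(all(m$bins["A", covering] == 5))
  expect_true(all(m$bins["A", !covering] == 0))
  expect_true(all(m$bins[c("B", "C"), ] == 0))

  # defaults carry the protocol parameters
  f <- formals(consensus_map)
  expect_equal(f$window_pct, 20); expect_equal(f$step_pct, 5)
  expect_equal(eval(f$top_k), 20L); expect_equal(eval(f$min_subjects), 8L)

  # bins never exceed the subject count
  expect_lte(max(m$bins), length(resp))
})

test_that("top-k ranking keeps only the strongest peaks and breaks ties deterministically", {
  set.seed(3)
  n_roi <- 30
  base <- matrix(0, n_roi, 100, dimnames = list(sprintf("R%02d", 1:n_roi), NULL))
  x <- seq(0, 100, length.out = 100)
  for (i in 1:n_roi) base[i, ] <- (n_roi + 1 - i) * stats::dnorm(x, 50.3, 3)
  resp <- list(make_resp(base))
  m1 <- consensus_map(resp, top_k = 5, min_subjects = 1)
  w_mid <- which(m1$window_starts == 40)
  expect_equal(sum(m1$bins[, w_mid]), 5)            # only the 5 largest peaks
  expect_equal(unname(m1$bins[1:5, w_mid]), rep(1L, 5))

  # shuffling region labels independently per subject washes consensus out
  resp14 <- lapply(1:14, function(s) {
    r <- matrix(stats::rnorm(n_roi * 100), n_roi,
                dimnames = list(sprintf("R%02d", 1:n_roi), NULL))
    make_resp(r, sprintf("sub-%02d", s))
  })
  mm <- consensus_map(resp14, top_k = 5, min_subjects = 8)
  expect_lt(mean(mm$thresholded), 0.01)
})

test_that("condition differences isolate cells with a planted yes-only effect", {
  mk_map <- function(bins) {
    structure(list(bins = bins, window_starts = seq(0, 80, 5),
                   window_pct = 20, step_pct = 5, top_k = 20L,
                   min_subjects = 8L, thresholded = bins >= 8,
                   condition = "x", n_subjects = 14,
                   roi_ids = rownames(bins)),
              class = "spatiotemporal_map")
  }
  b <- matrix(5L, 2, 17, dimnames = list(c("A", "B"), NULL))
  expect_equal(sum(condition_difference(mk_map(b), mk_map(b))$retained), 0)

  b2 <- b; b2["A", 10] <- 14L
  b3 <- b; b3["A", 10] <- 3L
  d <- condition_difference(mk_map(b2), mk_map(b3), min_diff = 7)
  expect_equal(sum(d$retained), 1)
  expect_equal(unname(d$dominant["A", 10]), "yes")
  expect_equal(unname(d$difference["A", 10]), 11L)
  expect_error(condition_difference(mk_map(b),
                                    mk_map(b[, 1:10][, rep(1:10, 2)][, 1:17,
                                                                    drop = FALSE])),
               NA)
})

test_that("a planted yes-only stage is detected in the window where its response peaks", {
  # selection fraction mirrors the study regime: few top slots among many regions
  rois <- c(sprintf("SIG%d", 1:3), sprintf("BG%02d", 1:27))
  stages <- list(stage_spec(rois[1:3], 0.2, 0.9, amplitude_yes = 2.5,
                            amplitude_no = 0))
  design <- study_design(14, 25, TR, rt_min = 10, rt_max = 45,
                         rt_mean_by_subject = seq(15, 27, length.out = 14),
                         rt_sd = 2, seed = 9)
  coh <- synthesize_cohort(design, stages, noise_spec(white_sd = 1),
                           roi_ids = rois)
  m_yes <- cohort_consensus(coh, "yes", top_k = 3, min_subjects = 8)
  m_no <- cohort_consensus(coh, "no", top_k = 3, min_subjects = 8)
  d <- condition_difference(m_yes, m_no, min_diff = 7)
  sig_rows <- match(c("SIG1", "SIG2", "SIG3"), d$roi_ids)
  expect_gt(sum(d$retained[sig_rows, ]), 0)
  # every yes-dominant cell belongs to a region carrying the yes-only stage
  yes_cells <- which(d$dominant == "yes", arr.ind = TRUE)
  expect_true(all(yes_cells[, "row"] %in% sig_rows))
  # the detected windows sit where the ground truth predicts the BOLD peak
  stage <- coh$truth$stages[[1]]
  exp_pct <- expected_stage_peak_pct(stage, mean(sapply(coh$trials, function(t)
    mean(t$duration))), coh$design$tr)
  hit <- which(colSums(d$retained[sig_rows, , drop = FALSE]) > 0)
  centers <- d$window_starts[hit] + 10
  expect_true(any(abs(centers - exp_pct) <= 15))
})

test_that("stage ordering is recovered after compensating the hemodynamic delay", {
  coh <- recovery_cohort(seed = 41)
  m <- cohort_consensus(coh)
  rec <- stage_order_recovery(m, recovery_sets, cohort_delay_pct(coh))
  expect_true(rec$ordered)
  # background regions stay below consensus nearly everywhere
  bg <- grepl("^BG", m$roi_ids)
  expect_lt(mean(m$thresholded[bg, ]), 0.01)
})

test_that("grid refinement moves peak-window assignments by at most one step", {
  f <- function(t) exp(-(t - 0.4)^2 / 0.01) + 0.5 * exp(-(t - 0.8)^2 / 0.005)
  seg_l <- matrix(f(seq(0, 1, length.out = 30)), 1, dimnames = list("A", NULL))
  seg_2l <- matrix(f(seq(0, 1, length.out = 60)), 1, dimnames = list("A", NULL))
  m_l <- consensus_map(list(make_resp(neurodyn:::resample_rows(seg_l, 100))),
                       top_k = 2, min_subjects = 1)
  m_2l <- consensus_map(list(make_resp(neurodyn:::resample_rows(seg_2l, 100))),
                        top_k = 2, min_subjects = 1)
  peak_win <- function(m) m$window_starts[which.max(m$bins["A", ])]
  expect_lte(abs(peak_win(m_l) - peak_win(m_2l)), 5)
})
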