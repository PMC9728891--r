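test_that("trial timings are consecutive, anchored at the lead-in, and reproducible", {
  d <- study_design(3, 3, 0.5, rt_min = 12, rt_max = 12,
                    rt_mean_by_subject = 12, rt_sd = 0, seed = 7)
  tt <- sample_trial_timings(d)
  expect_length(tt, 3)
  expect_equal(tt[[1]]$onset, c(10, 22, 34))
  expect_equal(tt[[2]]$duration, rep(12, 3))

  d2 <- study_design(4, 8, 0.545, 5, 40, c(11, 18, 25, 30), seed = 42)
  expect_identical(sample_trial_timings(d2), sample_trial_timings(d2))
  # conservation: no gaps between consecutive trials
  for (tab in sample_trial_timings(d2))
    expect_equal(diff(tab$onset), tab$duration[-nrow(tab)])
  expect_error(study_design(2, 5, 0.5, 10, 20, c(15, 25), seed = 1),
               "rt_min")
})

test_that("truncated-normal sampler hits each subject's mean response time", {
  d <- study_design(5, 10000, 0.5, rt_min = 5, rt_max = 45,
                    rt_mean_by_subject = c(11, 16, 21, 26, 30),
                    rt_sd = 3, seed = 3)
  tt <- sample_trial_timings(d)
  emp <- vapply(tt, function(tab) mean(tab$duration), numeric(1))
  expect_true(all(abs(emp - d$rt_mean_by_subject) / d$rt_mean_by_subject < 0.05))
  expect_true(all(unlist(lapply(tt, `[[`, "duration")) >= 5))
  expect_true(all(unlist(lapply(tt, `[[`, "duration")) <= 45))
})

test_that("stage templates are boxcars on the requested band of decision time", {
  full <- stage_spec("A", 0, 1, amplitude_yes = 1)
  expect_equal(make_stage_template(full, 10, 0.5), rep(1, 20))

  silent_yes <- stage_spec("A", 0, 1, amplitude_yes = 0, amplitude_no = 2)
  expect_equal(make_stage_template(silent_yes, 10, 0.5, "yes"), rep(0, 20))
  expect_equal(make_stage_template(silent_yes, 10, 0.5, "no"), rep(2, 20))

  # index-arithmetic oracle for a [20%, 50%] band of a 20-s trial at TR 0.545
  band <- stage_spec("A", 0.2, 0.5, amplitude_yes = 1)
  tmpl <- make_stage_template(band, 20, 0.545)
  times <- (seq_along(tmpl) - 1) * 0.545
  expect_equal(tmpl, as.numeric(times >= 4 & times < 10))
  expect_length(tmpl, ceiling(20 / 0.545))
})

test_that("noise-free subjects reproduce the convolved stage template exactly", {
  trials <- data.frame(onset = c(10, 25), duration = c(15, 15),
                       response = c("yes", "yes"))
  st <- stage_spec("A", 0.2, 0.6, amplitude_yes = 1)
  quiet <- noise_spec(white_sd = 0, drift_amplitude = 0)
  ser <- synthesize_subject(trials, list(st), quiet, tr = 0.5, seed = 1,
                            roi_ids = c("A", "B"))
  hrf <- double_gamma_hrf(tr = 0.5)
  x <- numeric(ncol(ser$data))
  for (k in 1:2) {
    tmpl <- make_stage_template(st, 15, 0.5)
    i0 <- floor(trials$onset[k] / 0.5) + 1
    x[i0:(i0 + length(tmpl) - 1)] <- x[i0:(i0 + length(tmpl) - 1)] + tmpl
  }
  expected <- stats::convolve(c(x, numeric(length(hrf))), rev(hrf),
                              type = "open")[seq_along(x)]
  expect_equal(unname(ser$data["A", ]), expected, tolerance = 1e-12)
  # silent before the first onset, active afterwards, silent region B
  expect_equal(max(abs(ser$data["A", 1:20])), 0)
  expect_gt(max(ser$data["A", ]), 0)
  expect_equal(max(abs(ser$data["B", ])), 0)

  # linearity: doubling the amplitude doubles the noise-free series
  st2 <- stage_spec("A", 0.2, 0.6, amplitude_yes = 2)
  ser2 <- synthesize_subject(trials, list(st2), quiet, tr = 0.5, seed = 1,
                             roi_ids = c("A", "B"))
  expect_equal(ser2$data, 2 * ser$data, tolerance = 1e-12)
})

test_that("planted noise-block correlation is recovered from long runs", {
  trials <- data.frame(onset = 10, duration = 5440, response = "yes")
  ns <- noise_spec(white_sd = 1, correlation_blocks =
                     list(list(roi_ids = c("A", "B"), r = 0.6)))
  ser <- synthesize_subject(trials, list(), ns, tr = 0.545, seed = 5,
                            roi_ids = c("A", "B", "C"))
  expect_gt(ncol(ser$data), 9000)
  expect_lt(abs(cor(ser$data["A", ], ser$data["B", ]) - 0.6), 0.05)
  expect_lt(abs(cor(ser$data["A", ], ser$data["C", ])), 0.05)

  # identical stages with no noise give perfectly correlated regions
  st <- stage_spec(c("A", "B"), 0.1, 0.9, amplitude_yes = 1)
  ser2 <- synthesize_subject(data.frame(onset = 10, duration = 20,
                                        response = "yes"),
                             list(st), noise_spec(white_sd = 0),
                             tr = 0.5, seed = 1, roi_ids = c("A", "B"))
  expect_equal(cor(ser2$data["A", ], ser2$data["B", ]), 1)

  expect_error(noise_spec(correlation_blocks = list(
    list(roi_ids = c("A", "B"), r = 0.5),
    list(roi_ids = c("B", "C"), r = 0.5))), "disjoint")
})

test_that("cohorts are consistent, deterministic and match the study preset", {
  d <- study_design(2, 4, 0.5, 8, 20, c(12, 15), seed = 11)
  st <- list(stage_spec("A", 0, 0.5, 1))
  coh <- synthesize_cohort(d, st, noise_spec(white_sd = 0.5),
                           roi_ids = c("A", "B"))
  expect_length(coh$series, 2)
  for (s in 1:2) {
    tab <- coh$trials[[s]]
    last <- (tab$onset[4] + tab$duration[4]) / d$tr
    expect_gte(ncol(coh$series[[s]]$data), ceiling(last))
    expect_true(all(coh$truth$labels[[s]] %in% c("yes", "no")))
  }
  coh2 <- synthesize_cohort(d, st, noise_spec(white_sd = 0.5),
                            roi_ids = c("A", "B"))
  expect_identical(coh$series[[1]]$data, coh2$series[[1]]$data)

  pd <- app_study_design(seed = 1)
  expect_equal(pd$n_subjects, 20L)
  expect_equal(pd$n_trials, 25L)
  expect_equal(pd$tr, 0.545)
  expect_equal(pd$lead_in, 10)
})

test_that("datasets round-trip through disk, including the volume rendering", {
  d <- study_design(2, 3, 0.5, 8, 20, c(12, 15), seed = 2)
  coh <- synthesize_cohort(d, list(stage_spec("A", 0, 0.5, 1)),
                           noise_spec(white_sd = 0.3),
                           roi_ids = c("A", "B", "C"))
  dir <- tempfile("ds_")
  write_dataset(coh, dir, nifti = TRUE)

  ev <- read.delim(file.path(dir, "sub-01_events.tsv"))
  expect_identical(colnames(ev), c("onset", "duration", "response"))

  back <- read_dataset(dir)
  expect_equal(back$tr, 0.5)
  expect_equal(back$trials[["sub-02"]], coh$trials[["sub-02"]])
  expect_equal(back$series[["sub-01"]]$data, coh$series[["sub-01"]]$data,
               tolerance = 1e-6, ignore_attr = TRUE)

  img <- RNifti::readNifti(file.path(dir, "sub-01_bold.nii"))
  expect_equal(RNifti::pixdim(img)[4], 0.5, tolerance = 1e-6)
  atlas <- RNifti::readNifti(file.path(dir, "atlas.nii"))
  rec <- extract_roi_timeseries(unclass(img), round(unclass(atlas)),
                                stats::setNames(1:3, c("A", "B", "C")),
                                tr = 0.5)
  expect_equal(rec$data, coh$series[["sub-01"]]$data, tolerance = 1e-6)
})

test_that("planted stage peaks are predicted where the uncorrected map will show them", {
  early <- stage_spec("A", 0, 0.2, 1)
  late <- stage_spec("A", 0.8, 1, 1)
  p_early <- expected_stage_peak_pct(early, rt = 20, tr = 0.545)
  p_late <- expected_stage_peak_pct(late, rt = 20, tr = 0.545)
  # early stage: observed a hemodynamic delay after its band
  expect_gt(p_early, 20); expect_lt(p_early, 50)
  # press-locked stage: peak carries over into the next trial's early bins
  expect_lt(p_late, 30)
})
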