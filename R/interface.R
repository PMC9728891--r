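#' Assemble a pipeline configuration
#'
#' Collects every stage parameter with the defaults of the emulated study protocol: TR 0.545 s,
#' 10-s connectivity windows, per-trial alpha 0.05, group consensus at 8 of
#' 14 subjects, 20% windows stepped by 5% with the top 20 peaks and a bin
#' threshold of 8 for the spatiotemporal map, condition-difference threshold
#' 7, fALFF threshold 1, subject inclusion at more than 10 s on at least 13
#' trials, fivefold cross-validation.
#'
#' @param seed Integer seed driving synthesis and fold assignment.
#' @param out_dir Output directory for artifacts.
#' @param ... Overrides for any default listed above.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("neurodyn_run_"),
                            ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    tr = 0.545, window_length = 10, alpha = 0.05,
    min_subjects_dfc = 8L, window_pct = 20, step_pct = 5, top_k = 20L,
    min_subjects_map = 8L, min_diff = 7L,
    falff_threshold = 1, min_rt = 10, min_trials = 13L,
    n_folds = 5L, n_permutations = 0L, n_decoding_rois = 10L,
    detrend_order = 3L, event_duration = 1,
    yes_effect = 1.5, figures = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop2("unknown options: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic study-like cohort
#'
#' Generates (or reads) a cohort, then executes subject inclusion, drift
#' removal, fALFF filtering, GLM contrasts, start/end dynamic-connectivity
#' consensus with difference graph, trial-length-normalized FIR
#' spatiotemporal consensus maps for all/yes/no trials with the yes-no
#' difference, and connectivity-feature decoding. Every stage artifact is
#' written under `config$out_dir` together with a machine-readable parameter
#' manifest; a run log records stage timings.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional `bold_cohort`; by default a study-like cohort is
#'   synthesized from `config$seed`.
#' @return Invisibly, a list with every stage result (`cohort`, `included`,
#'   `falff`, `glm`, `dfc`, `stmap`, `decoding`, `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  tic <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    log_lines <<- c(log_lines, sprintf("%-14s %8.2f s", label,
                                       proc.time()[["elapsed"]] - t0))
    val
  }

  if (is.null(cohort))
    cohort <- tic("synthesize", app_study_cohort(seed = config$seed,
                                             yes_effect = config$yes_effect))

  ## -- prep: inclusion, drift removal, fALFF filtering ---------------------
  included <- select_subjects(cohort$trials, config$min_rt, config$min_trials)
  if (!length(included)) stop2("no subject satisfies the inclusion rule")
  detr <- tic("detrend", lapply(cohort$series[included], detrend_timeseries,
                                basis_order = config$detrend_order))
  falff <- tic("falff", lapply(detr, compute_falff,
                               threshold = config$falff_threshold))
  # the connectivity branch drops noise components: a region survives when it
  # passes the fALFF rule in a majority of subjects; the spatiotemporal branch
  # keeps the full atlas universe, as in the emulated analysis
  keep_count <- Reduce(`+`, lapply(falff, `[[`, "keep_mask"))
  roi_keep <- cohort$series[[1]]$roi_ids[keep_count > length(included) / 2]
  if (length(roi_keep) < 2) stop2("fALFF filtering left fewer than 2 regions")
  dfc_series <- lapply(detr, function(s)
    roi_series(s$data[roi_keep, , drop = FALSE], roi_keep, s$tr, s$subject_id))

  ## -- glm -----------------------------------------------------------------
  contrasts <- list(yes_gt_no = c(1, -1, 0), no_gt_yes = c(-1, 1, 0),
                    both_gt_baseline = c(1, 1, 0))
  glm_res <- tic("glm", {
    fits <- lapply(included, function(s) {
      des <- build_design(cohort$trials[[s]], ncol(detr[[s]]$data),
                          config$tr, config$event_duration)
      fit_glm(detr[[s]], des)
    })
    names(fits) <- included
    lapply(contrasts, function(cv) {
      per_subj <- lapply(fits, contrast_map, contrast = cv)
      eff <- sapply(per_subj, `[[`, "effect")
      tt <- sapply(per_subj, `[[`, "t")
      data.frame(roi = per_subj[[1]]$roi, mean_effect = rowMeans(eff),
                 median_t = apply(tt, 1, stats::median),
                 stringsAsFactors = FALSE)
    })
  })
  for (nm in names(glm_res))
    write.table(glm_res[[nm]],
                file.path(config$out_dir, paste0("glm_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- dfc: start/end consensus + difference -------------------------------
  dfc_res <- tic("dfc", {
    one_epoch <- function(anchor, label) {
      es <- lapply(included, function(s)
        subject_connectivity(
          extract_windows(dfc_series[[s]], cohort$trials[[s]], anchor,
                          config$window_length),
          alpha = config$alpha))
      group_consistency(es, config$min_subjects_dfc, epoch = label)
    }
    cs <- one_epoch("trial_start", "start")
    ce <- one_epoch("trial_end", "end")
    list(start = cs, end = ce, difference = connectivity_difference(cs, ce))
  })
  write.table(as.data.frame(dfc_res$start),
              file.path(config$out_dir, "dfc_start.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(dfc_res$end),
              file.path(config$out_dir, "dfc_end.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(roi_a = dfc_res$start$roi_ids[dfc_res$start$pairs[, 1]],
               roi_b = dfc_res$start$roi_ids[dfc_res$start$pairs[, 2]],
               category = dfc_res$difference$category),
    file.path(config$out_dir, "dfc_difference.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- spatiotemporal ------------------------------------------------------
  stmap <- tic("stmap", {
    one_cond <- function(cond) {
      resp <- lapply(included, function(s)
        normalize_response(fit_fir(normalize_trials(
          detr[[s]], cohort$trials[[s]], condition = cond))))
      consensus_map(resp, config$window_pct, config$step_pct, config$top_k,
                    config$min_subjects_map, condition = cond)
    }
    maps <- list(all = one_cond("all"), yes = one_cond("yes"),
                 no = one_cond("no"))
    maps$difference <- condition_difference(maps$yes, maps$no,
                                            config$min_diff)
    maps
  })
  for (cond in c("all", "yes", "no"))
    write.table(as.data.frame(stmap[[cond]]),
                file.path(config$out_dir, paste0("stmap_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  diff_df <- data.frame(
    roi = rep(stmap$difference$roi_ids, times = ncol(stmap$difference$difference)),
    window_start_pct = rep(stmap$difference$window_starts,
                           each = length(stmap$difference$roi_ids)),
    difference = as.vector(stmap$difference$difference),
    retained = as.vector(stmap$difference$retained))
  write.table(diff_df, file.path(config$out_dir, "stmap_difference.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- decoding ------------------------------------------------------------
  decoding <- tic("decoding", {
    score <- apply(abs(stmap$difference$difference), 1L, max)
    rois <- stmap$difference$roi_ids[
      order(-score, seq_along(score))][seq_len(min(config$n_decoding_rois,
                                                   length(score)))]
    tabs <- lapply(included, function(s)
      trial_features(normalize_trials(detr[[s]], cohort$trials[[s]]), rois))
    pooled <- pool_features(tabs)
    cv <- crossval_classify(pooled, config$n_folds, seed = config$seed)
    perm <- if (config$n_permutations >= 100)
      permutation_chance(pooled, config$n_permutations, seed = config$seed,
                         n_folds = config$n_folds)
    list(rois = rois, table = pooled, cv = cv, permutation = perm)
  })
  jsonlite::write_json(
    list(rois = decoding$rois,
         train_acc_mean = decoding$cv$train_acc_mean,
         train_acc_sd = decoding$cv$train_acc_sd,
         test_acc_mean = decoding$cv$test_acc_mean,
         test_acc_sd = decoding$cv$test_acc_sd,
         n_folds = decoding$cv$n_folds,
         permutation_p = decoding$permutation$p_value),
    file.path(config$out_dir, "decoding.json"),
    auto_unbox = TRUE, digits = NA, null = "null")

  ## -- figures + manifest --------------------------------------------------
  if (isTRUE(config$figures)) {
    render_connectogram(dfc_res$start,
                        file.path(config$out_dir, "connectogram_start.png"))
    render_connectogram(dfc_res$difference,
                        file.path(config$out_dir, "connectogram_difference.png"))
    render_spatiotemporal(stmap$all,
                          file.path(config$out_dir, "stmap_all.png"))
    render_spatiotemporal(stmap$difference,
                          file.path(config$out_dir, "stmap_difference.png"))
  }
  manifest <- unclass(config)
  manifest$out_dir <- NULL            # machine-specific, not a parameter
  manifest$included_subjects <- included
  manifest$kept_rois <- roi_keep
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(cohort = cohort, included = included, falff = falff,
                 glm = glm_res, dfc = dfc_res, stmap = stmap,
                 decoding = decoding, out_dir = config$out_dir))
}

#' Render a connectivity consensus graph as a connectogram
#'
#' Regions on a circle; retained edges drawn as chords with width
#' proportional to the number of supporting subjects and color by correlation
#' sign (blue positive, red negative). For a difference object, thin lines
#' mark start-only edges and thick lines end-only edges, matching the figure
#' convention of the emulated analysis.
#'
#' @param consensus A `connectivity_consensus` or `connectivity_difference`.
#' @param out_path Optional PNG path; when `NULL`, draws on the active device.
#' @return `out_path` (or `NULL`), invisibly.
#' @export
render_connectogram <- function(consensus, out_path = NULL) {
  if (!is.null(out_path)) {
    grDevices::png(out_path, width = 800, height = 800)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  is_diff <- inherits(consensus, "connectivity_difference")
  roi_ids <- consensus$roi_ids
  n <- length(roi_ids)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  xy <- cbind(cos(theta), sin(theta))
  op <- graphics::par(mar = c(1, 1, 2, 1))
  if (is.null(out_path)) on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = if (is_diff) "Connectivity difference (start vs end)"
                        else sprintf("Connectivity consensus (%s)",
                                     consensus$epoch %||% ""))
  pairs <- consensus$pairs
  if (is_diff) {
    keep <- consensus$category %in% c("start_only", "end_only")
    if (!any(keep)) warning("no differing edges; blank connectogram")
    for (k in which(keep)) {
      lw <- if (consensus$category[k] == "end_only") 4 else 1
      graphics::segments(xy[pairs[k, 1], 1], xy[pairs[k, 1], 2],
                         xy[pairs[k, 2], 1], xy[pairs[k, 2], 2],
                         lwd = lw, col = "grey30")
    }
  } else {
    if (!any(consensus$retained)) warning("empty consensus; blank connectogram")
    for (k in which(consensus$retained)) {
      w <- 1 + 4 * (consensus$n_subjects[k] - consensus$min_subjects) /
        max(1, max(consensus$n_subjects) - consensus$min_subjects)
      graphics::segments(xy[pairs[k, 1], 1], xy[pairs[k, 1], 2],
                         xy[pairs[k, 2], 1], xy[pairs[k, 2], 2],
                         lwd = w,
                         col = if (consensus$sign[k] == "+") "blue" else "red")
    }
  }
  graphics::points(xy, pch = 21, bg = "white", cex = 2.2)
  graphics::text(1.12 * xy, labels = roi_ids, cex = 0.7)
  invisible(out_path)
}

#' @export
plot.connectivity_consensus <- function(x, ...) render_connectogram(x)

#' @export
plot.connectivity_difference <- function(x, ...) render_connectogram(x)

#' Render a spatiotemporal consensus map as a heatmap
#'
#' Normalized decision time (0-100%) on the x-axis, regions on the y-axis,
#' color encoding the number of subjects; only cells at or above the
#' consensus threshold are shown. Difference maps use a diverging red/blue
#' scale (red = more subjects on yes-trials, blue = no-trials).
#'
#' @param map A `spatiotemporal_map` or `spatiotemporal_difference`.
#' @param out_path Optional PNG path; when `NULL`, draws on the active device.
#' @return `out_path` (or `NULL`), invisibly.
#' @export
render_spatiotemporal <- function(map, out_path = NULL) {
  if (!is.null(out_path)) {
    grDevices::png(out_path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  is_diff <- inherits(map, "spatiotemporal_difference")
  vals <- if (is_diff) map$difference else map$bins
  show <- if (is_diff) map$retained else map$thresholded
  z <- vals; z[!show] <- NA
  if (!any(show)) warning("no cells above threshold; blank map")
  xs <- map$window_starts + map$window_pct / 2
  op <- graphics::par(mar = c(4.5, 6, 2.5, 5))
  if (is.null(out_path)) on.exit(graphics::par(op), add = TRUE)
  if (is_diff) {
    m <- max(1, max(abs(vals)))
    breaks <- seq(-m, m, length.out = 22)
    cols <- grDevices::hcl.colors(21, "Blue-Red 2")
    ttl <- sprintf("Yes - No consensus difference (|diff| >= %d)", map$min_diff)
  } else {
    m <- max(1, max(vals))
    breaks <- seq(map$min_subjects - 0.5, m + 0.5,
                  length.out = max(2, m - map$min_subjects + 2))
    cols <- grDevices::hcl.colors(length(breaks) - 1, "YlOrRd", rev = TRUE)
    ttl <- sprintf("Spatiotemporal consensus (%s trials, >= %d subjects)",
                   map$condition, map$min_subjects)
  }
  graphics::image(xs, seq_along(map$roi_ids), t(z), zlim = range(breaks),
                  breaks = breaks, col = cols, axes = FALSE,
                  xlab = "normalized decision time (%)", ylab = "", main = ttl,
                  xlim = c(0, 100))
  graphics::axis(1, at = seq(0, 100, 20))
  graphics::axis(2, at = seq_along(map$roi_ids), labels = map$roi_ids,
                 las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(out_path)
}

#' @export
plot.spatiotemporal_map <- function(x, ...) render_spatiotemporal(x)

#' @export
plot.spatiotemporal_difference <- function(x, ...) render_spatiotemporal(x)

#' @export
plot.fir_response <- function(x, ...) {
  y <- if (is.null(x$normalized)) x$weights else x$normalized
  xax <- if (is.null(x$normalized)) (seq_len(x$L) - 1) * x$tr
         else seq(0, 100, length.out = 100)
  graphics::matplot(xax, t(y), type = "l", lty = 1,
                    xlab = if (is.null(x$normalized)) "time (s)"
                           else "normalized decision time (%)",
                    ylab = "FIR weight",
                    main = sprintf("FIR response [%s]", x$subject_id), ...)
  invisible(x)
}
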