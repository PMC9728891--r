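#' Extract fixed-length trial-anchored windows
#'
#' Because self-paced trials differ in length, windowed connectivity uses a
#' fixed window (10 s in the emulated analysis) anchored either at the trial
#' start (stimulus onset) or at the trial end (ending at the button press).
#' Trials shorter than the window are skipped rather than padded.
#'
#' @param series A `roi_series`.
#' @param trials Trial table for the same subject.
#' @param anchor `"trial_start"` or `"trial_end"`.
#' @param length Window length in seconds (default 10); the window holds
#'   `floor(length / tr)` samples.
#' @return List of region-by-sample matrices, one per eligible trial, with
#'   attributes `trial_index` (row numbers of the trials used) and `n_skipped`.
#' @export
extract_windows <- function(series, trials,
                            anchor = c("trial_start", "trial_end"),
                            length = 10) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(series, "roi_series"), length > 0)
  tr <- series$tr
  n_samp <- floor(length / tr)
  n_time <- ncol(series$data)
  eligible <- which(trials$duration >= length)
  if (!base::length(eligible)) stop2("no trial is at least as long as the window")
  segs <- vector("list", base::length(eligible))
  for (m in seq_along(eligible)) {
    k <- eligible[m]
    if (anchor == "trial_start") {
      i0 <- floor(trials$onset[k] / tr) + 1L
      idx <- i0:(i0 + n_samp - 1L)
    } else {
      i1 <- floor((trials$onset[k] + trials$duration[k]) / tr)
      idx <- (i1 - n_samp + 1L):i1
    }
    if (idx[base::length(idx)] > n_time)
      stop2("trial ", k, " window extends past the series end")
    segs[[m]] <- series$data[, idx, drop = FALSE]
  }
  attr(segs, "trial_index") <- eligible
  attr(segs, "n_skipped") <- nrow(trials) - base::length(eligible)
  attr(segs, "anchor") <- anchor
  segs
}

# r and two-sided p (t-transform, n-2 dof) for all column pairs of t(seg).
# Constant rows yield NA entries (the caller excludes those pairs).
cor_with_p <- function(seg) {
  n <- ncol(seg)
  r <- suppressWarnings(cor(t(seg)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  list(r = r, p = p)
}

#' Per-subject windowed connectivity over all region pairs
#'
#' For every unordered region pair, the within-window Pearson correlation and
#' its two-sided p-value (t-transform on n-2 degrees of freedom) are computed
#' per trial. Trials with p above `alpha` are discarded for that pair; the
#' subject-level correlation is the mean over retained trials (or over all
#' eligible trials, if `average = "all"`), and the pair counts as significant
#' for the subject when retained trials form a majority of eligible trials.
#'
#' @param segments Output of [extract_windows()].
#' @param alpha Per-trial significance level (default 0.05).
#' @param average `"retained"` (default) averages r over significant trials
#'   only; `"all"` divides by the number of eligible trials.
#' @return An object of class `edge_stats`: `roi_ids`, `pairs` (index
#'   matrix), per-pair `r` and `p` (pair x trial), `mean_r`, `n_retained`,
#'   `n_eligible`, `significant`.
#' @export
subject_connectivity <- function(segments, alpha = 0.05,
                                 average = c("retained", "all")) {
  average <- match.arg(average)
  n_trials <- length(segments)
  if (n_trials < 2) stop2("need at least 2 trial windows")
  roi_ids <- rownames(segments[[1]])
  n_roi <- nrow(segments[[1]])
  pairs <- pair_index(n_roi)
  up <- upper.tri(matrix(0, n_roi, n_roi))
  r_mat <- p_mat <- matrix(NA_real_, nrow(pairs), n_trials)
  for (m in seq_len(n_trials)) {
    seg <- segments[[m]]
    constant <- apply(seg, 1L, function(v) max(v) == min(v))
    cp <- cor_with_p(seg)
    r <- t(cp$r)[t(up)]          # row-major upper triangle = pair order
    p <- t(cp$p)[t(up)]
    bad <- constant[pairs[, 1]] | constant[pairs[, 2]]
    r[bad] <- NA_real_; p[bad] <- NA_real_
    r_mat[, m] <- r; p_mat[, m] <- p
  }
  defined <- !is.na(p_mat)
  retained <- defined & p_mat <= alpha
  n_retained <- rowSums(retained)
  n_eligible <- rowSums(defined)
  sum_r <- rowSums(ifelse(retained, r_mat, 0))
  denom <- if (average == "retained") n_retained else n_eligible
  mean_r <- ifelse(denom > 0, sum_r / denom, NA_real_)
  structure(list(roi_ids = roi_ids, pairs = pairs,
                 r = r_mat, p = p_mat, alpha = alpha,
                 mean_r = mean_r, n_retained = n_retained,
                 n_eligible = n_eligible,
                 significant = n_retained > n_eligible / 2),
            class = "edge_stats")
}

#' @export
print.edge_stats <- function(x, ...) {
  cat(sprintf(
    "Windowed connectivity: %d regions, %d pairs, %d trials; %d pairs significant (alpha %g)\n",
    length(x$roi_ids), nrow(x$pairs), ncol(x$r), sum(x$significant), x$alpha))
  invisible(x)
}

#' Group-level connectivity consensus
#'
#' An edge is retained when it is subject-significant for at least
#' `min_subjects` subjects (the rule: more than half of 14 subjects, i.e. a
#' threshold of 8). Edge sign is the sign of the mean of subject-level mean
#' correlations.
#'
#' @param edge_list List of `edge_stats`, one per subject, over the same
#'   region universe.
#' @param min_subjects Consensus threshold (default 8).
#' @param epoch Optional label ("start"/"end") carried to outputs.
#' @return An object of class `connectivity_consensus`: `roi_ids`, `pairs`,
#'   `n_subjects` per edge, `mean_r`, `sign`, `retained`, `min_subjects`,
#'   `epoch`.
#' @export
group_consistency <- function(edge_list, min_subjects = 8L, epoch = NA) {
  stopifnot(length(edge_list) >= 1)
  roi_ids <- edge_list[[1]]$roi_ids
  for (e in edge_list)
    if (!identical(e$roi_ids, roi_ids)) stop2("subjects use different ROI sets")
  n_pair <- nrow(edge_list[[1]]$pairs)
  sig <- matrix(vapply(edge_list, `[[`, logical(n_pair), "significant"),
                nrow = n_pair)
  mr <- matrix(vapply(edge_list, `[[`, numeric(n_pair), "mean_r"),
               nrow = n_pair)
  count <- rowSums(sig)
  mean_r <- rowMeans(mr, na.rm = TRUE)
  structure(list(roi_ids = roi_ids, pairs = edge_list[[1]]$pairs,
                 n_subjects = count, mean_r = mean_r,
                 sign = ifelse(mean_r >= 0, "+", "-"),
                 retained = count >= min_subjects,
                 min_subjects = as.integer(min_subjects), epoch = epoch),
            class = "connectivity_consensus")
}

#' @export
print.connectivity_consensus <- function(x, ...) {
  cat(sprintf(
    "Connectivity consensus%s: %d regions, %d/%d edges retained (>= %d subjects)\n",
    if (is.na(x$epoch)) "" else paste0(" [", x$epoch, "]"),
    length(x$roi_ids), sum(x$retained), nrow(x$pairs), x$min_subjects))
  invisible(x)
}

#' @export
summary.connectivity_consensus <- function(object, ...) {
  as.data.frame(object)[as.data.frame(object)$retained, , drop = FALSE]
}

#' @export
as.data.frame.connectivity_consensus <- function(x, ...) {
  data.frame(roi_a = x$roi_ids[x$pairs[, 1]],
             roi_b = x$roi_ids[x$pairs[, 2]],
             n_subjects = x$n_subjects, mean_r = x$mean_r,
             sign = x$sign, retained = x$retained,
             epoch = x$epoch, stringsAsFactors = FALSE)
}

#' Start-versus-end difference of two consensus graphs
#'
#' Classifies every edge by whether it is retained only in the start-anchored
#' epoch, only in the end-anchored epoch, in both, or in neither —
#' highlighting connectivity that appears or disappears as the decision
#' concludes.
#'
#' @param consensus_start,consensus_end `connectivity_consensus` objects over
#'   the same region universe.
#' @return An object of class `connectivity_difference`: `roi_ids`, `pairs`,
#'   `category` factor (`both`, `start_only`, `end_only`, `neither`), plus
#'   both parents.
#' @export
connectivity_difference <- function(consensus_start, consensus_end) {
  if (!identical(consensus_start$roi_ids, consensus_end$roi_ids))
    stop2("consensus graphs use different ROI sets")
  a <- consensus_start$retained
  b <- consensus_end$retained
  category <- factor(ifelse(a & b, "both",
                     ifelse(a, "start_only",
                     ifelse(b, "end_only", "neither"))),
                     levels = c("both", "start_only", "end_only", "neither"))
  structure(list(roi_ids = consensus_start$roi_ids,
                 pairs = consensus_start$pairs, category = category,
                 start = consensus_start, end = consensus_end),
            class = "connectivity_difference")
}

#' @export
print.connectivity_difference <- function(x, ...) {
  tab <- table(x$category)
  cat("Connectivity start-vs-end difference:\n")
  cat(sprintf("  both %d | start-only %d | end-only %d | neither %d\n",
              tab["both"], tab["start_only"], tab["end_only"], tab["neither"]))
  invisible(x)
}
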