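#' Pairwise-correlation features per trial
#'
#' For each trial, the Pearson correlations of every unordered pair of the
#' selected regions over that trial's resampled segment, vectorized as the
#' upper triangle in fixed row-major (lexicographic) pair order: 10 regions
#' yield choose(10, 2) = 45 features. Pairs involving a constant segment are
#' set to 0 and flagged.
#'
#' @param norm A `normalized_trials` object.
#' @param roi_subset Character vector of at least two region ids.
#' @return An object of class `feature_table`: `features` (trial x pair
#'   matrix, columns named `a|b`), `labels`, `subject_id`, `flagged`
#'   (logical per trial: any constant-segment pair).
#' @export
trial_features <- function(norm, roi_subset) {
  stopifnot(inherits(norm, "normalized_trials"), length(roi_subset) >= 2)
  rows <- match(roi_subset, norm$roi_ids)
  if (anyNA(rows))
    stop2("unknown ROI ids: ", paste(roi_subset[is.na(rows)], collapse = ", "))
  if (norm$L < 3) stop2("trial segments need at least 3 samples")
  pairs <- pair_index(length(rows))
  cn <- paste(roi_subset[pairs[, 1]], roi_subset[pairs[, 2]], sep = "|")
  feats <- matrix(NA_real_, norm$n_trials, nrow(pairs),
                  dimnames = list(NULL, cn))
  flagged <- logical(norm$n_trials)
  for (m in seq_len(norm$n_trials)) {
    seg <- norm$data[rows, ((m - 1L) * norm$L + 1L):(m * norm$L), drop = FALSE]
    constant <- apply(seg, 1L, function(v) max(v) == min(v))
    r <- suppressWarnings(cor(t(seg)))
    v <- t(r)[t(upper.tri(r))]
    bad <- constant[pairs[, 1]] | constant[pairs[, 2]]
    v[bad] <- 0
    flagged[m] <- any(bad)
    feats[m, ] <- v
  }
  structure(list(features = feats, labels = norm$labels,
                 subject_id = norm$subject_id, flagged = flagged,
                 roi_subset = roi_subset),
            class = "feature_table")
}

#' Pool feature tables across subjects
#'
#' @param tables List of `feature_table` objects with identical feature
#'   columns.
#' @return A pooled `feature_table` with a `subject` vector marking the
#'   origin of every trial row.
#' @export
pool_features <- function(tables) {
  stopifnot(length(tables) >= 1)
  cn <- colnames(tables[[1]]$features)
  for (tb in tables)
    if (!identical(colnames(tb$features), cn)) stop2("feature columns differ")
  structure(list(
    features = do.call(rbind, lapply(tables, `[[`, "features")),
    labels = unlist(lapply(tables, `[[`, "labels"), use.names = FALSE),
    subject = rep(vapply(tables, `[[`, character(1), "subject_id"),
                  vapply(tables, function(tb) length(tb$labels), integer(1))),
    flagged = unlist(lapply(tables, `[[`, "flagged"), use.names = FALSE),
    roi_subset = tables[[1]]$roi_subset,
    subject_id = "pooled"),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "Connectivity feature table [%s]: %d trials x %d pair features (%d yes / %d no)\n",
    x$subject_id, nrow(x$features), ncol(x$features),
    sum(x$labels == "yes"), sum(x$labels == "no")))
  invisible(x)
}

# Stratified fold assignment: classes split separately, deterministic by seed.
stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# Ridge-regularized logistic classifier; returns a predict(newx) closure.
fit_linear_classifier <- function(x, y, lambda = 0.01, alpha = 0) {
  fit <- glmnet::glmnet(x, factor(y, levels = c("no", "yes")),
                        family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = TRUE)
  function(newx) {
    ifelse(as.numeric(stats::predict(fit, newx = newx, type = "response")) > 0.5,
           "yes", "no")
  }
}

#' Cross-validated decoding of the trial response
#'
#' Fits a ridge-regularized logistic regression on the correlation features
#' under stratified k-fold cross-validation (default fivefold) and reports
#' mean and standard deviation of training and test accuracy across folds.
#'
#' @param table A `feature_table`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param lambda Ridge penalty of the linear classifier.
#' @param alpha Elastic-net mixing (0 = ridge, 1 = lasso).
#' @param group_by_subject If `TRUE` and the table is pooled, whole subjects
#'   are assigned to folds (avoids subject-identity leakage across folds).
#' @return An object of class `cv_report`: `train_acc_mean`, `train_acc_sd`,
#'   `test_acc_mean`, `test_acc_sd`, `n_folds`, `seed`, `fold_test_acc`.
#' @export
crossval_classify <- function(table, n_folds = 5L, seed = 1L,
                              lambda = 0.01, alpha = 0,
                              group_by_subject = FALSE) {
  stopifnot(inherits(table, "feature_table"), n_folds >= 2)
  y <- table$labels
  if (length(unique(y)) < 2) stop2("both response classes must be present")
  if (min(table(y)) < n_folds)
    stop2("n_folds exceeds the size of the smaller class")
  if (group_by_subject && !is.null(table$subject)) {
    subj <- unique(table$subject)
    sf <- with_seed(seed, sample(rep_len(seq_len(n_folds), length(subj))))
    fold <- sf[match(table$subject, subj)]
  } else {
    fold <- stratified_folds(y, n_folds, seed)
  }
  train_acc <- test_acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr_i <- fold != f
    clf <- fit_linear_classifier(table$features[tr_i, , drop = FALSE],
                                 y[tr_i], lambda = lambda, alpha = alpha)
    train_acc[f] <- mean(clf(table$features[tr_i, , drop = FALSE]) == y[tr_i])
    test_acc[f] <- mean(clf(table$features[!tr_i, , drop = FALSE]) == y[!tr_i])
  }
  structure(list(train_acc_mean = mean(train_acc), train_acc_sd = sd(train_acc),
                 test_acc_mean = mean(test_acc), test_acc_sd = sd(test_acc),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 fold_test_acc = test_acc),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV: train accuracy %.3f +/- %.3f, test accuracy %.3f +/- %.3f\n",
    x$n_folds, x$train_acc_mean, x$train_acc_sd,
    x$test_acc_mean, x$test_acc_sd))
  invisible(x)
}

#' Permutation null for the decoding accuracy
#'
#' Re-runs the cross-validated classifier on label-permuted copies of the
#' feature table, giving the chance distribution of test accuracy and an
#' empirical p-value (fraction of null accuracies at or above the observed
#' one).
#'
#' @param table A `feature_table`.
#' @param n_permutations Number of label permutations (at least 100).
#' @param seed Integer seed.
#' @param ... Passed to [crossval_classify()].
#' @return List with `observed` (a `cv_report`), `null_acc` (numeric vector),
#'   `p_value`.
#' @export
permutation_chance <- function(table, n_permutations = 100L, seed = 1L, ...) {
  stopifnot(n_permutations >= 100)
  observed <- crossval_classify(table, seed = seed, ...)
  null_acc <- numeric(n_permutations)
  perm_seeds <- with_seed(seed, sample.int(2^30, n_permutations))
  for (b in seq_len(n_permutations)) {
    tb <- table
    tb$labels <- with_seed(perm_seeds[b], sample(table$labels))
    null_acc[b] <- crossval_classify(tb, seed = seed, ...)$test_acc_mean
  }
  list(observed = observed, null_acc = null_acc,
       p_value = mean(null_acc >= observed$test_acc_mean))
}
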