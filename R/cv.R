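#' Cross-validation plan
#'
#' Design of the r-repeated k-fold cross-validation that produces the
#' accuracy samples of the dimension tests: each repetition reshuffles the
#' trials and splits them into k near-equal folds; each fold is held out
#' once while the remaining k-1 folds train an embedding.  This yields
#' `k * r` accuracy samples per candidate dimension.  The default
#' `r = k = 10` follows common practice in repeated-CV model comparison.
#'
#' Folds partition *trials* (triplets), not stimuli: a stimulus will
#' usually appear in both training and test triplets.  The partition for a
#' given repetition is a pure function of `(seed, repetition)` and in
#' particular does not depend on the embedding dimension, so accuracy
#' samples for different dimensions are paired by (repetition, fold) —
#' the precondition of the corrected paired t-test.
#'
#' @param k number of folds (>= 2, default 10).
#' @param r number of repetitions (>= 1, default 10).
#' @param seed integer seed driving fold shuffles and embedding restarts.
#' @return an object of class `cv_plan`.
#' @export
cv_plan <- function(k = 10L, r = 10L, seed = 1L) {
  k <- as.integer(k); r <- as.integer(r)
  if (k < 2L) stop_input("`k` must be >= 2")
  if (r < 1L) stop_input("`r` must be >= 1")
  structure(list(k = k, r = r, seed = as.integer(seed)), class = "cv_plan")
}

#' Fold partition for one repetition
#'
#' Splits trial indices `1..m` into `k` disjoint parts whose sizes differ
#' by at most one.  Deterministic in `(plan$seed, repetition)`; different
#' repetitions give different shuffles.
#'
#' @param m number of triplets.
#' @param plan a [cv_plan()].
#' @param repetition repetition number in `1..plan$r`.
#' @return a list of `k` integer vectors partitioning `seq_len(m)`.
#' @export
make_folds <- function(m, plan, repetition) {
  stopifnot(inherits(plan, "cv_plan"))
  m <- as.integer(m)
  if (m < plan$k) {
    stop_input("cannot split ", m, " triplets into ", plan$k, " folds")
  }
  perm <- with_seed(child_seed(plan$seed, 101L, repetition),
                    sample.int(m, m))
  sizes <- rep(m %/% plan$k, plan$k)
  extra <- m %% plan$k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  unname(split(unname(perm), rep(seq_len(plan$k), times = sizes)))
}

# Core CV loop shared by cv_accuracy() and estimate_dimension(): fits every
# requested dimension on identical (repetition, fold) partitions.  With
# warm_start = TRUE each fold's fit at dimension d+1 gets one extra
# initialization from that fold's d-dimensional solution (padded with a
# zero column), which makes the attained stress non-increasing in d.
# Returns a list of accuracy_samples, one per dimension in `dims`.
cv_scan <- function(data, dims, plan, config, warm_start = TRUE) {
  stopifnot(inherits(plan, "cv_plan"))
  m <- n_triplets(data)
  k <- plan$k; r <- plan$r
  dims <- sort(unique(as.integer(dims)))
  nacc <- r * k
  test_acc <- matrix(NA_real_, nacc, length(dims))
  train_acc <- matrix(NA_real_, nacc, length(dims))
  for (rep_i in seq_len(r)) {
    folds <- make_folds(m, plan, rep_i)
    for (fold_i in seq_len(k)) {
      train_idx <- unlist(folds[-fold_i], use.names = FALSE)
      if (!length(train_idx)) {
        stop_input("empty training split at repetition ", rep_i,
                   ", fold ", fold_i)
      }
      train <- subset_triplets(data, train_idx)
      test <- subset_triplets(data, folds[[fold_i]])
      sample_i <- (rep_i - 1L) * k + fold_i
      prev_scale <- NULL
      for (di in seq_along(dims)) {
        cfg <- config
        cfg$dim <- dims[di]
        cfg$seed <- child_seed(plan$seed, 202L, rep_i, fold_i, dims[di])
        fit <- fit_embedding(train, cfg,
                             warm_start = if (warm_start) prev_scale)
        train_acc[sample_i, di] <- triplet_accuracy(fit$scale, train)
        test_acc[sample_i, di] <- triplet_accuracy(fit$scale, test)
        prev_scale <- fit$scale
      }
    }
  }
  lapply(seq_along(dims), function(di) {
    structure(list(dim = dims[di], test_acc = test_acc[, di],
                   train_acc = train_acc[, di], k = k, r = r,
                   seed = plan$seed),
              class = "accuracy_samples")
  })
}

#' Cross-validated triplet accuracy at one dimension
#'
#' Runs the r-repeated k-fold cross-validation at a single embedding
#' dimension: for each (repetition, fold) an embedding is fitted on the
#' k-1 training folds and its triplet accuracy is recorded on the training
#' folds (`train_acc`) and the held-out fold (`test_acc`).  Training
#' accuracy is kept alongside because the data-quality diagnostics need
#' the train/test gap.
#'
#' @param data a [triplet_dataset()].
#' @param dim embedding dimension.
#' @param plan a [cv_plan()].
#' @param config an [embed_config()] (its `dim` and `seed` are overridden
#'   per fold by the plan).
#' @return an object of class `accuracy_samples`: `dim`, `test_acc` and
#'   `train_acc` (numeric vectors of length `k * r`, ordered by repetition
#'   then fold), `k`, `r`, `seed`.
#' @export
cv_accuracy <- function(data, dim, plan = cv_plan(), config = embed_config()) {
  if (!inherits(data, "triplet_dataset")) data <- triplet_dataset(data)
  cv_scan(data, dims = dim, plan = plan, config = config)[[1L]]
}

#' @export
print.accuracy_samples <- function(x, ...) {
  cat(sprintf(
    "Accuracy samples at dimension %d (%d folds x %d repetitions)\n",
    x$dim, x$k, x$r))
  cat(sprintf("  test  %.4f (sd %.4f)\n", mean(x$test_acc), sd(x$test_acc)))
  cat(sprintf("  train %.4f (sd %.4f)\n", mean(x$train_acc),
              sd(x$train_acc)))
  invisible(x)
}

#' Final scale from the full dataset
#'
#' The cross-validated scales exist only to estimate accuracy; the final
#' scale for visualizing the observer's perception is estimated from all
#' triplets at the chosen dimension.  This is a direct delegation to
#' [fit_embedding()] on the complete dataset.
#'
#' @inheritParams cv_accuracy
#' @return an `embed_result` (see [fit_embedding()]).
#' @export
final_scale <- function(data, dim, config = embed_config()) {
  fit_embedding(data, config, dim = dim)
}
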