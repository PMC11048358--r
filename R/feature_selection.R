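#' Stratified cross-validation fold assignment
#'
#' Assigns each observation to one of `k` folds, shuffling within each
#' class so that class proportions are as equal as possible across folds.
#' Deterministic given `seed`.
#'
#' @param y Binary label vector.
#' @param k Number of folds (`2 <= k <= length(y)`).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  n <- length(y)
  if (k < 2 || k > n) abort(sprintf("Need 2 <= k <= n (= %d); got k = %d.", n, k))
  folds <- integer(n)
  set.seed(seed)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Feature importances of a freshly trained base classifier
#'
#' Pretrains one model of the given family on the full feature matrix and
#' returns its per-feature importances — step one of the two-step feature
#' selection.
#'
#' @inheritParams fit_base
#' @return Named nonnegative numeric vector of length `ncol(X)`.
#' @export
rank_importances <- function(family, X, y, params = list(), seed = 1L) {
  base_importance(fit_base(family, X, y, params = params, seed = seed))
}

#' Importance-threshold feature-selection sweep
#'
#' Step two of the two-step strategy: the distinct importance values from
#' [rank_importances()] are sorted ascending and each is tried as a
#' threshold; the candidate feature set `{importance >= t}` is scored by
#' stratified `n_folds`-fold cross-validated accuracy of a freshly fitted
#' model of the same family, and the best-scoring mask is returned. Ties
#' go to the larger threshold (fewer features). Because the comparison is
#' inclusive, the mask keeping only the argmax feature(s) is always a
#' candidate and the returned mask is never empty.
#'
#' When the number of distinct importances exceeds `max_thresholds`, the
#' candidate thresholds are subsampled at quantiles of the distinct
#' values (one-hot k = 3 matrices have over a thousand features; sweeping
#' every distinct value there buys nothing).
#'
#' @inheritParams fit_base
#' @param n_folds Folds for the selection cross-validation (default 5,
#'   independent of the stacking fold count).
#' @param max_thresholds Cap on the number of thresholds evaluated.
#' @param metric Score used to compare thresholds: CV `"accuracy"`
#'   (default) or `"mcc"`.
#' @param importance Optional precomputed importance vector (skips the
#'   pretraining fit).
#' @return A `pseu_mask` list: `keep` (logical vector), `threshold`,
#'   `score`, `importance`, and `evaluated` (tibble of all thresholds
#'   tried with their feature counts and scores).
#' @export
threshold_sweep <- function(family, X, y, params = list(), n_folds = 5,
                            seed = 1L, max_thresholds = 200,
                            metric = c("accuracy", "mcc"),
                            importance = NULL) {
  metric <- match.arg(metric)
  y <- as.integer(y)
  if (nrow(X) < n_folds) abort("Fewer rows than selection folds.")
  if (is.null(importance)) {
    importance <- rank_importances(family, X, y, params = params, seed = seed)
  }
  stopifnot(length(importance) == ncol(X))

  thr <- sort(unique(importance))
  if (length(thr) > max_thresholds) {
    thr <- unique(quantile(thr, probs = seq(0, 1, length.out = max_thresholds),
                           type = 1, names = FALSE))
  }
  folds <- stratified_folds(y, n_folds, seed = seed)

  score_mask <- function(keep) {
    Xs <- X[, keep, drop = FALSE]
    pred <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      hold <- folds == f
      m <- fit_base(family, Xs[!hold, , drop = FALSE], y[!hold],
                    params = params, seed = seed)
      pred[hold] <- predict_base(m, Xs[hold, , drop = FALSE])
    }
    cc <- confusion_counts(y, pred)
    if (metric == "accuracy") compute_metrics(cc)$acc else compute_metrics(cc)$mcc
  }

  best <- NULL
  rows <- vector("list", length(thr))
  for (i in seq_along(thr)) {
    keep <- importance >= thr[i]
    sc <- score_mask(keep)
    rows[[i]] <- tibble(threshold = thr[i], n_features = sum(keep), score = sc)
    # ascending thresholds: >= implements tie-break toward fewer features
    if (is.null(best) || sc >= best$score) {
      best <- list(keep = keep, threshold = thr[i], score = sc)
    }
  }
  structure(
    list(keep = best$keep, threshold = best$threshold, score = best$score,
         importance = importance, family = family,
         evaluated = dplyr::bind_rows(rows)),
    class = "pseu_mask"
  )
}

#' @export
print.pseu_mask <- function(x, ...) {
  cat(sprintf(
    "<pseu_mask> %s: %d/%d features kept (threshold %.4g, CV score %.4f)\n",
    x$family, sum(x$keep), length(x$keep), x$threshold, x$score
  ))
  invisible(x)
}
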