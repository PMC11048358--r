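#' Confusion counts at a decision threshold
#'
#' @param truth Binary labels (0/1).
#' @param prob Predicted positive-class probabilities (or hard 0/1
#'   labels).
#' @param threshold Decision threshold; predictions `>= threshold` are
#'   called positive (default 0.5).
#' @return One-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, prob, threshold = 0.5) {
  truth <- as.integer(truth)
  pred <- as.integer(prob >= threshold)
  tibble(
    tp = sum(truth == 1 & pred == 1),
    fp = sum(truth == 0 & pred == 1),
    tn = sum(truth == 0 & pred == 0),
    fn = sum(truth == 1 & pred == 0)
  )
}

#' Classification metrics from confusion counts
#'
#' Computes the four standard site-prediction metrics:
#' sensitivity `SN = TP / (TP + FN)`, specificity `SP = TN / (TN + FP)`,
#' accuracy `ACC = (TP + TN) / n`, and Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`.
#' Any metric whose denominator is zero is defined as 0 (a convention
#' that only degenerate inputs — e.g. a single-class evaluation set —
#' can trigger).
#'
#' @param counts A data frame or named vector/list with entries `tp`,
#'   `fp`, `tn`, `fn` (see [confusion_counts()]).
#' @return One-row tibble: `acc`, `sn`, `sp`, `mcc`, plus the four counts
#'   and `n`.
#' @examples
#' compute_metrics(list(tp = 6, fn = 4, tn = 7, fp = 3))
#' @export
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  if (any(c(tp, fp, tn, fn) < 0)) abort("Confusion counts must be nonnegative.")
  n <- tp + fp + tn + fn
  if (n < 1) abort("At least one evaluated observation is required.")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  tibble(
    acc = safe_div(tp + tn, n),
    sn = safe_div(tp, tp + fn),
    sp = safe_div(tn, tn + fp),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / sqrt(mcc_den),
    tp = tp, fp = fp, tn = tn, fn = fn, n = n
  )
}

#' Pearson correlation between RNA profile columns
#'
#' Diversity diagnostic for the stacked ensemble: correlated profile
#' columns indicate redundant (encoding, classifier) pairs. Constant
#' columns have no defined correlation and are reported as 0 (diagonal
#' stays 1).
#'
#' @param profile A profile matrix (see [oof_profile()]) or any numeric
#'   matrix with at least two rows.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
profile_correlation <- function(profile) {
  m <- unclass(profile)
  if (nrow(m) < 2) abort("Need at least two rows to correlate.")
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(cor(m))
  r[is.na(r)] <- 0
  const <- sds == 0
  r[const, ] <- 0
  r[, const] <- 0
  diag(r) <- 1
  r
}

#' Nested cross-validation of the full predictor
#'
#' The honest evaluation protocol: the data are split into `n_folds`
#' outer stratified folds; for each outer fold the *entire* pipeline
#' (feature selection, stacking, PSO weight search, meta-classifier) is
#' refit on the training part and the held-out part is predicted via the
#' averaged fold-model route. Metrics are pooled over all held-out
#' predictions (per-fold metrics are also returned). Each fold yields
#' both the unweighted stacking prediction (`mode = "stack"`, all
#' profile weights 1) and the PSO-weighted prediction (`mode = "pso"`)
#' from the same fold models, so the comparison costs one extra
#' meta-classifier fit per fold.
#'
#' @param x Labeled windows table.
#' @param config A [pseu_config()] list.
#' @param n_folds Outer fold count (default 10).
#' @param seed Seed for the outer split (stage seeds come from `config`).
#' @param modes Which predictor variants to evaluate: `"stack"`,
#'   `"pso"`, or both (default).
#' @return A `pseu_cv` list: `pooled` (tibble, one metric row per mode),
#'   `per_fold` (tibble of per-fold metrics), `predictions` (tibble of
#'   held-out probabilities), `n_folds`, `seed`.
#' @export
cross_validate <- function(x, config = pseu_config(), n_folds = 10,
                           seed = 1L, modes = c("stack", "pso")) {
  modes <- match.arg(modes, several.ok = TRUE)
  x <- rna_windows(as_tibble(x), center_u = "off")
  y <- require_labeled(x, "cross_validate")
  folds <- stratified_folds(y, n_folds, seed = seed)
  run_pso <- "pso" %in% modes

  preds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    hold <- folds == f
    train <- rna_windows(as_tibble(x)[!hold, ], center_u = "off")
    test <- rna_windows(as_tibble(x)[hold, ], center_u = "off")
    model <- fit_pseu(train, config = config, run_pso = run_pso)
    p_test <- test_profile(model$fold_models, test)
    out <- tibble(
      fold = f, id = test$id, label = y[hold]
    )
    if (run_pso) {
      out$pso <- predict_meta(model$meta, sweep(p_test, 2, model$weights$w, "*"))
    }
    if ("stack" %in% modes) {
      out$stack <- predict_meta(model$meta_unweighted, p_test)
    }
    preds[[f]] <- out
  }
  preds <- dplyr::bind_rows(preds)

  metric_rows <- function(df, mode) {
    compute_metrics(confusion_counts(df$label, df[[mode]])) |>
      dplyr::mutate(mode = mode, .before = 1)
  }
  pooled <- dplyr::bind_rows(lapply(intersect(c("stack", "pso"), modes),
                                    function(m) metric_rows(preds, m)))
  per_fold <- dplyr::bind_rows(lapply(
    intersect(c("stack", "pso"), modes),
    function(m) {
      preds |>
        dplyr::group_by(.data$fold) |>
        dplyr::group_modify(~ metric_rows(.x, m)) |>
        dplyr::ungroup()
    }
  ))
  structure(
    list(pooled = pooled, per_fold = per_fold, predictions = preds,
         n_folds = n_folds, seed = seed),
    class = "pseu_cv"
  )
}

#' @export
print.pseu_cv <- function(x, ...) {
  cat(sprintf("<pseu_cv> %d-fold nested cross-validation (pooled metrics)\n",
              x$n_folds))
  df <- as.data.frame(x$pooled[, c("mode", "acc", "mcc", "sn", "sp")])
  names(df) <- c("mode", "ACC", "MCC", "SN", "SP")
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
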