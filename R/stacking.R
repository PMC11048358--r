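#' Column layout of the RNA profile
#'
#' One profile column per (encoding, family) pair, encoding-major: all
#' five families for `onehot1`, then `onehot2`, ... ending with the five
#' families for `kmer3`. With the standard six encodings and five
#' families this gives the 30-dimensional RNA profile.
#'
#' @param encodings Encoding tibble as from [encoding_specs()].
#' @param families Character vector of family codes in registry order.
#' @return Tibble with columns `column` (name, e.g. `"onehot1_RF"`),
#'   `scheme`, `k`, `encoding`, `family`.
#' @export
profile_columns <- function(encodings = encoding_specs(),
                            families = base_registry()$family) {
  out <- tidyr::crossing(
    encodings |> dplyr::mutate(.enc_order = dplyr::row_number()),
    family = factor(families, levels = families)
  ) |>
    dplyr::arrange(.data$.enc_order, .data$family) |>
    dplyr::mutate(
      family = as.character(.data$family),
      column = paste0(.data$encoding, "_", .data$family)
    ) |>
    dplyr::select("column", "scheme", "k", "encoding", "family")
  out
}

# encode every configured representation once; returns named list of matrices
encode_all <- function(x, encodings) {
  out <- lapply(seq_len(nrow(encodings)), function(i) {
    encode_windows(x, encodings$scheme[i], encodings$k[i])
  })
  names(out) <- encodings$encoding
  out
}

#' Two-step feature selection for every (encoding, family) pair
#'
#' Runs the importance-threshold sweep ([threshold_sweep()]) once per
#' profile column on the full training data, before stacking. Masks are
#' fixed from here on; the stacking fold models all use them.
#'
#' @param x Labeled windows table.
#' @param config A [pseu_config()] list.
#' @param features Optional precomputed result of `encode_all()`
#'   (internal reuse).
#' @return Named list of `pseu_mask` objects, one per profile column.
#' @export
select_features <- function(x, config = pseu_config(), features = NULL) {
  y <- require_labeled(x, "select_features")
  cols <- profile_columns(config$encodings, config$families)
  if (is.null(features)) features <- encode_all(x, config$encodings)
  reg <- base_registry(config$base_params)
  masks <- vector("list", nrow(cols))
  names(masks) <- cols$column
  for (i in seq_len(nrow(cols))) {
    fam <- cols$family[i]
    masks[[i]] <- threshold_sweep(
      fam, features[[cols$encoding[i]]], y,
      params = reg$params[[match(fam, reg$family)]],
      n_folds = config$fs$n_folds,
      seed = config$seed + i,
      max_thresholds = config$fs$max_thresholds,
      metric = config$fs$metric
    )
  }
  masks
}

#' Out-of-fold RNA profile
#'
#' The stacking step: training rows are split into `config$stacking_folds`
#' stratified folds; for every profile column (encoding, family) and
#' every fold, a base classifier is fitted on the other folds (using the
#' column's feature mask) and predicts the held-out fold. Each row's
#' profile entry is therefore produced by a model that never saw that
#' row — the out-of-fold honesty that makes the profile a legitimate
#' training input for the meta-classifier.
#'
#' @param x Labeled windows table.
#' @param masks Per-column masks from [select_features()] (or `NULL` to
#'   keep all features).
#' @param config A [pseu_config()] list.
#' @param features Optional precomputed `encode_all()` result.
#' @return A list with `profile` (n x D matrix, entries in `[0,1]`,
#'   `provenance` attribute `"out_of_fold"`), and `fold_models` (a
#'   `pseu_fold_models` object holding the per-column, per-fold fitted
#'   models, the fold assignment, masks and column metadata).
#' @export
oof_profile <- function(x, masks = NULL, config = pseu_config(),
                        features = NULL) {
  y <- require_labeled(x, "oof_profile")
  cols <- profile_columns(config$encodings, config$families)
  if (is.null(features)) features <- encode_all(x, config$encodings)
  k <- config$stacking_folds
  folds <- stratified_folds(y, k, seed = config$seed)
  for (f in seq_len(k)) {
    if (length(unique(y[folds != f])) < 2) {
      abort("A stacking training fold lost one class entirely.")
    }
  }
  reg <- base_registry(config$base_params)
  n <- nrow(x)
  profile <- matrix(NA_real_, n, nrow(cols),
                    dimnames = list(x$id, cols$column))
  models <- vector("list", nrow(cols))
  names(models) <- cols$column
  for (i in seq_len(nrow(cols))) {
    Xe <- features[[cols$encoding[i]]]
    if (!is.null(masks)) Xe <- Xe[, masks[[cols$column[i]]]$keep, drop = FALSE]
    fam <- cols$family[i]
    par <- reg$params[[match(fam, reg$family)]]
    fold_fits <- vector("list", k)
    for (f in seq_len(k)) {
      hold <- folds == f
      m <- fit_base(fam, Xe[!hold, , drop = FALSE], y[!hold],
                    params = par, seed = config$seed + i)
      profile[hold, i] <- predict_base(m, Xe[hold, , drop = FALSE])
      fold_fits[[f]] <- m
    }
    models[[i]] <- fold_fits
  }
  fold_models <- structure(
    list(columns = cols, folds = folds, masks = masks, models = models,
         lambda = window_length(x), encodings = config$encodings,
         n_folds = k, seed = config$seed),
    class = "pseu_fold_models"
  )
  attr(profile, "provenance") <- "out_of_fold"
  attr(profile, "columns") <- cols
  list(profile = profile, fold_models = fold_models)
}

#' Profile for held-out sequences via fold-model averaging
#'
#' Scores new sequences with every retained fold model and averages the
#' `k` probabilities per column — the deployment-time counterpart of the
#' out-of-fold profile.
#'
#' @param fold_models A `pseu_fold_models` object from [oof_profile()].
#' @param newdata Windows table with the training window length.
#' @return n x D profile matrix with `provenance` attribute
#'   `"averaged_test"`.
#' @export
test_profile <- function(fold_models, newdata) {
  lam <- window_length(newdata)
  if (is.na(lam) || lam != fold_models$lambda) {
    abort(sprintf(
      "Window length mismatch: model expects %d nt, input has %s nt.",
      fold_models$lambda, lam
    ))
  }
  features <- encode_all(newdata, fold_models$encodings)
  cols <- fold_models$columns
  profile <- matrix(NA_real_, nrow(newdata), nrow(cols),
                    dimnames = list(newdata$id, cols$column))
  for (i in seq_len(nrow(cols))) {
    Xe <- features[[cols$encoding[i]]]
    if (!is.null(fold_models$masks)) {
      Xe <- Xe[, fold_models$masks[[cols$column[i]]]$keep, drop = FALSE]
    }
    preds <- vapply(
      fold_models$models[[i]],
      function(m) predict_base(m, Xe),
      numeric(nrow(newdata))
    )
    profile[, i] <- if (nrow(newdata) == 1) mean(preds) else rowMeans(preds)
  }
  attr(profile, "provenance") <- "averaged_test"
  attr(profile, "columns") <- cols
  profile
}

#' Per-column MCC of an RNA profile
#'
#' Thresholds each profile column at `threshold` and computes its
#' Matthews correlation with the labels — the per-dimension diagnostic
#' showing which (encoding, classifier) pairs carry signal.
#'
#' @param profile Profile matrix.
#' @param labels Binary labels for its rows.
#' @param threshold Decision threshold (default 0.5).
#' @return Tibble with `column` and `mcc` (plus encoding/family metadata
#'   when the profile carries it).
#' @export
profile_column_mcc <- function(profile, labels, threshold = 0.5) {
  mcc <- vapply(
    seq_len(ncol(profile)),
    function(j) {
      compute_metrics(confusion_counts(labels, profile[, j], threshold))$mcc
    },
    numeric(1)
  )
  out <- tibble(column = colnames(profile), mcc = mcc)
  cols <- attr(profile, "columns")
  if (!is.null(cols)) out <- dplyr::left_join(cols, out, by = "column")
  out
}
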