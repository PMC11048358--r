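#' Logistic meta-classifier on a (weighted) RNA profile
#'
#' Ridge-penalized logistic regression (penalty `lambda`, default `1/n`,
#' i.e. unit-strength L2) fitted without standardization — column
#' weights must pass through to the decision function, otherwise the
#' swarm's weights would be invisible to the meta-classifier. The same
#' settings are used inside the PSO fitness and for the final model, so
#' the searched weights are optimal for the surface they were scored on.
#'
#' @param profile Profile matrix (already weighted, if weighting is
#'   wanted).
#' @param labels Binary labels (0/1).
#' @param lambda Ridge penalty; `NULL` means `1/nrow(profile)`.
#' @return A `pseu_meta` object.
#' @export
fit_meta <- function(profile, labels, lambda = NULL) {
  labels <- as.integer(labels)
  if (is.null(lambda)) lambda <- 1 / nrow(profile)
  X <- unclass(profile)
  pad <- ncol(X) < 2
  if (pad) X <- cbind(X, .pad = 0)  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(X, labels, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-10)
  structure(list(fit = fit, lambda = lambda, pad = pad,
                 columns = colnames(profile)),
            class = "pseu_meta")
}

#' Positive-class probabilities from the meta-classifier
#'
#' @param meta A `pseu_meta` object.
#' @param profile Profile matrix (weighted the same way as at training).
#' @return Numeric vector of probabilities.
#' @export
predict_meta <- function(meta, profile) {
  X <- unclass(profile)
  if (meta$pad) X <- cbind(X, .pad = 0)
  as.numeric(predict(meta$fit, newx = X, s = meta$lambda, type = "response"))
}

#' Coefficients of the meta-classifier
#'
#' @param meta A `pseu_meta` object.
#' @return Named numeric vector: `(Intercept)` then one coefficient per
#'   profile column.
#' @export
meta_coefficients <- function(meta) {
  b <- as.numeric(glmnet::coef.glmnet(meta$fit, s = meta$lambda))
  names(b) <- rownames(glmnet::coef.glmnet(meta$fit, s = meta$lambda))
  if (meta$pad) b <- b[names(b) != ".pad"]
  b
}

# pooled CV accuracy of the meta-classifier on a weighted profile;
# the PSO fitness function
meta_cv_accuracy <- function(profile, labels, w, folds, lambda = NULL) {
  Pw <- sweep(unclass(profile), 2, w, "*")
  pred <- numeric(length(labels))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    m <- fit_meta(Pw[!hold, , drop = FALSE], labels[!hold], lambda = lambda)
    pred[hold] <- predict_meta(m, Pw[hold, , drop = FALSE])
  }
  mean((pred >= 0.5) == (labels == 1))
}

#' Train the full pseudouridine-site predictor
#'
#' Runs the complete pipeline on a labeled windows table:
#' 1. encode the sequences with every configured representation;
#' 2. per (encoding, family) pair, pick features by the
#'    importance-threshold sweep ([select_features()]);
#' 3. build the out-of-fold RNA profile ([oof_profile()]);
#' 4. search per-column profile weights by particle swarm
#'    ([optimize_weights()]) — skipped when `run_pso = FALSE`, which
#'    leaves all weights at 1 (plain stacking);
#' 5. fit the logistic meta-classifier on the weighted profile.
#'
#' Everything is reproducible from `config` (stage seeds derive from
#' `config$seed`), and the returned bundle carries all fitted artifacts
#' needed to score new sequences.
#'
#' @param x Labeled windows table (see [rna_windows()]); a file path is
#'   also accepted and read with [read_rna_windows()].
#' @param config A [pseu_config()] list.
#' @param run_pso Search profile weights (default) or keep them at 1.
#' @param center_u Center-base validation mode for the training windows.
#' @return A `pseu_model` object; see [predict.pseu_model()],
#'   [tidy.pseu_model()], [glance.pseu_model()].
#' @examples
#' \donttest{
#' w <- generate_windows(preset_spec("human_like", n_pos = 30, n_neg = 30))
#' cfg <- fast_config(pso = pso_config(n_particles = 5, n_iterations = 3,
#'                                     fitness_folds = 3),
#'                    stacking_folds = 3)
#' m <- fit_pseu(w, cfg)
#' predict(m, w)
#' }
#' @export
fit_pseu <- function(x, config = pseu_config(), run_pso = TRUE,
                     center_u = "require") {
  if (is.character(x) && length(x) == 1) x <- read_rna_windows(x)
  x <- rna_windows(as_tibble(x), center_u = center_u)
  y <- require_labeled(x, "fit_pseu")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("fit_pseu [", name, "]: ", conditionMessage(e)))
    })
  }
  features <- stage("encode", encode_all(x, config$encodings))
  masks <- stage("feature_selection",
                 select_features(x, config, features = features))
  prof <- stage("stacking",
                oof_profile(x, masks = masks, config = config,
                            features = features))
  D <- ncol(prof$profile)
  if (run_pso) {
    weights <- stage("pso", optimize_weights(
      prof$profile, y, config = config$pso,
      seed = config$seed, meta_lambda = config$meta_lambda
    ))
  } else {
    weights <- structure(
      list(w = rep(1, D), fitness = NA_real_, history = numeric(0),
           initial_fitness = NA_real_,
           columns = attr(prof$profile, "columns"),
           config = config$pso, seed = config$seed),
      class = "pseu_weights"
    )
  }
  meta <- stage("meta", fit_meta(
    sweep(prof$profile, 2, weights$w, "*"), y, lambda = config$meta_lambda
  ))
  meta_unweighted <- stage("meta", fit_meta(
    prof$profile, y, lambda = config$meta_lambda
  ))
  structure(
    list(lambda = window_length(x), config = config, masks = masks,
         fold_models = prof$fold_models, profile = prof$profile,
         labels = y, weights = weights, meta = meta,
         meta_unweighted = meta_unweighted, run_pso = run_pso),
    class = "pseu_model"
  )
}

#' Score new sequences with a fitted predictor
#'
#' New windows are profiled by fold-model averaging ([test_profile()]),
#' the profile is multiplied by the trained per-column weights, and the
#' logistic meta-classifier produces the positive-class probability; the
#' site call thresholds it at `threshold`.
#'
#' @param object A `pseu_model` from [fit_pseu()].
#' @param newdata Windows table or FASTA path; window length must equal
#'   the model's.
#' @param threshold Decision threshold (default 0.5).
#' @param ... Unused.
#' @return Tibble with `id`, `probability`, `label` (1 = predicted PseU
#'   site), in input order.
#' @export
predict.pseu_model <- function(object, newdata, threshold = 0.5, ...) {
  if (is.character(newdata) && length(newdata) == 1) {
    newdata <- read_rna_windows(newdata, center_u = "warn")
  }
  newdata <- rna_windows(as_tibble(newdata), center_u = "warn")
  p <- test_profile(object$fold_models, newdata)
  prob <- predict_meta(object$meta, sweep(p, 2, object$weights$w, "*"))
  tibble(
    id = newdata$id,
    probability = prob,
    label = as.integer(prob >= threshold)
  )
}

#' Save / load a fitted predictor bundle
#'
#' The bundle is a single serialized file holding every artifact needed
#' to score new sequences: fold models, feature masks, profile weights,
#' meta-classifier and the full configuration snapshot.
#'
#' @param model A `pseu_model`.
#' @param path File path for the bundle.
#' @return `save_pseu()` returns `path` invisibly; `load_pseu()` the
#'   restored `pseu_model`.
#' @export
save_pseu <- function(model, path) {
  stopifnot(inherits(model, "pseu_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pseu
#' @export
load_pseu <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pseu_model")) abort("Not a pseu_model bundle.")
  model
}

#' @export
print.pseu_model <- function(x, ...) {
  cat(sprintf(
    "<pseu_model> lambda = %d nt, %d profile columns, %d training windows\n",
    x$lambda, ncol(x$profile), nrow(x$profile)
  ))
  if (x$run_pso) {
    cat(sprintf("  PSO weights: fitness %.4f after %d iterations\n",
                x$weights$fitness, length(x$weights$history)))
  } else {
    cat("  unweighted stacking (all profile weights 1)\n")
  }
  invisible(x)
}

#' Tidy summary of a fitted predictor
#'
#' One row per RNA-profile column: its encoding and family, the number
#' of features its mask kept, the feature-selection CV score, the PSO
#' weight, the meta-classifier coefficient, and the column's individual
#' out-of-fold MCC.
#'
#' @param x A `pseu_model`.
#' @param ... Unused.
#' @return A tibble with one row per profile column.
#' @export
tidy.pseu_model <- function(x, ...) {
  cols <- x$fold_models$columns
  b <- meta_coefficients(x$meta)
  cols |>
    dplyr::mutate(
      n_features_kept = vapply(x$masks[cols$column],
                               function(m) sum(m$keep), integer(1)),
      fs_score = vapply(x$masks[cols$column],
                        function(m) m$score, numeric(1)),
      weight = x$weights$w,
      coefficient = unname(b[cols$column]),
      oof_mcc = profile_column_mcc(x$profile, x$labels)$mcc
    )
}

#' One-row summary of a fitted predictor
#'
#' @param x A `pseu_model`.
#' @param ... Unused.
#' @return A one-row tibble: training size, window length, profile
#'   width, stacking folds, PSO fitness at initialization and
#'   convergence, seed.
#' @export
glance.pseu_model <- function(x, ...) {
  tibble(
    n_train = nrow(x$profile),
    window_length = x$lambda,
    n_profile_columns = ncol(x$profile),
    stacking_folds = x$config$stacking_folds,
    pso_fitness = x$weights$fitness,
    pso_initial_fitness = x$weights$initial_fitness,
    seed = x$config$seed
  )
}

#' @export
tidy.pseu_cv <- function(x, ...) x$pooled

#' @export
glance.pseu_cv <- function(x, ...) {
  tibble(n_folds = x$n_folds, seed = x$seed,
         n = nrow(x$predictions))
}
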