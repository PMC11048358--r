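#' Registry of the five tree-ensemble base-classifier families
#'
#' The stacking layer uses five tree-ensemble families, always in this
#' order: adaptive boosting (`ADA`), gradient boosting decision trees
#' (`GBDT`), extreme gradient boosting (`XGB`), random forest (`RF`) and
#' extra trees (`ET`). Paired with the six encodings of
#' [encoding_specs()] they yield the 30 columns of the RNA profile.
#'
#' Hyperparameters are each family's widely used defaults (100 estimators
#' and standard depths/learning rates); nothing here is tuned. Every
#' default is overridable through the `params` list-column, and the
#' values in force are frozen into fitted model bundles.
#'
#' @param overrides Named list of per-family parameter overrides, e.g.
#'   `list(RF = list(num.trees = 200))`.
#' @return A tibble with columns `family` and `params` (list-column).
#' @export
base_registry <- function(overrides = list()) {
  defaults <- list(
    ADA  = list(n_rounds = 50, max_cuts = 32),
    GBDT = list(nrounds = 100, eta = 0.1, max_depth = 3, reg_lambda = 0,
                min_child_weight = 1, subsample = 1),
    XGB  = list(nrounds = 100, eta = 0.3, max_depth = 6, reg_lambda = 1,
                min_child_weight = 1, subsample = 1),
    RF   = list(num.trees = 100, mtry = NULL),
    ET   = list(num.trees = 100, mtry = NULL, num.random.splits = 1)
  )
  for (fam in names(overrides)) {
    if (!fam %in% names(defaults)) abort(paste0("Unknown family: ", fam))
    defaults[[fam]] <- modifyList(defaults[[fam]], overrides[[fam]])
  }
  tibble(family = names(defaults), params = unname(defaults))
}

#' Fit one base classifier
#'
#' Trains a single tree-ensemble model of the given family on a feature
#' matrix, with a fixed seed so that refitting reproduces the model
#' exactly. `GBDT` and `XGB` are both gradient-boosted trees backed by
#' xgboost with different configurations (`GBDT` uses the classical
#' unregularized shallow-tree setup, `XGB` the regularized defaults);
#' `RF` and `ET` are ranger forests (`ET` with the extra-trees split
#' rule on a full, unresampled sample); `ADA` is boosted decision stumps
#' (see [ada_fit()]).
#'
#' @param family One of `"ADA"`, `"GBDT"`, `"XGB"`, `"RF"`, `"ET"`.
#' @param X Numeric feature matrix (rows = sequences).
#' @param y Binary labels (0/1), both classes present.
#' @param params Hyperparameter list; missing entries fall back to
#'   [base_registry()] defaults.
#' @param seed Integer seed for the family's RNG.
#' @return A `pseu_base` object supporting [predict_base()] and
#'   [base_importance()].
#' @export
fit_base <- function(family, X, y, params = list(), seed = 1L) {
  family <- match.arg(family, c("ADA", "GBDT", "XGB", "RF", "ET"))
  y <- as.integer(y)
  if (nrow(X) != length(y)) abort("X rows must match length(y).")
  if (length(unique(y)) < 2) {
    abort(paste0(family, ": training labels contain a single class."))
  }
  reg <- base_registry()
  par <- modifyList(reg$params[[match(family, reg$family)]], params)

  fit <- switch(family,
    ADA = {
      set.seed(seed)  # ADA itself is deterministic; seed kept for uniformity
      ada_fit(X, y, n_rounds = par$n_rounds, max_cuts = par$max_cuts)
    },
    GBDT = ,
    XGB = {
      set.seed(seed)
      dtr <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(
          objective = "binary:logistic", nthread = 1, seed = seed,
          eta = par$eta, max_depth = par$max_depth,
          lambda = par$reg_lambda, min_child_weight = par$min_child_weight,
          subsample = par$subsample
        ),
        data = dtr, nrounds = par$nrounds, verbose = 0
      )
    },
    RF = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
      importance = "impurity", num.trees = par$num.trees, mtry = par$mtry,
      seed = seed, num.threads = 1
    ),
    ET = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
      importance = "impurity", num.trees = par$num.trees, mtry = par$mtry,
      splitrule = "extratrees", num.random.splits = par$num.random.splits,
      replace = FALSE, sample.fraction = 1,
      seed = seed, num.threads = 1
    )
  )
  structure(
    list(family = family, params = par, seed = seed, fit = fit,
         n_features = ncol(X), feature_names = colnames(X)),
    class = "pseu_base"
  )
}

#' Positive-class probabilities from a fitted base classifier
#'
#' @param model A `pseu_base` object from [fit_base()].
#' @param X Feature matrix with the same columns as at training.
#' @return Numeric vector in `[0, 1]`, one value per row of `X`.
#' @export
predict_base <- function(model, X) {
  if (ncol(X) != model$n_features) {
    abort(sprintf(
      "Feature count mismatch: model trained on %d features, got %d.",
      model$n_features, ncol(X)
    ))
  }
  p <- switch(model$family,
    ADA = predict(model$fit, X),
    GBDT = ,
    XGB = predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    RF = ,
    ET = predict(model$fit, data = X, num.threads = 1)$predictions[, "1"]
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' Per-feature importances of a fitted base classifier
#'
#' Gain-type importances for the boosted families, impurity importances
#' for the forests, alpha mass per feature for AdaBoost. Always a full
#' nonnegative vector over the training features (features a model never
#' used score 0), as required by the feature-selection threshold sweep.
#'
#' @param model A `pseu_base` object.
#' @return Named nonnegative numeric vector, one entry per training
#'   feature.
#' @export
base_importance <- function(model) {
  imp <- switch(model$family,
    ADA = ada_importance(model$fit),
    GBDT = ,
    XGB = {
      tab <- xgboost::xgb.importance(model = model$fit)
      v <- setNames(numeric(model$n_features), model$feature_names)
      if (nrow(tab) > 0) v[tab$Feature] <- tab$Gain
      v
    },
    RF = ,
    ET = model$fit$variable.importance
  )
  imp <- pmax(as.numeric(imp), 0)
  names(imp) <- model$feature_names
  imp
}
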