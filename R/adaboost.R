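#' Adaptive boosting of decision stumps
#'
#' Discrete AdaBoost (two-class SAMME) over depth-one decision stumps,
#' the classical weak learner. Each round fits the stump minimizing the
#' weighted 0/1 error, reweights the observations by
#' `exp(-alpha * y * h(x))`, and accumulates the stage score
#' `F(x) = sum_t alpha_t h_t(x)`; the positive-class probability is the
#' logistic transform `1 / (1 + exp(-2 F(x)))`.
#'
#' Stump search is exact over a per-feature threshold grid: for binary
#' features (one-hot encodings) the single cut at 0.5, for discrete
#' numeric features (k-mer frequencies) the midpoints between consecutive
#' observed values, capped at `max_cuts` quantile cuts per feature.
#' Feature importance is the total `alpha` mass of the rounds that chose
#' each feature.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (0/1).
#' @param n_rounds Number of boosting rounds (stumps).
#' @param max_cuts Maximum candidate thresholds per feature.
#' @return An object of class `ada_stumps` with `predict()` support.
#' @keywords internal
ada_fit <- function(X, y, n_rounds = 50, max_cuts = 32) {
  n <- nrow(X)
  p <- ncol(X)
  ypm <- ifelse(y == 1, 1, -1)

  # candidate thresholds per feature
  cand_feat <- integer(0)
  cand_thr <- numeric(0)
  for (j in seq_len(p)) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) next
    if (length(u) > max_cuts + 1) {
      u <- unique(quantile(X[, j], probs = seq(0, 1, length.out = max_cuts + 1),
                           type = 1, names = FALSE))
    }
    thr <- (u[-1] + u[-length(u)]) / 2
    cand_feat <- c(cand_feat, rep(j, length(thr)))
    cand_thr <- c(cand_thr, thr)
  }
  model <- list(
    feature = integer(0), threshold = numeric(0), polarity = integer(0),
    alpha = numeric(0), p = p, feature_names = colnames(X)
  )
  class(model) <- "ada_stumps"
  if (length(cand_feat) == 0) return(model)  # all features constant

  B <- (X[, cand_feat, drop = FALSE] >
          matrix(cand_thr, n, length(cand_thr), byrow = TRUE)) * 1
  w <- rep(1 / n, n)
  for (t in seq_len(n_rounds)) {
    s_pos <- as.vector(crossprod(B, w * (ypm == 1)))
    s_neg <- as.vector(crossprod(B, w * (ypm == -1)))
    w_pos <- sum(w[ypm == 1])
    # polarity +1: predict +1 where x > thr; error = missed positives + hit negatives
    err_plus <- (w_pos - s_pos) + s_neg
    err <- pmin(err_plus, 1 - err_plus)
    best <- which.min(err)
    e <- err[best]
    if (e >= 0.5 - 1e-12) break
    pol <- if (err_plus[best] <= 1 - err_plus[best]) 1L else -1L
    h <- pol * (2 * B[, best] - 1)
    e <- min(max(e, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - e) / e)
    model$feature <- c(model$feature, cand_feat[best])
    model$threshold <- c(model$threshold, cand_thr[best])
    model$polarity <- c(model$polarity, pol)
    model$alpha <- c(model$alpha, alpha)
    w <- w * exp(-alpha * ypm * h)
    w <- w / sum(w)
    if (e <= 1e-9) break  # perfect stump; further rounds add nothing
  }
  model
}

#' @export
predict.ada_stumps <- function(object, newdata, type = c("prob", "score"), ...) {
  type <- match.arg(type)
  n <- nrow(newdata)
  f <- numeric(n)
  for (t in seq_along(object$alpha)) {
    h <- object$polarity[t] *
      (2 * (newdata[, object$feature[t]] > object$threshold[t]) - 1)
    f <- f + object$alpha[t] * h
  }
  if (type == "score") f else 1 / (1 + exp(-2 * f))
}

ada_importance <- function(model) {
  imp <- numeric(model$p)
  if (length(model$alpha)) {
    agg <- tapply(model$alpha, model$feature, sum)
    imp[as.integer(names(agg))] <- agg
  }
  names(imp) <- model$feature_names
  imp
}
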