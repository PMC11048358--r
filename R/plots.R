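#' Fitness curve of a weight search
#'
#' Global-best CV accuracy against PSO iteration — the standard
#' convergence diagnostic for the weight search (the curve is
#' non-decreasing by construction).
#'
#' @param object A `pseu_weights` from [optimize_weights()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pseu_weights <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$history),
               gbest_accuracy = object$history)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$gbest_accuracy)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "PSO iteration",
      y = "Global-best CV accuracy",
      title = "Fitness curve of the profile-weight search"
    ) +
    ggplot2::theme_minimal()
}

#' Per-dimension MCC of an RNA profile
#'
#' Bar chart of each (encoding, family) column's individual Matthews
#' correlation with the labels, grouped by encoding.
#'
#' @param profile Profile matrix (with column metadata) or a tibble from
#'   [profile_column_mcc()].
#' @param labels Labels, required when `profile` is a matrix.
#' @return A ggplot object.
#' @export
plot_profile_mcc <- function(profile, labels = NULL) {
  df <- if (is.matrix(profile)) {
    stopifnot(!is.null(labels))
    profile_column_mcc(profile, labels)
  } else {
    profile
  }
  stopifnot(all(c("column", "mcc") %in% names(df)))
  if (!"encoding" %in% names(df)) df$encoding <- ""
  if (!"family" %in% names(df)) df$family <- df$column
  ggplot2::ggplot(df, ggplot2::aes(.data$family, .data$mcc,
                                   fill = .data$family)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~encoding, nrow = 1) +
    ggplot2::labs(x = NULL, y = "MCC",
                  title = "Per-dimension MCC of the RNA profile") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Correlation heatmap of an RNA profile
#'
#' Pearson correlations between profile columns; blocks of similar
#' color expose redundant (encoding, classifier) pairs, while
#' low-correlation blocks (typically between one-hot and k-mer columns)
#' show where the ensemble's diversity comes from.
#'
#' @param profile Profile matrix, or a precomputed correlation matrix
#'   from [profile_correlation()].
#' @return A ggplot object.
#' @export
plot_profile_correlation <- function(profile) {
  r <- if (isSymmetric(unname(unclass(profile)))) unclass(profile)
       else profile_correlation(profile)
  df <- as_tibble(as.table(r), .name_repair = ~ c("a", "b", "r"))
  lev <- colnames(r)
  df$a <- factor(df$a, levels = lev)
  df$b <- factor(df$b, levels = rev(lev))
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Pearson r") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "RNA profile column correlations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
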