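#' Tidy a cross-validation result
#'
#' One row per fold with its held-out accuracy.
#'
#' @param x A `taste_rf_cv` object.
#' @param ... Unused.
#' @return A tibble with columns `fold` and `accuracy`.
#' @method tidy taste_rf_cv
#' @export
tidy.taste_rf_cv <- function(x, ...) {
  tibble(fold = seq_along(x$fold_accuracy),
         accuracy = as.numeric(x$fold_accuracy))
}

#' Glance at a cross-validation result
#'
#' @param x A `taste_rf_cv` object.
#' @param ... Unused.
#' @return A one-row tibble with `mean_accuracy`, the fold-accuracy
#'   spread, and the problem size.
#' @method glance taste_rf_cv
#' @export
glance.taste_rf_cv <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy,
         sd_accuracy = stats::sd(x$fold_accuracy),
         k = x$settings$k,
         n_samples = x$settings$n_samples,
         n_features = x$settings$n_features,
         num_trees = x$settings$num_trees)
}

#' Tidy a sweep
#'
#' Per-size best and mean accuracies (identical to [sweep_summary()]).
#'
#' @param x A `taste_sweep`.
#' @param ... Unused.
#' @method tidy taste_sweep
#' @export
tidy.taste_sweep <- function(x, ...) {
  sweep_summary(x)
}

#' Confusion-matrix heatmap
#'
#' Row-normalized confusion matrix of the pooled cross-validation
#' predictions; cell labels below `min_display` are suppressed, mirroring
#' the convention of hiding proportions under 0.01.
#'
#' @param object A `taste_rf_cv` object.
#' @param min_display Hide printed values below this proportion
#'   (default 0.01).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot taste_rf_cv
#' @export
autoplot.taste_rf_cv <- function(object, min_display = 0.01, ...) {
  cm <- object$confusion
  df <- as_tibble(as.table(cm), .name_repair = "minimal")
  names(df) <- c("truth", "pred", "prop")
  df$truth <- factor(df$truth, levels = rev(taste_levels()))
  df$pred <- factor(df$pred, levels = taste_levels())
  df$label <- ifelse(df$prop < min_display, "", sprintf("%.2f", df$prop))
  ggplot2::ggplot(df, ggplot2::aes(x = pred, y = truth, fill = prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = label), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Predicted taste", y = "True taste",
                  fill = "Proportion",
                  title = sprintf("Confusion matrix (mean accuracy %.3f)",
                                  object$mean_accuracy)) +
    ggplot2::theme_minimal()
}

#' Sweep curve
#'
#' Accuracy against subset size: a single mean curve for NF sweeps, best
#' and mean curves for NC and NS sweeps.
#'
#' @param object A `taste_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot taste_sweep
#' @export
autoplot.taste_sweep <- function(object, ...) {
  axis <- attr(object, "axis")
  s <- sweep_summary(object)
  size_col <- names(s)[1]
  df <- tidyr::pivot_longer(s, c("best", "mean_acc"),
                            names_to = "stat", values_to = "accuracy")
  df$stat <- ifelse(df$stat == "best", "best", "mean")
  if (axis == "NF") df <- filter(df, .data$stat == "mean")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[size_col]], y = accuracy,
                                   colour = .data$stat)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = switch(axis, NF = "Number of feature types (NF)",
                             NC = "Number of channels (NC)",
                             NS = "Number of subjects (NS)"),
                  y = "5-fold CV accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Muscle-activity grayscale tiles
#'
#' Renders the 6 x 3 activity table as grayscale tiles. With
#' `invert = TRUE` stronger activity is drawn darker.
#'
#' @param object A `taste_activity` tibble.
#' @param invert Draw stronger activity darker (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot taste_activity
#' @export
autoplot.taste_activity <- function(object, invert = FALSE, ...) {
  df <- activity_grayscale(object, invert = invert)
  df$taste <- factor(df$taste, levels = rev(taste_levels()))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(channel), y = taste,
                                   fill = gray)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = gray),
                       colour = "red", size = 3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::labs(x = "Channel", y = "Taste", fill = "Grayscale") +
    ggplot2::theme_minimal()
}
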