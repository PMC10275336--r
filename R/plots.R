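#' Plot a precision-recall sweep
#'
#' @param object A [pr_curve()] result.
#' @param ... Unused.
#' @return A ggplot: precision against recall, annotated with the AUC.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("Precision-recall sweep (AUC = %.3f)", object$auc),
      subtitle = sprintf("Optimal threshold %.2f (max Dice %.3f)",
                         object$optimal_threshold, max(object$curve$dice))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fascicle error breakdown
#'
#' Bar chart of the percentage of fascicles affected by each error type
#' (missed, split, added, merged), broken down by size class.
#'
#' @param object A `fascicle_error_report` from [error_breakdown()] or
#'   [evaluate_stack()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fascicle_error_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$size_class != "total") |>
    tidyr::pivot_longer(
      cols = dplyr::ends_with("_pct"),
      names_to = "error", values_to = "pct"
    ) |>
    dplyr::mutate(
      error = sub("_pct$", "", .data$error),
      size_class = factor(.data$size_class, levels = size_class_levels)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$error, .data$pct,
                                   fill = .data$size_class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "Error type", y = "% of fascicles in size class",
                  fill = "Size class",
                  title = "Fascicle error taxonomy by size class") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation: Dice distribution and F1 against threshold
#'
#' @param object A `stack_evaluation`.
#' @param which `"dice"` for the per-slice Dice histogram or `"f1"` for
#'   the detection-F1-versus-threshold curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stack_evaluation <- function(object, which = c("dice", "f1"), ...) {
  which <- match.arg(which)
  if (which == "dice") {
    ggplot2::ggplot(object$per_slice, ggplot2::aes(.data$dice)) +
      ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
      ggplot2::labs(x = "Per-slice Dice coefficient", y = "Slices",
                    title = sprintf("Mean Dice %.3f",
                                    object$summary$mean_dice)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$f1_curve, ggplot2::aes(.data$t, .data$f1_mean)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::geom_point() +
      ggplot2::labs(x = "IoU matching threshold t",
                    y = "Fascicle F1 (per-slice mean)",
                    title = "Detection F1 against matching threshold") +
      ggplot2::theme_minimal()
  }
}

#' Plot a training history
#'
#' @param object A trained `unet`.
#' @param ... Unused.
#' @return A ggplot of training loss and validation Dice per epoch.
#' @export
autoplot.unet <- function(object, ...) {
  h <- tidy(object) |>
    tidyr::pivot_longer(c("train_loss", "val_dice"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = NULL, colour = NULL,
                  title = "Training loss and validation Dice") +
    ggplot2::theme_minimal()
}
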