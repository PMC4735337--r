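# broom-style tidiers and plotting for learning_curve objects.

#' Tidy per-round learning-curve results
#'
#' One row per round x condition, list-columns flattened to plain columns
#' (hyperparameters serialized as `key=value` strings) so the result writes
#' cleanly to TSV.
#'
#' @param x A `learning_curve` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy learning_curve
#' @export
tidy.learning_curve <- function(x, ...) {
  out <- x$results
  if ("hyperparameters" %in% names(out)) {
    out$hyperparameters <- vapply(out$hyperparameters, function(hp) {
      paste(sprintf("%s=%s", names(hp), vapply(hp, format, character(1))),
        collapse = ";"
      )
    }, character(1))
  }
  dplyr::select(out, -dplyr::any_of(c("per_class", "confusion")))
}

#' Per-condition learning-curve summary
#'
#' @param x A `learning_curve` object.
#' @param ... Unused.
#' @return The per-condition mean/SD/SEM tibble (see [summarize_curve()]).
#' @method glance learning_curve
#' @export
glance.learning_curve <- function(x, ...) {
  x$summary
}

#' Per-class accuracy across rounds
#'
#' Unnests the per-class (class-wise recall) records, giving the data behind
#' subtype-stratified learning curves.
#'
#' @param curve A `learning_curve` object.
#' @return Tibble with one row per round x condition x class.
#' @export
per_class_accuracy <- function(curve) {
  stopifnot(inherits(curve, "learning_curve"))
  curve$results |>
    dplyr::select(dplyr::any_of(
      c("round", "dataset", "depth", "classifier", "size", "per_class")
    )) |>
    tidyr::unnest("per_class")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf(
    "Learning curve: %d rounds x %d conditions\n",
    max(x$results$round), nrow(x$summary)
  ))
  print(x$summary)
  invisible(x)
}

#' Plot a learning curve
#'
#' Mean accuracy against training-set size with error bars of one standard
#' error of the cross-validation mean, coloured by classifier and faceted by
#' dataset (and read depth, when varied).
#'
#' @param object A `learning_curve` object.
#' @param metric `"accuracy"` or `"balanced_accuracy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot learning_curve
#' @export
autoplot.learning_curve <- function(object, metric = c("accuracy", "balanced_accuracy"), ...) {
  metric <- match.arg(metric)
  s <- object$summary
  ycol <- paste0("mean_", metric)
  semcol <- paste0("sem_", metric)
  p <- ggplot2::ggplot(s, ggplot2::aes(
    x = .data$size, y = .data[[ycol]],
    colour = .data$classifier, group = .data$classifier
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data[[ycol]] - .data[[semcol]],
        ymax = .data[[ycol]] + .data[[semcol]]
      ),
      width = 8
    ) +
    ggplot2::labs(
      x = "Training sample size",
      y = gsub("_", " ", sprintf("Mean %s (± SEM)", metric))
    ) +
    ggplot2::theme_bw()
  facets <- intersect(c("dataset", "depth"), names(s))
  facets <- facets[vapply(
    facets, function(f) length(unique(s[[f]])) > 1L, logical(1)
  )]
  if (length(facets) > 0L) {
    p <- p + ggplot2::facet_wrap(facets)
  }
  p
}

#' Heat-tile plot of a row-normalized confusion matrix
#'
#' @param rates Row-normalized confusion matrix (true classes in rows), e.g.
#'   from [pooled_confusion()].
#' @return A ggplot object.
#' @export
plot_confusion <- function(rates) {
  df <- tibble::as_tibble(rates, rownames = "true") |>
    tidyr::pivot_longer(-"true", names_to = "predicted", values_to = "rate") |>
    dplyr::mutate(
      true = factor(.data$true, levels = rev(rownames(rates))),
      predicted = factor(.data$predicted, levels = colnames(rates))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true, fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$rate)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = "Predicted label", y = "True label", fill = "Rate") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = 1 - .data$specificity, y = .data$sensitivity
  )) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_bw()
}
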