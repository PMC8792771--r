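#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report into its per-class table
#'
#' @param x An `edss_eval` from [evaluate_edss()].
#' @param ... Unused.
#' @return A tibble with one row per scored class: confusion counts and
#'   per-class precision, recall and F1.
#' @export
tidy.edss_eval <- function(x, ...) {
  as_tibble(x$per_class)
}

#' One-row summary of an evaluation report
#'
#' @param x An `edss_eval`.
#' @param ... Unused.
#' @return A one-row tibble with the headline metrics.
#' @export
glance.edss_eval <- function(x, ...) {
  tibble(
    n_notes = x$n_notes,
    accuracy = x$accuracy,
    converted_accuracy = x$converted_accuracy,
    unknown_prediction_rate = x$unknown_prediction_rate,
    macro_precision = x$macro_precision,
    macro_recall = x$macro_recall,
    macro_f1 = x$macro_f1,
    tolerance = x$tolerance
  )
}

#' Tidy a trained classifier into its training history
#'
#' @param x A trained `text_cnn`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `train_loss`, `val_loss`, `improved`.
#' @export
tidy.text_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(
      epoch = integer(), train_loss = numeric(),
      val_loss = numeric(), improved = logical()
    ))
  }
  x$history
}

#' One-row summary of a trained classifier
#'
#' @param x A `text_cnn`.
#' @param ... Unused.
#' @return A one-row tibble: class count, parameter count, stopping and
#'   best epochs, best validation loss.
#' @export
glance.text_cnn <- function(x, ...) {
  n_params <- sum(vapply(x$W, length, numeric(1))) +
    sum(vapply(x$b, length, numeric(1))) +
    length(x$Wd) + length(x$bd)
  tibble(
    n_classes = length(x$class_values),
    n_parameters = n_params,
    trained = x$trained,
    stopped_epoch = x$stopped_epoch %||% NA_integer_,
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_loss = x$best_val_loss %||% NA_real_
  )
}

#' Plot the training history of a classifier
#'
#' @param object A trained `text_cnn`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch, with the retained
#'   (best-validation) epoch marked.
#' @export
autoplot.text_cnn <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(
    h[, c("epoch", "train_loss", "val_loss")],
    cols = c("train_loss", "val_loss"),
    names_to = "set", values_to = "loss"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$epoch, y = .data$loss,
    colour = .data$set
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = object$best_epoch, linetype = "dashed",
      colour = "grey40"
    ) +
    ggplot2::labs(
      x = "epoch", y = "cross-entropy loss", colour = NULL,
      title = "Training history (dashed: retained epoch)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-class confusion profile of an evaluation report
#'
#' @param object An `edss_eval`.
#' @param ... Unused.
#' @return A ggplot showing per-class precision, recall and F1 across the
#'   scored classes.
#' @export
autoplot.edss_eval <- function(object, ...) {
  tab <- tidy(object)
  long <- tidyr::pivot_longer(
    tab[, c("class", "precision", "recall", "f1")],
    cols = c("precision", "recall", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$class), y = .data$value,
    fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "class", y = NULL, fill = NULL,
      title = "Per-class precision / recall / F1"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the label distribution of a corpus
#'
#' @param corpus A notes tibble with an `edss` column.
#' @return A ggplot bar chart of the EDSS label distribution (unknown
#'   labels shown as their own bar).
#' @export
plot_class_distribution <- function(corpus) {
  d <- tibble(label = ifelse(is.na(corpus$edss), "unknown",
    sprintf("%.1f", corpus$edss)
  ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "EDSS label", y = "notes",
      title = "Corpus label distribution"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
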