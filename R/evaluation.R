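#' Five-class confusion matrix
#'
#' Rows are reference (true) labels, columns predicted labels, both in the
#' canonical order N, S, V, F, Q. `counts[i, j]` is the number of beats with
#' true class i predicted as class j.
#'
#' @param true_labels,predicted_labels Equal-length character vectors with
#'   values in `aami_classes`.
#' @return A 5x5 integer matrix of class `confusion_matrix5`.
#' @export
#' @examples
#' confusion_matrix5(c("N", "N", "S"), c("N", "S", "S"))
confusion_matrix5 <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label vectors must have equal length")
  }
  bad <- !(true_labels %in% aami_classes) |
    !(predicted_labels %in% aami_classes)
  if (any(bad)) stop("labels must be in {N, S, V, F, Q}")
  cm <- table(
    factor(true_labels, levels = aami_classes),
    factor(predicted_labels, levels = aami_classes)
  )
  out <- matrix(as.integer(cm), 5, 5,
                dimnames = list(reference = aami_classes,
                                predicted = aami_classes))
  class(out) <- c("confusion_matrix5", class(out))
  out
}

#' Per-class TP / FP / TN / FN decomposition
#'
#' For class `c`: TP is the diagonal cell, FN the rest of the row (class-`c`
#' beats predicted as something else), FP the rest of the column (other beats
#' predicted as `c`), and TN everything else. The four counts always sum to
#' the matrix total.
#'
#' @param cm A `confusion_matrix5`.
#' @param class Optional single class; by default all five are returned.
#' @return A tibble with columns `class`, `TP`, `FP`, `TN`, `FN`.
#' @export
per_class_counts <- function(cm, class = NULL) {
  stopifnot(inherits(cm, "confusion_matrix5"))
  classes <- class %||% aami_classes
  if (!all(classes %in% aami_classes)) stop("invalid class")
  total <- sum(cm)
  rows <- lapply(classes, function(cl) {
    i <- match(cl, aami_classes)
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tibble::tibble(class = cl, TP = tp, FP = fp,
                   TN = total - tp - fn - fp, FN = fn)
  })
  dplyr::bind_rows(rows)
}

rate_pct <- function(num, den) ifelse(den == 0, NA_real_, 100 * num / den)

#' Per-class classification metrics
#'
#' Sensitivity `Se = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, positive
#' predictive value `+p = TP/(TP+FP)` and per-class accuracy
#' `Acc = (TP+TN)/total`, all as percentages. A zero denominator yields `NA`
#' (the rate is undefined, e.g. Se of a class absent from the data) rather
#' than an error; `NA` rates are excluded from any averaging done downstream.
#'
#' @param cm A `confusion_matrix5`.
#' @return A tibble with one row per class (`class`, `TP`, `FP`, `TN`, `FN`,
#'   `Se`, `Sp`, `PPV`, `Acc`) carrying the overall accuracy
#'   (`100 * trace / total`) in the `overall_accuracy` attribute.
#' @export
class_metrics <- function(cm) {
  counts <- per_class_counts(cm)
  out <- dplyr::mutate(
    counts,
    Se = rate_pct(.data$TP, .data$TP + .data$FN),
    Sp = rate_pct(.data$TN, .data$TN + .data$FP),
    PPV = rate_pct(.data$TP, .data$TP + .data$FP),
    Acc = rate_pct(.data$TP + .data$TN,
                   .data$TP + .data$TN + .data$FP + .data$FN)
  )
  attr(out, "overall_accuracy") <- overall_accuracy(cm)
  out
}

#' Overall accuracy of a confusion matrix
#'
#' `100 * trace / total`, i.e. the percentage of beats assigned their true
#' class.
#'
#' @param cm A `confusion_matrix5`.
#' @return Scalar percentage.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix5"))
  100 * sum(diag(cm)) / sum(cm)
}

#' @export
tidy.confusion_matrix5 <- function(x, ...) {
  out <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(out) <- c("reference", "predicted", "n")
  tibble::as_tibble(out)
}

#' Evaluate a fitted classifier on held-out segments
#'
#' Runs per-beat prediction and assembles the confusion matrix and metric
#' table.
#'
#' @param fit A `bilstm_fit`.
#' @param segments Held-out rows of an [assemble_segments()] tibble.
#' @return A list of class `beat_evaluation`: `confusion` (the matrix),
#'   `metrics` (per-class tibble), `overall_accuracy`, `predictions`
#'   (per-beat tibble).
#' @export
evaluate_fit <- function(fit, segments) {
  preds <- predict(fit, segments)
  cm <- confusion_matrix5(preds$truth, preds$prediction)
  metrics <- class_metrics(cm)
  structure(
    list(confusion = cm, metrics = metrics,
         overall_accuracy = overall_accuracy(cm), predictions = preds),
    class = "beat_evaluation"
  )
}

#' @export
print.beat_evaluation <- function(x, ...) {
  cat(sprintf("<beat_evaluation: %d beats, overall accuracy %.2f%%>\n",
              sum(x$confusion), x$overall_accuracy))
  m <- as.data.frame(x$metrics[, c("class", "Se", "Sp", "PPV", "Acc")])
  m[-1] <- round(m[-1], 2)
  print(m)
  invisible(x)
}

#' Write a per-class metric report to CSV
#'
#' Percentages are rounded to 2 decimals at this reporting layer only;
#' in-memory values keep full precision.
#'
#' @param evaluation A `beat_evaluation` (or a metrics tibble).
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(evaluation, path) {
  m <- if (inherits(evaluation, "beat_evaluation")) evaluation$metrics
       else evaluation
  m <- dplyr::mutate(m, dplyr::across(dplyr::all_of(c("Se", "Sp", "PPV", "Acc")),
                                      ~ round(.x, 2)))
  write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Confusion-matrix heatmap
#'
#' @param object A `confusion_matrix5`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix5 <- function(object, ...) {
  df <- tidy.confusion_matrix5(object)
  df$reference <- factor(df$reference, levels = rev(aami_classes))
  df$predicted <- factor(df$predicted, levels = aami_classes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$reference,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted label", y = "Reference label", fill = "beats")
}
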