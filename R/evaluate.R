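#' Confusion-matrix evaluation
#'
#' Builds the classes x classes confusion matrix (rows = actual,
#' columns = predicted) and the derived metrics: overall accuracy
#' (correct / total), and per-class one-vs-rest sensitivity
#' `TP / (TP + FN)` and precision `TP / (TP + FP)`.
#'
#' @param labels_true,labels_pred character vectors of equal length.
#' @param class_order class names fixing row/column order; defaults to
#'   the sorted union of the true labels. Predicted labels outside it
#'   are an error.
#' @return An object of class `confusion_report`: list with `matrix`,
#'   `accuracy`, `sensitivity`, `precision` (the latter two named by
#'   class; precision is `NaN` for a never-predicted class).
#' @export
evaluate_classification <- function(labels_true, labels_pred,
                                    class_order = NULL) {
  labels_true <- as.character(labels_true)
  labels_pred <- as.character(labels_pred)
  stopifnot(length(labels_true) == length(labels_pred))
  if (is.null(class_order)) class_order <- sort(unique(labels_true))
  unseen <- setdiff(unique(c(labels_true, labels_pred)), class_order)
  if (length(unseen)) {
    stop("label(s) not in class_order: ", paste(unseen, collapse = ", "))
  }
  tf <- factor(labels_true, levels = class_order)
  pf <- factor(labels_pred, levels = class_order)
  cm <- table(actual = tf, predicted = pf)
  cm <- matrix(as.integer(cm), nrow = length(class_order),
               dimnames = list(actual = class_order,
                               predicted = class_order))
  tp <- diag(cm)
  sens <- tp / rowSums(cm)
  prec <- tp / colSums(cm)
  structure(
    list(matrix = cm,
         accuracy = sum(tp) / sum(cm),
         sensitivity = sens,
         precision = prec),
    class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("<confusion_report> accuracy %.4f\n", x$accuracy))
  print(x$matrix)
  cat("sensitivity:", paste(sprintf("%s=%.3f", names(x$sensitivity),
                                    x$sensitivity), collapse = ", "), "\n")
  cat("precision:  ", paste(sprintf("%s=%.3f", names(x$precision),
                                    x$precision), collapse = ", "), "\n")
  invisible(x)
}

#' Before/after transfer discrimination comparison
#'
#' Applies master-trained classifiers to a slave test set, unchanged
#' and after each supplied calibration transfer, and tabulates the
#' accuracies. This is the cross-instrument validation table: without
#' transfer the accuracies quantify the damage done by instrument
#' differences; the transfer rows show how much each method recovers.
#'
#' @param slave_test matrix or [spectrum_set()] of slave test spectra
#'   on the common grid.
#' @param labels_true true class labels of the test samples.
#' @param transfer_models named list of fitted transfer models; an
#'   entry named `"none"` (or a `NULL` element) is the no-transfer
#'   baseline and is added automatically if absent.
#' @param classifiers named list of classifiers with `predict` methods
#'   returning `$labels`, e.g. `list(plsda = ..., svm = ...)`.
#' @return data.frame with columns `transfer`, `classifier`,
#'   `accuracy`; failed transfer rows are dropped with a message.
#' @export
before_after_comparison <- function(slave_test, labels_true,
                                    transfer_models, classifiers) {
  X <- as_spec_matrix(slave_test)
  if (!"none" %in% names(transfer_models)) {
    transfer_models <- c(list(none = NULL), transfer_models)
  }
  rows <- list()
  for (tn in names(transfer_models)) {
    Xt <- tryCatch(transfer_spectra(transfer_models[[tn]], X),
                   error = function(e) {
                     message("transfer '", tn, "' skipped: ",
                             conditionMessage(e))
                     NULL
                   })
    if (is.null(Xt)) next
    for (cn in names(classifiers)) {
      pred <- predict(classifiers[[cn]], Xt)$labels
      rows[[length(rows) + 1L]] <- data.frame(
        transfer = tn, classifier = cn,
        accuracy = mean(pred == as.character(labels_true)))
    }
  }
  do.call(rbind, rows)
}
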