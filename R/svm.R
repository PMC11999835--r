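#' RBF-SVM species classifier with grid-search CV
#'
#' Radial-basis-function support vector machine (one-vs-one multiclass,
#' solver from \pkg{e1071}) with the kernel parameters chosen by
#' seeded stratified cross-validated accuracy over a `(C, gamma)`
#' grid. Ties break to the smaller `C`, then the smaller `gamma`.
#' Spectra are used unscaled so the decision function depends only on
#' the supplied reflectance values.
#'
#' @param X numeric matrix or [spectrum_set()] of training spectra.
#' @param labels class labels; at least 2 classes.
#' @param C_grid candidate penalty values.
#' @param gamma_grid candidate RBF widths.
#' @param n_folds CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return An object of class `svm_model` wrapping the fitted
#'   \pkg{e1071} model with `class_order`, chosen `C`/`gamma` and the
#'   CV accuracy table.
#' @export
fit_svm <- function(X, labels = NULL, C_grid = c(1, 10, 100),
                    gamma_grid = c(0.01, 0.1, 1), n_folds = 5L, seed = 1L) {
  if (inherits(X, "spectrum_set")) {
    if (is.null(labels)) labels <- X$labels
    X <- X$spectra
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  class_order <- sort(unique(labels))
  if (length(class_order) < 2L) stop("need at least 2 classes")
  stopifnot(length(C_grid) > 0, length(gamma_grid) > 0)
  yfac <- factor(labels, levels = class_order)
  fold <- stratified_folds(labels, n_folds, seed)
  n_folds <- max(fold)
  tab <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  tab$accuracy <- vapply(seq_len(nrow(tab)), function(r) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- e1071::svm(X[tr, , drop = FALSE], yfac[tr], kernel = "radial",
                        cost = tab$C[r], gamma = tab$gamma[r], scale = FALSE)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      correct <- correct + sum(pred == yfac[!tr])
    }
    correct / length(yfac)
  }, 0)
  ord <- order(-tab$accuracy, tab$C, tab$gamma)
  best <- ord[1L]
  final <- e1071::svm(X, yfac, kernel = "radial", cost = tab$C[best],
                      gamma = tab$gamma[best], scale = FALSE)
  structure(
    list(svm = final, class_order = class_order,
         C = tab$C[best], gamma = tab$gamma[best],
         cv_table = tab, n_bands = ncol(X), seed = as.integer(seed)),
    class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat("<svm_model> RBF, C =", x$C, ", gamma =", x$gamma, ", classes:",
      paste(x$class_order, collapse = ", "), "\n")
  invisible(x)
}

#' @param object an `svm_model`.
#' @param newdata matrix or [spectrum_set()] on the training grid.
#' @param ... unused.
#' @return `predict`: list with `labels` (character).
#' @rdname fit_svm
#' @export
predict.svm_model <- function(object, newdata, ...) {
  X <- as_spec_matrix(newdata)
  if (ncol(X) != object$n_bands) {
    stop("input has ", ncol(X), " bands but the model was trained on ",
         object$n_bands)
  }
  list(labels = as.character(predict(object$svm, X)))
}
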