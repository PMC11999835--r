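#' PLS-DA species classifier
#'
#' Partial least squares discriminant analysis: class labels are
#' one-hot encoded (class order fixed alphabetically and recorded in
#' the model) and regressed on the spectra with SIMPLS. The component
#' count is chosen by seeded stratified 10-fold cross-validation: a
#' held-out sample counts as misclassified when its predicted score
#' for the true class deviates from the one-hot target by more than
#' 0.5; the count minimizing CV misclassification wins, ties going to
#' fewer components. Prediction assigns the argmax class score.
#'
#' @param X numeric matrix or [spectrum_set()] of training spectra.
#' @param labels class labels (character/factor), at least 2 classes.
#' @param max_components largest component count tried, at most
#'   `min(m - 1, n_bands)`.
#' @param n_folds CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param n_components optional fixed component count; skips CV.
#' @return An object of class `plsda_model` with the SIMPLS fit,
#'   `class_order`, `n_components` and the CV error table.
#' @export
fit_plsda <- function(X, labels = NULL, max_components = 10L,
                      n_folds = 10L, seed = 1L, n_components = NULL) {
  if (inherits(X, "spectrum_set")) {
    if (is.null(labels)) labels <- X$labels
    X <- X$spectra
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  m <- nrow(X)
  class_order <- sort(unique(labels))
  if (length(class_order) < 2L) stop("need at least 2 classes")
  Y <- outer(labels, class_order, "==") * 1
  cap <- min(m - 1L, ncol(X))
  cv_errors <- NULL
  if (is.null(n_components)) {
    max_components <- min(max_components, cap)
    fold <- stratified_folds(labels, n_folds, seed)
    n_folds <- max(fold)
    errs <- matrix(0L, n_folds, max_components)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      if (length(unique(labels[tr])) < length(class_order)) {
        stop("a class is absent from a training fold; reduce n_folds")
      }
      for (a in seq_len(max_components)) {
        fit <- simpls_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                          ncomp = a)
        sc <- simpls_predict(fit, X[!tr, , drop = FALSE])
        true_sc <- sc[cbind(seq_len(nrow(sc)),
                            match(labels[!tr], class_order))]
        errs[f, a] <- sum(abs(true_sc - 1) > 0.5)
      }
    }
    cv_errors <- colSums(errs)
    n_components <- which.min(cv_errors)   # first minimum: fewest components
  } else {
    if (n_components > cap) stop("n_components exceeds min(m - 1, n_bands)")
  }
  fit <- simpls_fit(X, Y, ncomp = n_components)
  structure(
    list(fit = fit, class_order = class_order,
         n_components = as.integer(n_components),
         cv_errors = cv_errors, n_bands = ncol(X), seed = as.integer(seed)),
    class = "plsda_model")
}

stratified_folds <- function(labels, n_folds, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("<plsda_model>", x$n_components, "components, classes:",
      paste(x$class_order, collapse = ", "), "\n")
  invisible(x)
}

#' @param object a `plsda_model`.
#' @param newdata matrix or [spectrum_set()] on the training grid.
#' @param ... unused.
#' @return `predict`: list with `labels` (character) and `scores`
#'   (matrix, one column per class in `class_order`).
#' @rdname fit_plsda
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  X <- as_spec_matrix(newdata)
  if (ncol(X) != object$n_bands) {
    stop("input has ", ncol(X), " bands but the model was trained on ",
         object$n_bands)
  }
  sc <- simpls_predict(object$fit, X)
  colnames(sc) <- object$class_order
  list(labels = object$class_order[max.col(sc, ties.method = "first")],
       scores = sc)
}
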