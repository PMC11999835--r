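#' Apply a fitted calibration transfer to slave spectra
#'
#' Common contract for all transfer estimators: map spectra measured
#' on the slave instrument into the master's spectral space, on the
#' common grid the model was fitted with.
#'
#' @param model a fitted `pds_model`, `sst_model` or `atld_model`;
#'   `NULL` is accepted and acts as the identity (no transfer).
#' @param X matrix or [spectrum_set()] of slave spectra on the model's
#'   fitted grid.
#' @param ... passed to methods.
#' @return Numeric matrix of transformed spectra, same row count as
#'   the input.
#' @export
transfer_spectra <- function(model, X, ...) {
  if (is.null(model)) return(as_spec_matrix(X))
  UseMethod("transfer_spectra")
}

#' Five-fold component selection for SST / ATLD
#'
#' Seeded 5-fold cross-validation over the standard set: for each
#' candidate component (SST) or factor (ATLD) count, the transfer is
#' fitted on the training folds and the held-out slave standards are
#' transformed; the score is the RMSE against the held-out master
#' standards. The argmin is returned, ties breaking to the smallest
#' value. Folds with fewer than 2 samples trigger a reduction of the
#' fold count with a warning.
#'
#' @param method `"sst"` or `"atld"`.
#' @param Xm_std,Xs_std row-aligned standards on a common grid (at
#'   least 5).
#' @param grid integer candidate counts.
#' @param n_folds folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return A `transfer_fit_report` (see [optimize_pds()]); its
#'   `cv_table` has columns `value` and `rmse`.
#' @export
cv_select_components <- function(method = c("sst", "atld"), Xm_std, Xs_std,
                                 grid, n_folds = 5L, seed = 1L) {
  method <- match.arg(method)
  Xm <- as_spec_matrix(Xm_std); Xs <- as_spec_matrix(Xs_std)
  m <- nrow(Xm)
  stopifnot(m >= 5, length(grid) > 0)
  if (m / n_folds < 2) {
    n_folds <- max(2L, floor(m / 2))
    warning("too few standards for requested folds; using ", n_folds, " folds")
  }
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(n_folds), m))
  grid <- sort(unique(as.integer(grid)))
  rmse <- vapply(grid, function(g) {
    err2 <- 0; cnt <- 0
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- tryCatch({
        if (method == "sst") {
          fit_sst(Xm[tr, , drop = FALSE], Xs[tr, , drop = FALSE],
                  n_components = g)
        } else {
          fit_atld(Xm[tr, , drop = FALSE], Xs[tr, , drop = FALSE],
                   n_factors = g)
        }
      }, error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pred <- transfer_spectra(fit, Xs[!tr, , drop = FALSE])
      err2 <- err2 + sum((pred - Xm[!tr, , drop = FALSE])^2)
      cnt <- cnt + length(pred)
    }
    sqrt(err2 / cnt)
  }, 0)
  tab <- data.frame(value = grid, rmse = rmse)
  if (all(is.na(tab$rmse))) stop("no candidate value could be fitted")
  cand <- which(tab$rmse <= min(tab$rmse, na.rm = TRUE) + 1e-12)
  best <- cand[order(tab$value[cand])][1L]
  structure(
    list(method = method,
         chosen = list(value = tab$value[best], rmse = tab$rmse[best]),
         cv_table = tab, seed = as.integer(seed)),
    class = "transfer_fit_report")
}
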