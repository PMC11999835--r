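#' Piecewise direct standardization (PDS)
#'
#' For every target (master) wavelength `i`, regresses the master
#' standards' column `i` on the slave standards' columns in the index
#' window `[i - w, i + w]` (clipped at the spectrum ends) using SIMPLS
#' with mean-centring, storing a coefficient vector and intercept per
#' wavelength. The moving window absorbs wavelength-shift and
#' bandwidth differences that a purely per-band map cannot.
#'
#' Master and slave standards must be row-aligned and on the same
#' (common) grid, so the window index refers to the same wavelength on
#' both instruments.
#'
#' @param Xm_std,Xs_std row-aligned standard sets (matrices or
#'   [spectrum_set()]s) on a common grid.
#' @param w window halfwidth; the window width is `2w + 1`.
#' @param n_components PLS components per local regression; per window
#'   the effective count is capped at
#'   `min(n_components, window size, standards - 1)`.
#' @return An object of class `pds_model`.
#' @export
fit_pds <- function(Xm_std, Xs_std, w = 12L, n_components = 6L) {
  Xm <- as_spec_matrix(Xm_std); Xs <- as_spec_matrix(Xs_std)
  stopifnot(nrow(Xm) == nrow(Xs), ncol(Xm) == ncol(Xs), w >= 0)
  m <- nrow(Xm); p <- ncol(Xm)
  if (n_components > m - 1L) {
    stop("n_components must be at most standards - 1")
  }
  coeffs <- vector("list", p)
  intercepts <- numeric(p)
  windows <- vector("list", p)
  for (i in seq_len(p)) {
    win <- max(1L, i - w):min(p, i + w)
    fit <- simpls_fit(Xs[, win, drop = FALSE], Xm[, i],
                      ncomp = min(n_components, length(win), m - 1L))
    coeffs[[i]] <- as.numeric(fit$coef)
    intercepts[i] <- fit$intercept
    windows[[i]] <- win
  }
  structure(
    list(method = "pds", w = as.integer(w),
         n_components = as.integer(n_components),
         coeffs = coeffs, intercepts = intercepts, windows = windows,
         n_bands = p),
    class = c("pds_model", "transfer_model"))
}

#' @export
print.pds_model <- function(x, ...) {
  cat("<pds_model> window halfwidth", x$w, "(width", 2 * x$w + 1,
      "), components", x$n_components, ",", x$n_bands, "bands\n")
  invisible(x)
}

#' @export
transfer_spectra.pds_model <- function(model, X, ...) {
  X <- as_spec_matrix(X)
  if (ncol(X) != model$n_bands) {
    stop("input has ", ncol(X), " bands but the PDS model was fitted on ",
         model$n_bands)
  }
  out <- matrix(0, nrow(X), model$n_bands)
  for (i in seq_len(model$n_bands)) {
    out[, i] <- X[, model$windows[[i]], drop = FALSE] %*% model$coeffs[[i]] +
      model$intercepts[i]
  }
  out
}

#' Leave-one-out window/component search for PDS
#'
#' Leave-one-out cross-validation over the standard set: for each
#' `(w, n_components)` cell, each standard in turn is held out, PDS is
#' fitted on the rest, and the held-out slave spectrum is transformed;
#' the cell score is the RMSE against the held-out master spectrum.
#' The chosen cell is the argmin; ties break to the smallest window,
#' then the fewest components.
#'
#' @param Xm_std,Xs_std row-aligned standards on a common grid.
#' @param w_grid candidate window halfwidths (default includes 12,
#'   i.e. window width 25).
#' @param component_grid candidate component counts (default includes 6).
#' @return An object of class `transfer_fit_report`: list with
#'   `method`, `chosen` (named list), and `cv_table` (data.frame of
#'   parameter combinations and RMSE; `NA` where a cell was unfit).
#' @export
optimize_pds <- function(Xm_std, Xs_std,
                         w_grid = c(0L, 2L, 5L, 8L, 12L, 16L),
                         component_grid = 1:6) {
  Xm <- as_spec_matrix(Xm_std); Xs <- as_spec_matrix(Xs_std)
  m <- nrow(Xm)
  stopifnot(length(w_grid) > 0, length(component_grid) > 0, m >= 3)
  tab <- expand.grid(w = sort(unique(w_grid)),
                     n_components = sort(unique(component_grid)))
  tab$rmse <- NA_real_
  for (r in seq_len(nrow(tab))) {
    if (tab$n_components[r] > m - 2L) next   # unfit with one sample out
    err2 <- 0; cnt <- 0
    ok <- TRUE
    for (ho in seq_len(m)) {
      fit <- tryCatch(
        fit_pds(Xm[-ho, , drop = FALSE], Xs[-ho, , drop = FALSE],
                w = tab$w[r], n_components = tab$n_components[r]),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pred <- transfer_spectra(fit, Xs[ho, , drop = FALSE])
      err2 <- err2 + sum((pred - Xm[ho, ])^2)
      cnt <- cnt + length(pred)
    }
    if (ok) tab$rmse[r] <- sqrt(err2 / cnt)
  }
  # argmin with parsimony tie-break; RMSEs within 1e-12 count as tied
  if (all(is.na(tab$rmse))) stop("no (w, n_components) cell could be fitted")
  cand <- which(tab$rmse <= min(tab$rmse, na.rm = TRUE) + 1e-12)
  best <- cand[order(tab$w[cand], tab$n_components[cand])][1L]
  structure(
    list(method = "pds",
         chosen = list(w = tab$w[best], n_components = tab$n_components[best],
                       rmse = tab$rmse[best]),
         cv_table = tab),
    class = "transfer_fit_report")
}

#' @export
print.transfer_fit_report <- function(x, ...) {
  cat("<transfer_fit_report> method:", x$method, "\n  chosen:",
      paste(names(x$chosen), unlist(x$chosen), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
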