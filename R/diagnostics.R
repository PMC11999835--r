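#' Spectral-angle and correlation transfer diagnostics
#'
#' Row-wise shape-similarity measures between paired master and slave
#' spectra. The spectral angle of sample i is
#' `theta_i = arccos(<M_i, S_i> / (||M_i|| ||S_i||))`, reported in
#' degrees; it is invariant to positive rescaling of either spectrum.
#' The spectral correlation is the centred Pearson correlation across
#' wavelengths. Small mean angle and correlation near 1 indicate that
#' the slave spectra live in the master's spectral space.
#'
#' @param M,S numeric matrices (or [spectrum_set()]s) of identical
#'   shape, rows aligned sample-by-sample.
#' @return `spectral_angle`: list with `per_sample_angles` (degrees)
#'   and `mean_angle_deg`. `spectral_correlation`: list with
#'   `per_sample_correlations` and `mean_correlation`.
#'   `transfer_diagnostics`: both, as an object of class
#'   `transfer_diagnostics`.
#' @export
spectral_angle <- function(M, S) {
  M <- as_spec_matrix(M); S <- as_spec_matrix(S)
  stopifnot(all(dim(M) == dim(S)))
  nm <- sqrt(rowSums(M^2)); ns <- sqrt(rowSums(S^2))
  bad <- which(nm == 0 | ns == 0)
  if (length(bad)) stop("zero-norm spectrum in row(s) ",
                        paste(bad, collapse = ", "))
  cosang <- rowSums(M * S) / (nm * ns)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  list(per_sample_angles = ang, mean_angle_deg = mean(ang))
}

#' @rdname spectral_angle
#' @export
spectral_correlation <- function(M, S) {
  M <- as_spec_matrix(M); S <- as_spec_matrix(S)
  stopifnot(all(dim(M) == dim(S)))
  Mc <- M - rowMeans(M); Sc <- S - rowMeans(S)
  vm <- rowSums(Mc^2); vs <- rowSums(Sc^2)
  bad <- which(vm == 0 | vs == 0)
  if (length(bad)) stop("zero-variance spectrum in row(s) ",
                        paste(bad, collapse = ", "))
  r <- rowSums(Mc * Sc) / sqrt(vm * vs)
  list(per_sample_correlations = r, mean_correlation = mean(r))
}

#' @rdname spectral_angle
#' @export
transfer_diagnostics <- function(M, S) {
  a <- spectral_angle(M, S)
  r <- spectral_correlation(M, S)
  structure(c(a, r), class = "transfer_diagnostics")
}

#' @export
print.transfer_diagnostics <- function(x, ...) {
  cat(sprintf("<transfer_diagnostics> mean angle %.2f deg, mean r %.4f (m = %d)\n",
              x$mean_angle_deg, x$mean_correlation,
              length(x$per_sample_angles)))
  invisible(x)
}

as_spec_matrix <- function(x) {
  if (inherits(x, "spectrum_set")) x$spectra else as.matrix(x)
}

#' Standard-set sizing curve
#'
#' For each candidate standard-set size `k`, fits a transfer on the
#' first `k` candidate standards (SPXY prefix order), transforms a
#' held-out slave set and reports the mean spectral angle against the
#' matching held-out master set. The curve typically decreases and
#' flattens; the returned `best_k` is the argmin.
#'
#' @param Xm_std,Xs_std row-aligned master/slave standard candidates
#'   (matrices or [spectrum_set()]s), already in SPXY prefix order.
#' @param transfer_factory function `(Xm, Xs) -> model` for which
#'   [transfer_spectra()] is defined, e.g.
#'   `function(m, s) fit_sst(m, s, n_components = 6)`.
#' @param k_grid integer vector of sizes to evaluate.
#' @param Xm_eval,Xs_eval held-out row-aligned evaluation sets.
#' @return data.frame with columns `k` and `mean_angle_deg` (NA where
#'   the fit failed), with attribute `best_k`.
#' @export
size_standard_set <- function(Xm_std, Xs_std, transfer_factory, k_grid,
                              Xm_eval, Xs_eval) {
  Xm_std <- as_spec_matrix(Xm_std); Xs_std <- as_spec_matrix(Xs_std)
  Xm_eval <- as_spec_matrix(Xm_eval); Xs_eval <- as_spec_matrix(Xs_eval)
  stopifnot(max(k_grid) <= nrow(Xm_std))
  angles <- vapply(k_grid, function(k) {
    model <- tryCatch(
      transfer_factory(Xm_std[seq_len(k), , drop = FALSE],
                       Xs_std[seq_len(k), , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(model)) return(NA_real_)
    spectral_angle(Xm_eval, transfer_spectra(model, Xs_eval))$mean_angle_deg
  }, 0)
  out <- data.frame(k = k_grid, mean_angle_deg = angles)
  ok <- which(!is.na(angles))
  attr(out, "best_k") <- if (length(ok)) k_grid[ok[which.min(angles[ok])]]
                         else NA_integer_
  out
}
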