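#' Spectral space transformation (SST)
#'
#' Column-concatenates the mean-centred master and slave standard
#' matrices into `X_comb = [Xm, Xs]`, extracts `n_components`
#' principal components, and splits the loadings into a master block
#' `P_m` and a slave block `P_s`. The transfer matrix is
#' `F = I + pinv(P_s^T) (P_m^T - P_s^T)`, so slave spectra projected
#' onto the shared scores are re-expressed with the master loadings
#' while variation outside the retained subspace passes through
#' unchanged. With identical standards on both instruments, `P_s =
#' P_m` and `F` is exactly the identity.
#'
#' @param Xm_std,Xs_std row-aligned standard sets on a common grid.
#' @param n_components retained principal components, at most
#'   `min(standards - 1, total columns)`.
#' @return An object of class `sst_model` with the transfer matrix
#'   `F_mat`, the centring vectors, and the split loadings.
#' @export
fit_sst <- function(Xm_std, Xs_std, n_components = 6L) {
  Xm <- as_spec_matrix(Xm_std); Xs <- as_spec_matrix(Xs_std)
  stopifnot(nrow(Xm) == nrow(Xs), ncol(Xm) == ncol(Xs))
  m <- nrow(Xm); p <- ncol(Xm)
  if (n_components > min(m - 1L, 2L * p)) {
    stop("n_components must be at most min(standards - 1, total columns)")
  }
  cm <- colMeans(Xm); cs <- colMeans(Xs)
  Xcomb <- cbind(sweep(Xm, 2L, cm), sweep(Xs, 2L, cs))
  sv <- svd(Xcomb, nu = 0L, nv = n_components)
  P <- sv$v                      # 2p x k loadings
  Pm <- P[seq_len(p), , drop = FALSE]
  Ps <- P[p + seq_len(p), , drop = FALSE]
  # F = I + pinv(Ps^T) (Pm^T - Ps^T); pinv(Ps^T) is p x k
  Fmat <- diag(p) + MASS::ginv(t(Ps)) %*% (t(Pm) - t(Ps))
  structure(
    list(method = "sst", n_components = as.integer(n_components),
         F_mat = Fmat, P_m = Pm, P_s = Ps,
         center_master = cm, center_slave = cs, n_bands = p),
    class = c("sst_model", "transfer_model"))
}

#' @export
print.sst_model <- function(x, ...) {
  cat("<sst_model>", x$n_components, "components,", x$n_bands, "bands\n")
  invisible(x)
}

#' @export
transfer_spectra.sst_model <- function(model, X, ...) {
  X <- as_spec_matrix(X)
  if (ncol(X) != model$n_bands) {
    stop("input has ", ncol(X), " bands but the SST model was fitted on ",
         model$n_bands)
  }
  Xc <- sweep(X, 2L, model$center_slave)
  sweep(Xc %*% model$F_mat, 2L, model$center_master, "+")
}
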