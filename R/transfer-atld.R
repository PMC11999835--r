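#' Alternating trilinear decomposition (ATLD) transfer
#'
#' Stacks the master and slave standard matrices into an
#' `I x J x 2` tensor (samples x wavelengths x instruments) and fits
#' the trilinear model `x_ijk = sum_n a_in b_jn c_kn + e_ijk` by
#' alternating least squares: each of the factor matrices `A`
#' (samples), `B` (wavelengths) and `C` (instruments) is updated in
#' turn by an exact least-squares solve on the corresponding
#' matricized tensor using Moore-Penrose pseudoinverses, so the
#' reconstruction error is nonincreasing across iterations.
#' Initialization is deterministic: `A` and `B` from the SVD of the
#' mean instrument slice, `C` from ones.
#'
#' Each instrument's response is summarized by
#' `F_k = diag(c_k) B^T`; a spectrum `x` measured on instrument `k1`
#' is mapped to instrument `k2` as
#' `x + x pinv(F_k1) (F_k2 - F_k1)`, i.e. the part of `x` explained by
#' the factor model is re-expressed with the target instrument's
#' weights while the residual passes through unchanged. Identical
#' instrument weights give the identity map.
#'
#' @param Xm_std,Xs_std row-aligned standards on a common grid;
#'   instrument 1 is the master, instrument 2 the slave.
#' @param n_factors number of trilinear factors `N`, at most
#'   `min(samples, wavelengths)`.
#' @param tol relative change in reconstruction error below which
#'   iteration stops.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE`
#'   with a warning.
#' @return An object of class `atld_model` with factor matrices `A`,
#'   `B`, `C`, per-instrument `F_k` list, `sse_trace`, `iterations`
#'   and `converged`.
#' @export
fit_atld <- function(Xm_std, Xs_std, n_factors = 2L, tol = 1e-10,
                     max_iter = 10000L) {
  Xm <- as_spec_matrix(Xm_std); Xs <- as_spec_matrix(Xs_std)
  stopifnot(nrow(Xm) == nrow(Xs), ncol(Xm) == ncol(Xs))
  I <- nrow(Xm); J <- ncol(Xm); K <- 2L
  N <- as.integer(n_factors)
  if (N > min(I, J)) {
    stop("n_factors must be at most min(samples, wavelengths)")
  }
  X <- array(c(Xm, Xs), dim = c(I, J, K))
  # deterministic init from the mean slice
  Mbar <- (X[, , 1L] + X[, , 2L]) / 2
  sv <- svd(Mbar, nu = N, nv = N)
  A <- sv$u %*% diag(sv$d[seq_len(N)], N)
  B <- sv$v
  C <- matrix(1, K, N)
  X1 <- matrix(X, I, J * K)                     # mode-1 unfolding
  X2 <- matrix(aperm(X, c(2L, 1L, 3L)), J, I * K)
  X3 <- matrix(aperm(X, c(3L, 1L, 2L)), K, I * J)
  ls_update <- function(Xu, KR) Xu %*% KR %*% MASS::ginv(crossprod(KR))
  sse <- function(A, B, C) {
    sum((X1 - A %*% t(khatri_rao(C, B)))^2)
  }
  trace <- sse(A, B, C)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A <- ls_update(X1, khatri_rao(C, B))
    B <- ls_update(X2, khatri_rao(C, A))
    C <- ls_update(X3, khatri_rao(B, A))
    e <- sse(A, B, C)
    prev <- trace[length(trace)]
    trace <- c(trace, e)
    if (prev <= 0 || abs(prev - e) / max(prev, .Machine$double.eps) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("ATLD did not converge in ", max_iter, " iterations")
  Fk <- lapply(seq_len(K), function(k) diag(C[k, ], N) %*% t(B))
  structure(
    list(method = "atld", n_factors = N, A = A, B = B, C = C, F_k = Fk,
         sse_trace = trace, iterations = it, converged = converged,
         total_ss = sum(X^2), n_bands = J),
    class = c("atld_model", "transfer_model"))
}

# column-wise Khatri-Rao (kron per factor column)
khatri_rao <- function(U, V) {
  n <- ncol(U)
  stopifnot(ncol(V) == n)
  out <- matrix(0, nrow(U) * nrow(V), n)
  for (j in seq_len(n)) out[, j] <- kronecker(U[, j], V[, j])
  out
}

#' @export
print.atld_model <- function(x, ...) {
  cat("<atld_model>", x$n_factors, "factors,", x$n_bands, "bands;",
      x$iterations, "iterations, relative error",
      format(sqrt(x$sse_trace[length(x$sse_trace)] / x$total_ss),
             digits = 3), "\n")
  invisible(x)
}

#' Map spectra between the instruments of an ATLD model
#'
#' @param model a fitted [fit_atld()] model.
#' @param X spectra measured on instrument `from_k`.
#' @param from_k,to_k instrument indices in `{1, 2}` (1 = master,
#'   2 = slave as fitted).
#' @return Matrix of transformed spectra.
#' @export
apply_atld <- function(model, X, from_k = 2L, to_k = 1L) {
  stopifnot(inherits(model, "atld_model"))
  if (!from_k %in% 1:2 || !to_k %in% 1:2) {
    stop("instrument index must be 1 or 2")
  }
  X <- as_spec_matrix(X)
  if (ncol(X) != model$n_bands) {
    stop("input has ", ncol(X), " bands but the ATLD model was fitted on ",
         model$n_bands)
  }
  F1 <- model$F_k[[from_k]]; F2 <- model$F_k[[to_k]]
  X + X %*% MASS::ginv(F1) %*% (F2 - F1)
}

#' @export
transfer_spectra.atld_model <- function(model, X, ...) {
  apply_atld(model, X, from_k = 2L, to_k = 1L)
}
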