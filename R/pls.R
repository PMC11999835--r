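#' SIMPLS partial least squares regression (internal engine)
#'
#' Compact SIMPLS used by the PDS local regressions and by PLS-DA.
#' X and Y are mean-centred internally; deflation acts on the
#' cross-product matrix, never on X. When the requested number of
#' components reaches the rank of the centred X, the fitted values
#' coincide with ordinary least squares on the same design.
#'
#' @param X numeric matrix n x p.
#' @param Y numeric matrix n x q (a vector is treated as one column).
#' @param ncomp number of latent components.
#' @return list with `coef` (p x q), `intercept` (length q),
#'   `ncomp_used`, `x_center`, `y_center`.
#' @keywords internal
simpls_fit <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  stopifnot(nrow(Y) == n, ncomp >= 1)
  ncomp <- min(ncomp, n - 1L, p)
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2L, xc)
  Yc <- sweep(Y, 2L, yc)
  S <- crossprod(Xc, Yc)
  R <- matrix(0, p, ncomp); Q <- matrix(0, q, ncomp)
  V <- matrix(0, p, ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    if (q == 1L) {
      r <- S[, 1L]
    } else {
      r <- svd(S, nu = 1L, nv = 0L)$u[, 1L]
    }
    t_sc <- Xc %*% r
    nt <- sqrt(sum(t_sc^2))
    if (nt < 1e-12 || sqrt(sum(r^2)) < 1e-14) break
    t_sc <- t_sc / nt
    r <- r / nt
    p_l <- crossprod(Xc, t_sc)
    q_l <- crossprod(Yc, t_sc)
    v <- p_l
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_l)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[, a] <- q_l; V[, a] <- v
    a_used <- a
  }
  if (a_used == 0L) {
    coef <- matrix(0, p, q)
  } else {
    coef <- R[, seq_len(a_used), drop = FALSE] %*%
      t(Q[, seq_len(a_used), drop = FALSE])
  }
  list(coef = coef, intercept = as.numeric(yc - crossprod(coef, xc)),
       ncomp_used = a_used, x_center = xc, y_center = yc)
}

simpls_predict <- function(fit, X) {
  X <- as.matrix(X)
  sweep(X %*% fit$coef, 2L, fit$intercept, "+")
}
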