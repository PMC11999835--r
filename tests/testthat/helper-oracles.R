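# Independent brute-force oracles used to verify the fast implementations.

# Naive SPXY greedy selection, written directly from the max-min rule with
# explicit loops; deliberately independent of spxy_split().
spxy_oracle <- function(X, Y, n_train) {
  m <- nrow(X)
  dX <- matrix(0, m, m); dY <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      dX[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
      dY[i, j] <- sqrt(sum((Y[i, ] - Y[j, ])^2))
    }
  }
  d <- dX / max(dX) + dY / max(dY)
  bv <- -Inf; best <- c(1L, 2L)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (d[i, j] > bv) { bv <- d[i, j]; best <- c(i, j) }
    }
  }
  sel <- best
  while (length(sel) < n_train) {
    rem <- setdiff(seq_len(m), sel)
    mv <- -Inf; pick <- rem[1L]
    for (r in rem) {
      md <- min(d[r, sel])
      if (md > mv) { mv <- md; pick <- r }
    }
    sel <- c(sel, pick)
  }
  sel
}

one_hot <- function(labels) {
  lev <- sort(unique(labels))
  outer(labels, lev, "==") * 1
}

# per-wavelength ordinary least squares transfer (oracle for PDS w = 0)
ols_band_transfer <- function(Xm, Xs, Xnew) {
  out <- matrix(0, nrow(Xnew), ncol(Xm))
  for (i in seq_len(ncol(Xm))) {
    cf <- stats::lm.fit(cbind(1, Xs[, i]), Xm[, i])$coefficients
    out[, i] <- cf[1] + cf[2] * Xnew[, i]
  }
  out
}

# small deterministic spectra-like matrix
rand_spectra <- function(m, p, seed) {
  set.seed(seed)
  matrix(stats::runif(m * p, 0.1, 0.9), m, p)
}

# paired master/slave data on the common grid, shared by several tests
make_common_pair <- function(seed = 1, n_per_class = 16) {
  pair <- generate_paired_sets(n_per_class = n_per_class, seed = seed)
  grid <- pair$slave$wavelengths_nm
  list(master = resample_to_grid(pair$master, grid),
       slave = pair$slave, grid = grid)
}
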