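test_that("ATLD recovers a noiseless rank-2 trilinear tensor", {
  set.seed(10)
  A0 <- matrix(stats::runif(20, 0.5, 1.5), 10, 2)
  B0 <- matrix(stats::runif(60, 0.2, 1), 30, 2)
  C0 <- matrix(c(1, 0.7, 0.6, 1.3), 2, 2)
  Xm <- A0 %*% (diag(C0[1, ]) %*% t(B0))
  Xs <- A0 %*% (diag(C0[2, ]) %*% t(B0))
  fit <- fit_atld(Xm, Xs, n_factors = 2)
  rel_err <- sqrt(fit$sse_trace[length(fit$sse_trace)] / fit$total_ss)
  expect_lt(rel_err, 1e-8)
  expect_true(fit$converged)
  # objective nonincreasing at every accepted iteration
  expect_true(all(diff(fit$sse_trace) <= 1e-10 * fit$sse_trace[1]))
  # wavelength factors recovered up to permutation and scale
  congr <- abs(crossprod(
    sweep(fit$B, 2, sqrt(colSums(fit$B^2)), "/"),
    sweep(B0, 2, sqrt(colSums(B0^2)), "/")))
  perm_best <- max(congr[1, 1] * congr[2, 2], congr[1, 2] * congr[2, 1])
  expect_gt(sqrt(perm_best), 0.999)
})

test_that("identical instrument slices give an identity transfer", {
  X <- rand_spectra(8, 20, seed = 11)
  fit <- fit_atld(X, X, n_factors = 2)
  expect_lt(max(abs(fit$F_k[[1]] - fit$F_k[[2]])), 1e-8)
  Xnew <- rand_spectra(3, 20, seed = 12)
  expect_equal(apply_atld(fit, Xnew, from_k = 2, to_k = 1), Xnew,
               tolerance = 1e-8)
})

test_that("ATLD transfer improves the synthetic instrument shift and
           round-trips", {
  pair <- make_common_pair(seed = 6, n_per_class = 10)
  idx <- 1:20; te <- 21:30
  fit <- fit_atld(pair$master$spectra[idx, ], pair$slave$spectra[idx, ],
                  n_factors = 2)
  Xs_te <- pair$slave$spectra[te, ]
  Xm_te <- pair$master$spectra[te, ]
  before <- spectral_angle(Xm_te, Xs_te)$mean_angle_deg
  moved <- apply_atld(fit, Xs_te, from_k = 2, to_k = 1)
  expect_lt(spectral_angle(Xm_te, moved)$mean_angle_deg, before)
  expect_equal(dim(moved), dim(Xs_te))
  # slave -> master -> slave round trip barely changes the shape
  back <- apply_atld(fit, moved, from_k = 1, to_k = 2)
  expect_lt(spectral_angle(Xs_te, back)$mean_angle_deg, 1)
  expect_error(apply_atld(fit, Xs_te, from_k = 3), "index")
  expect_error(fit_atld(pair$master$spectra[1:3, ], pair$slave$spectra[1:3, ],
                        n_factors = 5), "n_factors")
})

test_that("five-fold CV selects the constructed rank and breaks ties small", {
  # rank-2 instrument difference: CV should pick 2 factors
  set.seed(13)
  A0 <- matrix(stats::runif(40, 0.5, 1.5), 20, 2)
  B0 <- matrix(stats::runif(50, 0.2, 1), 25, 2)
  Xm <- A0 %*% t(B0)
  Xs <- A0 %*% diag(c(1.4, 0.7)) %*% t(B0)
  rep_atld <- cv_select_components("atld", Xm, Xs, grid = 1:4, seed = 3)
  expect_equal(rep_atld$chosen$value, 2)
  expect_equal(rep_atld$chosen$rmse, min(rep_atld$cv_table$rmse))
  # master = slave: near-zero RMSE everywhere, smallest value wins
  X <- rand_spectra(12, 10, seed = 14)
  rep_id <- cv_select_components("sst", X, X, grid = c(1, 2, 3), seed = 4)
  expect_equal(rep_id$chosen$value, 1)
  expect_lt(rep_id$chosen$rmse, 1e-10)
})
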