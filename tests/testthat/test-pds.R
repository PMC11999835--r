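test_that("PDS reproduces identity and affine instrument relations", {
  Xm <- rand_spectra(12, 20, seed = 1)
  # slave = master, w = 0, 1 component: exact identity
  fit <- fit_pds(Xm, Xm, w = 0, n_components = 1)
  expect_equal(transfer_spectra(fit, Xm), Xm, tolerance = 1e-8)
  # slave = 2 * master + 0.1: inverse map has slope 0.5, intercept -0.05
  Xs <- 2 * Xm + 0.1
  fit2 <- fit_pds(Xm, Xs, w = 0, n_components = 1)
  expect_equal(unlist(fit2$coeffs), rep(0.5, 20), tolerance = 1e-8)
  expect_equal(fit2$intercepts, rep(-0.05, 20), tolerance = 1e-8)
  expect_equal(transfer_spectra(fit2, Xs), Xm, tolerance = 1e-8)
})

test_that("PDS with w=0 and 1 component equals per-wavelength OLS", {
  Xm <- rand_spectra(15, 25, seed = 2)
  Xs <- Xm * 1.2 + matrix(stats::rnorm(15 * 25, 0, 0.01), 15, 25) + 0.05
  Xnew <- rand_spectra(6, 25, seed = 3) * 1.2 + 0.05
  fit <- fit_pds(Xm, Xs, w = 0, n_components = 1)
  expect_equal(transfer_spectra(fit, Xnew), ols_band_transfer(Xm, Xs, Xnew),
               tolerance = 1e-8)
})

test_that("PDS transfer contracts the standards toward the master", {
  pair <- make_common_pair(seed = 4, n_per_class = 10)
  Xm <- pair$master$spectra; Xs <- pair$slave$spectra
  fit <- fit_pds(Xm[1:15, ], Xs[1:15, ], w = 12, n_components = 6)
  before <- sqrt(mean((Xs[1:15, ] - Xm[1:15, ])^2))
  after <- sqrt(mean((transfer_spectra(fit, Xs[1:15, ]) - Xm[1:15, ])^2))
  expect_lt(after, before)
  # all-zero slave spectrum returns the stored intercepts; rows preserved
  z <- transfer_spectra(fit, matrix(0, 2, ncol(Xm)))
  expect_equal(z[1, ], fit$intercepts)
  expect_equal(nrow(z), 2)
  expect_error(transfer_spectra(fit, Xs[, 1:10]), "bands")
  expect_error(fit_pds(Xm[1:5, ], Xs[1:5, ], w = 2, n_components = 8),
               "standards")
})

test_that("window search selects no window on identical instruments and a
           window under wavelength shift", {
  Xm <- rand_spectra(8, 15, seed = 6)
  rep0 <- optimize_pds(Xm, Xm, w_grid = c(0, 2, 4), component_grid = 1:2)
  expect_equal(rep0$chosen$w, 0)
  expect_equal(rep0$chosen$n_components, 1)
  expect_lt(rep0$chosen$rmse, 1e-10)
  expect_equal(rep0$chosen$rmse, min(rep0$cv_table$rmse, na.rm = TRUE))
  # synthetic 3 nm wavelength shift on a 5 nm grid: neighbours informative
  grid <- seq(400, 800, 5)
  lat <- generate_latent_spectra(default_meat_models()$beef, 14, seed = 7)
  master <- apply_instrument(lat, instrument_model("m", grid, fwhm_nm = 5))
  slave <- apply_instrument(
    lat, instrument_model("s", grid, fwhm_nm = 5, wavelength_shift_nm = 3))
  rep1 <- optimize_pds(master$spectra, slave$spectra, w_grid = c(0, 2, 5),
                       component_grid = c(2, 4))
  expect_gt(rep1$chosen$w, 0)
  best <- which(rep1$cv_table$rmse == min(rep1$cv_table$rmse, na.rm = TRUE))
  expect_true(rep1$chosen$w %in% rep1$cv_table$w[best])
})
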