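test_that("latent spectra carry the myoglobin band structure", {
  mods <- default_meat_models()
  # deterministic single spectra (no within-class variability)
  quiet <- lapply(mods, function(m) {
    m$within_class_sd <- 0
    generate_latent_spectra(m, 1, seed = 1)
  })
  wl <- quiet$chicken$wavelengths_nm
  # local reflectance minimum within +/- 5 nm of 540 nm
  around <- which(wl >= 520 & wl <= 560)
  dip <- wl[around][which.min(quiet$chicken$spectra[1, around])]
  expect_lte(abs(dip - 540), 5)
  # beef has a 630 nm dip that chicken lacks: compare curvature of the
  # residual after removing a straight line across 600-660 nm
  win <- which(wl >= 600 & wl <= 660)
  dip_depth <- function(s) {
    y <- s[1, win]
    line <- seq(y[1], y[length(y)], length.out = length(y))
    max(line - y)
  }
  expect_gt(dip_depth(quiet$beef$spectra), 0.02)
  expect_lt(dip_depth(quiet$chicken$spectra), 0.005)
  # chicken is the most reflective class
  expect_gt(mean(quiet$chicken$spectra), mean(quiet$beef$spectra))
  expect_gt(mean(quiet$chicken$spectra), mean(quiet$duck$spectra))
  # all values in [0, 1]
  s <- generate_latent_spectra(mods$beef, 20, seed = 3)
  expect_true(all(s$spectra >= 0 & s$spectra <= 1))
})

test_that("latent generation is deterministic and validates input", {
  m <- default_meat_models()$duck
  a <- generate_latent_spectra(m, 10, seed = 42)
  b <- generate_latent_spectra(m, 10, seed = 42)
  expect_identical(a$spectra, b$spectra)
  expect_false(identical(
    a$spectra, generate_latent_spectra(m, 10, seed = 43)$spectra))
  bad <- m
  bad$bands$center_nm[1] <- 250
  expect_error(meat_class_model("x", 0.5, 0, bad$bands), "400")
  expect_error(generate_latent_spectra(m, 1, dense_grid = seq(500, 800, 1)),
               "dense_grid")
})

test_that("apply_instrument reduces to identity, linearity and offset limits", {
  grid <- seq(400, 800, by = 0.5)
  m <- default_meat_models()$beef
  m$within_class_sd <- 0
  lat <- generate_latent_spectra(m, 1, dense_grid = seq(380, 820, 0.5),
                                 seed = 1)
  ident <- instrument_model("id", grid_nm = grid, fwhm_nm = 1e-4)
  out <- apply_instrument(lat, ident)
  keep <- match(grid, lat$wavelengths_nm)
  expect_equal(out$spectra[1, ], lat$spectra[1, keep], tolerance = 1e-6)
  # gain doubles the convolved value
  g2 <- instrument_model("g2", grid_nm = seq(420, 780, 5), fwhm_nm = 5,
                         gain = 2)
  g1 <- instrument_model("g1", grid_nm = seq(420, 780, 5), fwhm_nm = 5)
  expect_equal(apply_instrument(lat, g2)$spectra,
               2 * apply_instrument(lat, g1)$spectra, tolerance = 1e-12)
  # constant spectrum: convolution passes the constant, offset adds
  flat <- spectrum_set(lat$wavelengths_nm,
                       matrix(0.5, 1, length(lat$wavelengths_nm)))
  off <- instrument_model("off", grid_nm = seq(420, 780, 5), fwhm_nm = 12,
                          offset = 0.1)
  expect_equal(unname(apply_instrument(flat, off)$spectra[1, ]),
               rep(0.6, length(seq(420, 780, 5))), tolerance = 1e-12)
  # uncovered range is refused with the range named
  wide <- instrument_model("wide", grid_nm = seq(310, 790, 5), fwhm_nm = 5)
  expect_error(apply_instrument(lat, wide), "latent")
})

test_that("paired sets are row-aligned and sized by the sampling design", {
  pair <- generate_paired_sets(n_per_class = 48, seed = 7)
  expect_equal(nrow(pair$master$spectra), 144)
  expect_equal(nrow(pair$slave$spectra), 144)
  expect_identical(pair$master$labels, pair$slave$labels)
  expect_identical(pair$master$sample_ids, pair$slave$sample_ids)
  # same instrument (including its noise seed) on both arms: identical data
  instr <- slave_instrument()
  instr$seed <- 99L
  same <- generate_paired_sets(n_per_class = 4, master = instr,
                               slave = instr, seed = 1)
  expect_identical(same$master$spectra, same$slave$spectra)
})

test_that("class separation and instrument shift have the designed geometry", {
  mods <- default_meat_models()
  ch <- generate_latent_spectra(mods$chicken, 100, seed = 11)
  bf <- generate_latent_spectra(mods$beef, 100, seed = 12)
  between <- spectral_angle(ch$spectra, bf$spectra)$mean_angle_deg
  within <- spectral_angle(ch$spectra[1:50, ],
                           ch$spectra[51:100, ])$mean_angle_deg
  expect_gt(between, within)
  # default master/slave difference is a sizeable shape distortion
  pair <- make_common_pair(seed = 3, n_per_class = 20)
  expect_gt(spectral_angle(pair$master, pair$slave)$mean_angle_deg, 5)
})

test_that("spliced cubes honour the requested proportions exactly", {
  cube <- generate_spliced_cube(proportions = c(1, 1, 1), shape = c(60, 60),
                                seed = 1)
  expect_equal(unname(cube$truth_proportions), rep(1 / 3, 3),
               tolerance = 1 / 3600)
  counts <- tabulate(cube$truth_map, 3)
  expect_equal(counts / sum(counts), unname(cube$truth_proportions))
  # 2:1:1 with alphabetical class order beef, chicken, duck
  cube2 <- generate_spliced_cube(proportions = c(2, 1, 1), shape = c(40, 40),
                                 seed = 2)
  expect_equal(unname(cube2$truth_proportions["beef"]), 0.5)
  expect_equal(dim(cube2$data), c(40, 40, 81))
  # stripes are contiguous: each class occupies a contiguous column block
  runs <- rle(as.vector(cube$truth_map[1, ]))
  expect_lte(length(runs$values), 4)  # 3 stripes + at most 1 boundary split
  expect_error(generate_spliced_cube(proportions = c(1e-5, 1, 1),
                                     shape = c(16, 16), seed = 1),
               "region")
})
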