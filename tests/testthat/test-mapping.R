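# shared small pipeline: noiseless instruments, SVM trained on slave-space
# spectra from the same generator (no shift), plus a shifted variant
make_map_fixture <- function(seed = 1) {
  mods <- default_meat_models()
  slave0 <- slave_instrument(noise_sd = 0)
  slave0$gain <- 1; slave0$offset <- 0
  slave0$wavelength_shift_nm <- 0; slave0$response <- NULL
  pair <- generate_paired_sets(mods, n_per_class = 48, master = slave0,
                               slave = slave0, seed = seed)
  svm <- fit_svm(pair$master$spectra, pair$master$labels,
                 C_grid = c(100, 1000), gamma_grid = c(1, 5),
                 seed = seed)
  list(mods = mods, ideal = slave0, svm = svm)
}

test_that("a single-class cube is classified almost entirely as that class", {
  fx <- make_map_fixture(seed = 2)
  cube <- generate_spliced_cube(list(duck = fx$mods$duck), c(1),
                                shape = c(24, 24), slave = fx$ideal,
                                seed = 3)
  map <- classify_cube(cube, fx$svm)
  expect_equal(dim(map$labels), c(24, 24))
  acc <- mean(map$class_order[map$labels] == "duck")
  expect_gt(acc, 0.99)
})

test_that("stripe boundaries are recovered on a noiseless cube", {
  fx <- make_map_fixture(seed = 4)
  cube <- generate_spliced_cube(fx$mods, c(1, 1, 1), shape = c(30, 30),
                                slave = fx$ideal, seed = 5)
  map <- classify_cube(cube, fx$svm)
  # per-column modal class must match the truth stripes within 2 columns
  modal <- apply(map$labels, 2, function(col) which.max(tabulate(col, 3)))
  truth_modal <- apply(cube$truth_map, 2, function(col)
    which.max(tabulate(col, 3)))
  expect_lte(sum(modal != truth_modal), 2)
})

test_that("proportions are conserved and exact against the truth map", {
  fx <- make_map_fixture(seed = 6)
  cube <- generate_spliced_cube(fx$mods, c(2, 1, 1), shape = c(20, 20),
                                slave = fx$ideal, seed = 7)
  map <- classify_cube(cube, fx$svm)
  pr <- proportions(map, cube)
  expect_equal(sum(pr$predicted), 1, tolerance = 1e-9)
  # truth-equal map gives zero deviation
  perfect <- map
  perfect$labels <- cube$truth_map
  pr2 <- proportions(perfect, cube)
  expect_true(all(pr2$abs_deviation == 0))
  # counting identity: 200/100/100 pixels -> 50/25/25 %
  expect_equal(pr2$predicted, c(0.5, 0.25, 0.25))
})

test_that("rendered maps round-trip through the palette", {
  fx <- make_map_fixture(seed = 8)
  cube <- generate_spliced_cube(fx$mods, c(1, 1, 1), shape = c(18, 18),
                                slave = fx$ideal, seed = 9)
  map <- classify_cube(cube, fx$svm)
  path <- tempfile(fileext = ".png")
  render_map(map, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".legend.txt")))
  back <- read_map_png(path, map$palette)
  expect_identical(back, map$labels)
  # distinct classes map to distinct colours
  expect_equal(nrow(unique(map$palette)), nrow(map$palette))
  unlink(c(path, paste0(path, ".legend.txt")))
})

test_that("transfer before pixel classification reduces proportion error", {
  mods <- default_meat_models()
  pair <- generate_paired_sets(mods, n_per_class = 16, seed = 10)
  grid <- pair$slave$wavelengths_nm
  master <- resample_to_grid(pair$master, grid)
  sp <- spxy_split(master$spectra, master$labels, 32)
  std <- select_standard_samples(sp, 10)
  sst <- fit_sst(master$spectra[std, ], pair$slave$spectra[std, ], 6)
  svm <- fit_svm(master$spectra[sp$train_indices, ],
                 master$labels[sp$train_indices],
                 C_grid = c(1, 10), gamma_grid = c(0.1, 1), seed = 10)
  cube <- generate_spliced_cube(mods, c(1, 1, 1), shape = c(24, 24),
                                slave = slave_instrument(noise_sd = 0),
                                seed = 11)
  mad_of <- function(transfer) {
    pr <- proportions(classify_cube(cube, svm, transfer = transfer), cube)
    mean(pr$abs_deviation)
  }
  expect_lt(mad_of(sst), mad_of(NULL))
})
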