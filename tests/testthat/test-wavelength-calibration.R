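# Printed dispersion coefficients of the reference imager
seg1 <- c(a = -7.44e-6, b = -0.201, c = 796.19)
seg2 <- c(a = -3.39e-6, b = -0.208, c = 799.5)

test_that("quadratic segment coefficients are recovered from noiseless pairs", {
  px <- c(seq(10, 940, by = 30), seq(950, 1860, by = 30))
  wl <- ifelse(px <= 944,
               seg1[1] * px^2 + seg1[2] * px + seg1[3],
               seg2[1] * px^2 + seg2[2] * px + seg2[3])
  cal <- fit_wavelength_calibration(data.frame(pixel = px,
                                               wavelength_nm = wl))
  expect_equal(unname(cal$segment_coeffs[1, ]), unname(seg1),
               tolerance = 1e-8)
  expect_equal(unname(cal$segment_coeffs[2, ]), unname(seg2),
               tolerance = 1e-8)
  expect_true(all(cal$residual_rms < 1e-9))
  expect_true(cal$monotone)
})

test_that("linear pairs give a vanishing quadratic term", {
  px <- c(seq(50, 900, by = 50), seq(1000, 1800, by = 50))
  wl <- 800 - 0.2 * px
  cal <- fit_wavelength_calibration(data.frame(px, wl))
  expect_equal(unname(cal$segment_coeffs[, "a"]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(cal$segment_coeffs[, "b"]), c(-0.2, -0.2),
               tolerance = 1e-10)
  expect_equal(unname(cal$segment_coeffs[, "c"]), c(800, 800),
               tolerance = 1e-8)
})

test_that("underdetermined segments are rejected", {
  px <- c(100, 200, seq(1000, 1800, 100))
  wl <- 800 - 0.2 * px
  expect_error(fit_wavelength_calibration(data.frame(px, wl)), "3")
})

test_that("pixel evaluation matches direct evaluation of the dispersion", {
  cal <- wavelength_calibration(seg1, seg2)
  expect_equal(wavelength_for_pixel(cal, 1),
               seg1[[1]] * 1 + seg1[[2]] * 1 + seg1[[3]],
               tolerance = 1e-12)  # 795.98899256 nm
  expect_equal(wavelength_for_pixel(cal, 1000),
               seg2[[1]] * 1e6 + seg2[[2]] * 1000 + seg2[[3]],
               tolerance = 1e-12)  # 588.11 nm
  expect_equal(wavelength_for_pixel(cal, 1000), 588.11, tolerance = 1e-10)
  # dispersion is decreasing in pixel index
  expect_gt(wavelength_for_pixel(cal, 100), wavelength_for_pixel(cal, 900))
  expect_error(wavelength_for_pixel(cal, 5000), "range")
})

test_that("fit then evaluate round-trips arbitrary quadratics", {
  set.seed(5)
  for (rep in 1:5) {
    s1 <- c(stats::runif(1, -1e-5, 1e-5), stats::runif(1, -0.3, -0.1),
            stats::runif(1, 700, 900))
    s2 <- s1 + c(stats::runif(1, -1e-6, 1e-6), stats::runif(1, -0.01, 0.01),
                 stats::runif(1, -5, 5))
    px <- sort(c(sample(5:940, 12), sample(945:1870, 12)))
    wl <- ifelse(px <= 944, s1[1] * px^2 + s1[2] * px + s1[3],
                 s2[1] * px^2 + s2[2] * px + s2[3])
    # independent random segments need not join monotonically at the
    # breakpoint; the property under test is per-segment fit accuracy
    cal <- suppressWarnings(fit_wavelength_calibration(data.frame(px, wl)))
    eval_px <- seq(min(px), max(px), length.out = 101)
    truth <- ifelse(eval_px <= 944,
                    s1[1] * eval_px^2 + s1[2] * eval_px + s1[3],
                    s2[1] * eval_px^2 + s2[2] * eval_px + s2[3])
    expect_lt(max(abs(wavelength_for_pixel(cal, eval_px) - truth)), 1e-6)
  }
})

test_that("FWHM estimation matches closed forms", {
  # Gaussian line: FWHM = 2 sqrt(2 log 2) sigma
  ax <- seq(540, 553, by = 0.1)
  y <- exp(-0.5 * ((ax - 546.6) / 1.5)^2)
  expect_equal(estimate_fwhm(ax, y), 2 * sqrt(2 * log(2)) * 1.5,
               tolerance = 0.01 / 3.53)
  # triangular peak with half-width 2 at half height
  ax2 <- seq(-5, 5, by = 0.25)
  tri <- pmax(0, 1 - abs(ax2) / 4)   # falls to 0.5 at |x| = 2
  expect_equal(estimate_fwhm(ax2, tri), 4, tolerance = 1e-9)
  # flat scan has no peak
  expect_error(estimate_fwhm(ax, rep(1, length(ax))), "maximum")
})

test_that("FWHM is invariant to intensity scale and additive baseline", {
  ax <- seq(430, 443, by = 0.05)
  y <- exp(-0.5 * ((ax - 436.6) / 1.66)^2)
  f0 <- estimate_fwhm(ax, y)
  expect_equal(estimate_fwhm(ax, 37 * y), f0, tolerance = 1e-12)
  expect_equal(estimate_fwhm(ax, y + 0.8), f0, tolerance = 1e-9)
  # unresolved line: left flank truncated above half maximum
  ax3 <- seq(-1, 3, 0.1)
  expect_error(estimate_fwhm(ax3, exp(-0.5 * ax3^2)), "unresolved")
})
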