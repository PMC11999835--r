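#' Piecewise pixel-to-wavelength calibration
#'
#' Push-broom imagers map detector pixel index to wavelength through a
#' dispersion curve that is well described by two quadratic segments
#' joined at a fixed breakpoint pixel. `fit_wavelength_calibration`
#' fits each segment by ordinary least squares from (pixel, known
#' wavelength) pairs, e.g. monochromator scans at 1 nm steps. Segment
#' membership uses half-open intervals `(min, breakpoint]` and
#' `(breakpoint, max]`.
#'
#' Fitting is done on centred pixel values for conditioning and the
#' coefficients are converted back to the raw form
#' `lambda = a * i^2 + b * i + c`, so noiseless quadratic pairs are
#' recovered to machine precision.
#'
#' @param pairs data.frame or matrix with columns `pixel` and
#'   `wavelength_nm` (first two columns are used).
#' @param breakpoint_pixel pixel index separating the two segments.
#' @return An object of class `wavelength_calibration` with
#'   `segment_coeffs` (2 x 3 matrix of `a`, `b`, `c`), `breakpoint_pixel`,
#'   `pixel_range`, per-segment `residual_rms`, and `monotone` flag.
#' @export
fit_wavelength_calibration <- function(pairs, breakpoint_pixel = 944L) {
  pairs <- as.data.frame(pairs)
  px <- as.numeric(pairs[[1L]])
  wl <- as.numeric(pairs[[2L]])
  seg <- ifelse(px <= breakpoint_pixel, 1L, 2L)
  if (sum(seg == 1L) < 3L || sum(seg == 2L) < 3L) {
    stop("need at least 3 (pixel, wavelength) pairs per segment")
  }
  coeffs <- matrix(NA_real_, 2L, 3L,
                   dimnames = list(c("seg1", "seg2"), c("a", "b", "c")))
  rms <- numeric(2L)
  for (s in 1:2) {
    x <- px[seg == s]; y <- wl[seg == s]
    mu <- mean(x)
    xc <- x - mu
    fit <- stats::lm.fit(cbind(1, xc, xc^2), y)
    cf <- fit$coefficients            # y = cf3*xc^2 + cf2*xc + cf1
    a <- cf[3]; b <- cf[2] - 2 * cf[3] * mu
    cc <- cf[1] - cf[2] * mu + cf[3] * mu^2
    coeffs[s, ] <- c(a, b, cc)
    rms[s] <- sqrt(mean(fit$residuals^2))
  }
  cal <- structure(
    list(breakpoint_pixel = breakpoint_pixel,
         segment_coeffs = coeffs,
         pixel_range = range(px),
         residual_rms = rms,
         monotone = NA),
    class = "wavelength_calibration")
  # monotonicity check over the fitted range
  grid <- seq(cal$pixel_range[1], cal$pixel_range[2], length.out = 512L)
  lam <- vapply(grid, function(i) wavelength_for_pixel(cal, i), 0)
  d <- diff(lam)
  cal$monotone <- all(d > 0) || all(d < 0)
  if (!cal$monotone) {
    warning("fitted pixel-to-wavelength mapping is not monotone")
  }
  cal
}

#' @export
print.wavelength_calibration <- function(x, ...) {
  cat("<wavelength_calibration> breakpoint at pixel", x$breakpoint_pixel, "\n")
  for (s in 1:2) {
    cat(sprintf("  segment %d: lambda = %.6g i^2 + %.6g i + %.6g (rms %.3g nm)\n",
                s, x$segment_coeffs[s, 1], x$segment_coeffs[s, 2],
                x$segment_coeffs[s, 3], x$residual_rms[s]))
  }
  invisible(x)
}

#' Evaluate a wavelength calibration at a pixel
#'
#' @param cal a [fit_wavelength_calibration()] result, or any object
#'   with `segment_coeffs`, `breakpoint_pixel` and `pixel_range`.
#' @param i pixel index (vectorized), within the calibrated range.
#' @return Wavelength(s) in nm.
#' @export
wavelength_for_pixel <- function(cal, i) {
  if (any(i < cal$pixel_range[1] | i > cal$pixel_range[2])) {
    stop(sprintf("pixel index outside calibrated range [%g, %g]",
                 cal$pixel_range[1], cal$pixel_range[2]))
  }
  s <- ifelse(i <= cal$breakpoint_pixel, 1L, 2L)
  a <- unname(cal$segment_coeffs[s, 1])
  b <- unname(cal$segment_coeffs[s, 2])
  cc <- unname(cal$segment_coeffs[s, 3])
  a * i^2 + b * i + cc
}

#' Reference dispersion coefficients
#'
#' Convenience constructor for a `wavelength_calibration` object from
#' explicit per-segment quadratic coefficients, without fitting.
#'
#' @param seg1,seg2 numeric length-3 vectors `c(a, b, c)` for
#'   `lambda = a i^2 + b i + c` on `(0, breakpoint]` and
#'   `(breakpoint, max]`.
#' @param breakpoint_pixel breakpoint pixel.
#' @param pixel_range calibrated pixel range.
#' @return A `wavelength_calibration` object.
#' @export
wavelength_calibration <- function(seg1, seg2, breakpoint_pixel = 944L,
                                   pixel_range = c(1L, 1870L)) {
  structure(
    list(breakpoint_pixel = breakpoint_pixel,
         segment_coeffs = rbind(seg1 = seg1, seg2 = seg2),
         pixel_range = pixel_range,
         residual_rms = c(NA_real_, NA_real_),
         monotone = NA),
    class = "wavelength_calibration")
}

#' Estimate the FWHM of an emission line
#'
#' Locates the local maximum nearest `peak_location`, subtracts the
#' scan minimum as a baseline, and finds the half-maximum crossing on
#' each flank by linear interpolation between the bracketing samples.
#' The returned width is the separation of the two crossings, in the
#' units of `axis` — the operational spectral resolution when the scan
#' is an isolated calibration-lamp line.
#'
#' @param axis pixel indices or wavelengths, strictly monotone.
#' @param intensity nonnegative intensities, same length as `axis`.
#' @param peak_location position (in `axis` units) near the line of
#'   interest; defaults to the global maximum.
#' @return FWHM in axis units.
#' @export
estimate_fwhm <- function(axis, intensity, peak_location = NULL) {
  stopifnot(length(axis) == length(intensity), length(axis) >= 3L)
  n <- length(axis)
  base <- min(intensity)
  y <- intensity - base
  # candidate interior local maxima
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(is_max) == 0L) stop("no interior local maximum in scan")
  if (is.null(peak_location)) {
    pk <- is_max[which.max(y[is_max])]
  } else {
    pk <- is_max[which.min(abs(axis[is_max] - peak_location))]
  }
  half <- y[pk] / 2
  if (half <= 0) stop("no interior local maximum in scan")
  cross <- function(idx_seq) {
    # first crossing below half along idx_seq (walking away from peak)
    for (j in seq_along(idx_seq)[-1L]) {
      i0 <- idx_seq[j - 1L]; i1 <- idx_seq[j]
      if (y[i1] <= half) {
        f <- (y[i0] - half) / (y[i0] - y[i1])
        return(axis[i0] + f * (axis[i1] - axis[i0]))
      }
    }
    stop("unresolved line: flank never falls below half maximum")
  }
  left <- cross(pk:1L)
  right <- cross(pk:n)
  abs(right - left)
}
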