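#' Meat class reflectance models
#'
#' Parametric model of a meat species' visible reflectance curve: a
#' linear baseline minus a sum of Gaussian absorption bands, with
#' multiplicative within-class variability. Band positions follow the
#' myoglobin absorption features that distinguish poultry and red meat
#' in the 400-800 nm window: the Soret band near 420 nm
#' (deoxymyoglobin) and the oxymyoglobin doublet at 540/575 nm; beef
#' additionally shows a weak metmyoglobin band near 630 nm. Chicken
#' breast has the highest overall reflectance (pale meat), beef and
#' duck are darker and mutually similar.
#'
#' @param class_name one of `"chicken"`, `"beef"`, `"duck"` (other
#'   names are allowed for custom classes).
#' @param baseline_level reflectance at 600 nm, in `(0, 1]`.
#' @param baseline_slope baseline slope, reflectance per nm.
#' @param bands data.frame with columns `center_nm`, `depth`,
#'   `width_nm` (Gaussian sigma) describing absorption dips. All
#'   centres must lie in `[400, 800]`, depths must be nonnegative.
#' @param within_class_sd multiplicative variability fraction applied
#'   to the baseline amplitude and band depths of each sample.
#' @return An object of class `meat_class_model`.
#' @export
meat_class_model <- function(class_name, baseline_level, baseline_slope,
                             bands, within_class_sd = 0.05) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center_nm", "depth", "width_nm") %in% names(bands)))
  if (any(bands$center_nm < 400 | bands$center_nm > 800)) {
    stop("band centers must lie within [400, 800] nm")
  }
  if (any(bands$depth < 0)) stop("band depths must be >= 0")
  if (any(bands$width_nm <= 0)) stop("band widths must be > 0")
  if (baseline_level <= 0 || baseline_level > 1) {
    stop("baseline_level must be in (0, 1]")
  }
  structure(
    list(class_name = as.character(class_name),
         baseline_level = baseline_level,
         baseline_slope = baseline_slope,
         bands = bands,
         within_class_sd = within_class_sd),
    class = "meat_class_model")
}

#' Default species models
#'
#' Default chicken/beef/duck models. Depths and baselines are fixed so
#' that chicken is clearly the most reflective class while beef and
#' duck have similar dark-red baselines separated mainly by the 630 nm
#' beef band and the strength of the 540/575 nm doublet.
#'
#' @param within_class_sd multiplicative within-class variability.
#' @return Named list of three [meat_class_model()] objects
#'   (alphabetical: beef, chicken, duck).
#' @export
default_meat_models <- function(within_class_sd = 0.05) {
  band <- function(c, d, w) data.frame(center_nm = c, depth = d, width_nm = w)
  list(
    beef = meat_class_model(
      "beef", baseline_level = 0.36, baseline_slope = 4.0e-4,
      bands = rbind(band(420, 0.20, 11), band(540, 0.100, 8),
                    band(575, 0.090, 8), band(630, 0.035, 9)),
      within_class_sd = within_class_sd),
    chicken = meat_class_model(
      "chicken", baseline_level = 0.46, baseline_slope = 3.0e-4,
      bands = rbind(band(420, 0.16, 11), band(540, 0.070, 8),
                    band(575, 0.060, 8)),
      within_class_sd = within_class_sd),
    duck = meat_class_model(
      "duck", baseline_level = 0.30, baseline_slope = 3.5e-4,
      bands = rbind(band(420, 0.19, 11), band(540, 0.110, 8),
                    band(575, 0.100, 8)),
      within_class_sd = within_class_sd)
  )
}

#' Dense latent wavelength grid
#'
#' 0.5 nm grid over 290-821 nm, wide enough to support slit convolution
#' for both a 300-800 nm benchtop spectrometer and a 400-800 nm imager
#' including a few nm of wavelength-calibration error.
#'
#' @return Numeric wavelength vector.
#' @export
latent_grid <- function() seq(290, 821, by = 0.5)

#' Generate latent (instrument-free) spectra for one class
#'
#' Draws `n` reflectance spectra from a class model on a dense grid.
#' Each sample gets a multiplicative amplitude factor and per-band
#' depth jitter, both `Normal(1, within_class_sd)`; results are clipped
#' to `[0, 1]`.
#'
#' @param class_model a [meat_class_model()].
#' @param n number of samples.
#' @param dense_grid wavelength vector covering at least `[400, 800]`
#'   at 1 nm spacing or finer; defaults to [latent_grid()].
#' @param seed integer seed; same seed, same model and same `n`
#'   reproduce the output exactly.
#' @return A [spectrum_set()] with `n` rows labelled by the class name.
#' @export
generate_latent_spectra <- function(class_model, n, dense_grid = latent_grid(),
                                    seed = 1L) {
  stopifnot(inherits(class_model, "meat_class_model"), n >= 1)
  if (min(dense_grid) > 400 || max(dense_grid) < 800 ||
      max(diff(dense_grid)) > 1 + 1e-12) {
    stop("dense_grid must cover [400, 800] nm at <= 1 nm spacing")
  }
  if (any(class_model$bands$center_nm < min(dense_grid)) ||
      any(class_model$bands$center_nm > max(dense_grid))) {
    stop("band center outside dense_grid")
  }
  set.seed(as.integer(seed))
  base <- class_model$baseline_level +
    class_model$baseline_slope * (dense_grid - 600)
  nb <- nrow(class_model$bands)
  sdv <- class_model$within_class_sd
  amp <- pmax(0.2, stats::rnorm(n, 1, sdv))
  depth_jit <- matrix(pmax(0, stats::rnorm(n * nb, 1, sdv)), n, nb)
  # precompute unit band profiles: one column per latent wavelength
  profiles <- vapply(seq_len(nb), function(b) {
    exp(-0.5 * ((dense_grid - class_model$bands$center_nm[b]) /
                  class_model$bands$width_nm[b])^2)
  }, numeric(length(dense_grid)))
  depths <- depth_jit * rep(class_model$bands$depth, each = n)
  spectra <- amp %o% base - depths %*% t(profiles)
  spectra[spectra < 0] <- 0
  spectra[spectra > 1] <- 1
  spectrum_set(dense_grid, spectra,
               labels = rep(class_model$class_name, n))
}

#' Instrument response models
#'
#' Describes how an instrument observes a latent spectrum: Gaussian
#' slit convolution at a stated FWHM, sampling on the instrument's
#' wavelength grid (offset by a wavelength-calibration error), a
#' multiplicative gain (scalar, optionally modulated by a smooth
#' relative spectral-response curve), an additive reflectance offset,
#' and additive Gaussian noise.
#'
#' @param name instrument name, conventionally `"master"` or `"slave"`.
#' @param grid_nm strictly increasing wavelength grid within
#'   `[300, 800]` nm.
#' @param fwhm_nm Gaussian slit full width at half maximum, > 0.
#' @param gain scalar multiplicative gain.
#' @param response optional function of wavelength giving the relative
#'   spectral response (unitless, around 1); `NULL` means flat.
#' @param offset additive reflectance bias.
#' @param wavelength_shift_nm wavelength-calibration error: the
#'   instrument reports band centre `x` while actually sampling
#'   `x + shift`.
#' @param noise_sd additive Gaussian noise standard deviation, >= 0.
#' @param seed optional integer; when set, noise is drawn from this
#'   seed so repeated observation is reproducible without an external
#'   seed.
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(name, grid_nm, fwhm_nm, gain = 1,
                             response = NULL, offset = 0,
                             wavelength_shift_nm = 0, noise_sd = 0,
                             seed = NULL) {
  grid_nm <- as.numeric(grid_nm)
  if (any(diff(grid_nm) <= 0)) stop("grid_nm must be strictly increasing")
  if (min(grid_nm) < 300 || max(grid_nm) > 800) {
    stop("grid_nm must lie within [300, 800] nm")
  }
  stopifnot(fwhm_nm > 0, noise_sd >= 0)
  structure(
    list(name = name, grid_nm = grid_nm, fwhm_nm = fwhm_nm, gain = gain,
         response = response, offset = offset,
         wavelength_shift_nm = wavelength_shift_nm,
         noise_sd = noise_sd, seed = seed),
    class = "instrument_model")
}

#' @describeIn instrument_model Default master: benchtop spectrometer,
#'   300-800 nm in 386 bands (1.3 nm spacing), 1.3 nm FWHM, ideal
#'   radiometry, low noise.
#' @export
master_instrument <- function(noise_sd = 0.002) {
  instrument_model("master",
                   grid_nm = seq(300, 800, length.out = 386L),
                   fwhm_nm = 1.3, gain = 1, offset = 0,
                   wavelength_shift_nm = 0, noise_sd = noise_sd)
}

#' @describeIn instrument_model Default slave: portable push-broom
#'   imager, 400-800 nm at 5 nm steps, 5 nm FWHM, overall gain 1.15
#'   modulated by a smooth relative spectral-response curve (reduced
#'   response near 415 nm and 630 nm and a broad ripple across the
#'   range), offset 0.03, wavelength-calibration error 3 nm.
#' @export
slave_instrument <- function(noise_sd = 0.004) {
  instrument_model("slave", grid_nm = seq(400, 800, by = 5),
                   fwhm_nm = 5, gain = 1.15,
                   response = slave_response_curve,
                   offset = 0.03, wavelength_shift_nm = 3,
                   noise_sd = noise_sd)
}

#' Default slave relative spectral-response curve
#'
#' Smooth unit-scale modulation of the slave gain: a broad ripple from
#' grating/detector efficiency plus localized response loss near
#' 415 nm and 630 nm, the regions where portable imagers in this range
#' deviate most from benchtop references.
#'
#' @param wl wavelength in nm.
#' @return Relative response values around 1.
#' @export
slave_response_curve <- function(wl) {
  1 + 0.15 * cos(2 * pi * (wl - 400) / 400) -
    0.06 * exp(-0.5 * ((wl - 415) / 15)^2) -
    0.05 * exp(-0.5 * ((wl - 630) / 25)^2)
}

#' Observe latent spectra through an instrument
#'
#' Convolves each latent spectrum with a Gaussian slit of the stated
#' FWHM while sampling at the instrument's grid shifted by its
#' wavelength-calibration error, then applies gain/response and offset
#' and adds Gaussian noise. Convolution and sampling are realized as a
#' single row-normalized Gaussian weight matrix, so a constant
#' spectrum maps to `gain * constant + offset` exactly.
#'
#' @param latent a [spectrum_set()] on a dense grid (finer than
#'   `fwhm_nm`).
#' @param instrument an [instrument_model()].
#' @param seed optional integer seed for the noise draw; falls back to
#'   the instrument's own `seed`, then to the current RNG state.
#' @return A [spectrum_set()] on the instrument's grid.
#' @export
apply_instrument <- function(latent, instrument, seed = NULL) {
  stopifnot(inherits(latent, "spectrum_set"),
            inherits(instrument, "instrument_model"))
  src <- latent$wavelengths_nm
  centers <- instrument$grid_nm + instrument$wavelength_shift_nm
  pad <- 3 * instrument$fwhm_nm / 2.3548200450309493
  if (min(centers) - pad < min(src) || max(centers) + pad > max(src)) {
    stop(sprintf(
      paste0("instrument '%s' needs latent coverage of [%.1f, %.1f] nm ",
             "but the latent grid spans [%.1f, %.1f] nm"),
      instrument$name, min(centers) - pad, max(centers) + pad,
      min(src), max(src)))
  }
  sigma <- max(instrument$fwhm_nm / 2.3548200450309493, 1e-9)
  # weight matrix: latent bands x output bands
  W <- exp(-0.5 * (outer(src, centers, "-") / sigma)^2)
  W <- sweep(W, 2L, colSums(W), "/")
  out <- latent$spectra %*% W
  g <- instrument$gain
  if (!is.null(instrument$response)) {
    g <- g * instrument$response(instrument$grid_nm)
  }
  out <- sweep(out, 2L, rep_len(g, ncol(out)), "*") + instrument$offset
  if (instrument$noise_sd > 0) {
    s <- if (!is.null(seed)) seed else instrument$seed
    if (!is.null(s)) set.seed(as.integer(s))
    out <- out + matrix(stats::rnorm(length(out), 0, instrument$noise_sd),
                        nrow(out), ncol(out))
  }
  spectrum_set(instrument$grid_nm, out, labels = latent$labels,
               sample_ids = latent$sample_ids)
}

#' Generate row-aligned master/slave spectrum sets
#'
#' Simulates the dual-measurement design used for calibration transfer:
#' the same physical samples observed by both instruments. Latent
#' spectra are drawn per class, then passed through master and slave
#' models with independent noise draws (seeds derived from `seed`
#' unless an instrument carries its own seed).
#'
#' @param class_models list of [meat_class_model()] objects.
#' @param n_per_class samples per class (default 48, i.e. 144 samples
#'   for the three default classes).
#' @param master,slave [instrument_model()] objects.
#' @param seed integer seed.
#' @return List with elements `master` and `slave`, two row-aligned
#'   [spectrum_set()]s with identical labels and sample ids.
#' @export
generate_paired_sets <- function(class_models = default_meat_models(),
                                 n_per_class = 48,
                                 master = master_instrument(),
                                 slave = slave_instrument(),
                                 seed = 1L) {
  seed <- as.integer(seed)
  latents <- lapply(seq_along(class_models), function(i) {
    generate_latent_spectra(class_models[[i]], n_per_class, seed = seed + i)
  })
  wl <- latents[[1L]]$wavelengths_nm
  all_spec <- do.call(rbind, lapply(latents, `[[`, "spectra"))
  all_lab <- unlist(lapply(latents, `[[`, "labels"))
  latent <- spectrum_set(wl, all_spec, labels = all_lab)
  list(
    master = apply_instrument(latent, master,
                              seed = if (is.null(master$seed)) seed + 1001L),
    slave = apply_instrument(latent, slave,
                             seed = if (is.null(slave$seed)) seed + 2002L)
  )
}
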