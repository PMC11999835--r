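#' Spectrum collections
#'
#' A `spectrum_set` holds a samples-by-wavelengths reflectance matrix
#' together with its wavelength axis, optional class labels and sample
#' identifiers. It is the exchange container used by every stage of the
#' pipeline: simulation, partitioning, calibration transfer and
#' classification all consume and return `spectrum_set` objects.
#'
#' @param wavelengths_nm strictly increasing numeric vector of band
#'   centres in nanometres.
#' @param spectra numeric matrix, one row per sample, one column per
#'   wavelength; reflectance values (unitless, nominally in `[0, 1]`).
#' @param labels optional character/factor vector of class labels, one
#'   per sample.
#' @param sample_ids optional character vector of sample identifiers;
#'   generated as `s0001, s0002, ...` when absent.
#'
#' @return An object of class `spectrum_set`: a list with elements
#'   `wavelengths_nm`, `spectra`, `labels`, `sample_ids`.
#' @export
spectrum_set <- function(wavelengths_nm, spectra, labels = NULL,
                         sample_ids = NULL) {
  spectra <- as.matrix(spectra)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (ncol(spectra) != length(wavelengths_nm)) {
    stop("spectra has ", ncol(spectra), " columns but ",
         length(wavelengths_nm), " wavelengths were supplied")
  }
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths_nm must be strictly increasing")
  }
  if (!all(is.finite(spectra))) stop("spectra must be finite")
  m <- nrow(spectra)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != m) stop("labels length must equal sample count")
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%04d", seq_len(m))
  } else {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) != m) stop("sample_ids length must equal sample count")
  }
  dimnames(spectra) <- NULL
  structure(
    list(wavelengths_nm = wavelengths_nm, spectra = spectra,
         labels = labels, sample_ids = sample_ids),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$spectra), " spectra x ",
      length(x$wavelengths_nm), " bands (",
      min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm)\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$spectra)

#' Subset a spectrum set by sample
#'
#' @param x a [spectrum_set()].
#' @param i integer or logical index over samples.
#' @return A `spectrum_set` with the selected rows.
#' @export
subset_samples <- function(x, i) {
  stopifnot(inherits(x, "spectrum_set"))
  spectrum_set(x$wavelengths_nm, x$spectra[i, , drop = FALSE],
               labels = if (!is.null(x$labels)) x$labels[i],
               sample_ids = x$sample_ids[i])
}

#' Resample spectra onto a new wavelength grid
#'
#' Linear interpolation of each spectrum onto `target_grid`. Used to
#' place master and slave measurements on a common grid (the coarser
#' instrument's axis restricted to the shared range) before any transfer
#' is estimated. Extrapolation is refused: the target grid must lie
#' inside the span of the source grid.
#'
#' @param x a [spectrum_set()].
#' @param target_grid strictly increasing numeric wavelength vector.
#' @return A `spectrum_set` on `target_grid` with labels and ids kept.
#' @export
resample_to_grid <- function(x, target_grid) {
  stopifnot(inherits(x, "spectrum_set"))
  target_grid <- as.numeric(target_grid)
  src <- x$wavelengths_nm
  if (min(target_grid) < min(src) || max(target_grid) > max(src)) {
    stop(sprintf(
      "target grid [%g, %g] nm extends beyond source grid [%g, %g] nm",
      min(target_grid), max(target_grid), min(src), max(src)))
  }
  out <- t(apply(x$spectra, 1L, function(row) {
    stats::approx(src, row, xout = target_grid, method = "linear")$y
  }))
  if (length(target_grid) == 1L) out <- matrix(out, ncol = 1L)
  spectrum_set(target_grid, out, labels = x$labels, sample_ids = x$sample_ids)
}

#' Write / read a spectrum set as CSV
#'
#' Layout: header row `sample_id, label`, then one column per wavelength
#' named by its value in nm; one row per sample. Numbers are written
#' with 15 significant digits so a round trip is lossless to well below
#' 1e-9.
#'
#' @param x a [spectrum_set()].
#' @param path file path.
#' @return `write_spectra_csv` returns `path` invisibly;
#'   `read_spectra_csv` returns a `spectrum_set`.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectrum_set"))
  labels <- if (is.null(x$labels)) rep("", nrow(x$spectra)) else x$labels
  header <- c("sample_id", "label", format(x$wavelengths_nm, digits = 15,
                                           trim = TRUE, scientific = FALSE))
  body <- cbind(x$sample_ids, labels,
                matrix(format(x$spectra, digits = 15, trim = TRUE),
                       nrow = nrow(x$spectra)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("sample_id", "label"))) {
    stop("not a spectrum-set CSV: expected columns sample_id, label, <wavelengths>")
  }
  wl <- as.numeric(names(df)[-(1:2)])
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(mat) <- "double"
  labels <- df$label
  if (all(labels == "")) labels <- NULL
  spectrum_set(wl, mat, labels = labels, sample_ids = df$sample_id)
}
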