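#' Hyperspectral cubes
#'
#' A `hypercube` is a rows x cols x bands reflectance array with its
#' wavelength axis and, for simulated data, a ground-truth class map
#' and the per-class area fractions it implies.
#'
#' @param data numeric array `rows x cols x bands`.
#' @param wavelengths_nm length-`bands` wavelength vector.
#' @param truth_map optional `rows x cols` integer matrix of class ids
#'   (indices into `class_order`).
#' @param class_order optional character vector naming the classes the
#'   truth ids refer to.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths_nm, truth_map = NULL,
                      class_order = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[3L] != length(wavelengths_nm)) {
    stop("third array dimension must match wavelength count")
  }
  truth_proportions <- NULL
  if (!is.null(truth_map)) {
    stopifnot(all(dim(truth_map) == dim(data)[1:2]))
    counts <- tabulate(truth_map, nbins = max(truth_map))
    truth_proportions <- counts / sum(counts)
    if (!is.null(class_order)) names(truth_proportions) <- class_order
  }
  structure(
    list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
         truth_map = truth_map, truth_proportions = truth_proportions,
         class_order = class_order),
    class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat("<hypercube> ", d[1], " x ", d[2], " pixels x ", d[3], " bands (",
      min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm)\n", sep = "")
  if (!is.null(x$truth_proportions)) {
    cat("  truth proportions:",
        paste(sprintf("%s=%.3f", names(x$truth_proportions),
                      x$truth_proportions), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten cube pixels to a spectrum set
#'
#' @param cube a [hypercube()].
#' @return A [spectrum_set()] with `rows * cols` samples in column-major
#'   pixel order.
#' @export
cube_to_spectra <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  spectrum_set(cube$wavelengths_nm,
               matrix(cube$data, nrow = d[1] * d[2], ncol = d[3]))
}

#' Simulate a spliced-meat hypercube
#'
#' Builds an image of side-by-side meat pieces: pixel counts per class
#' follow the supplied ratio (normalized by its sum, rounded by largest
#' remainder) and regions are laid out as contiguous vertical stripes
#' filled in column-major order, so a non-divisible ratio splits only
#' the boundary column. Each pixel's spectrum is drawn from its class
#' model and observed through the slave instrument.
#'
#' @param class_models named list of [meat_class_model()] objects; the
#'   names, in list order, define the truth-map class ids.
#' @param proportions numeric ratio per class, e.g. `c(2, 1, 1)`;
#'   normalized internally.
#' @param shape `c(rows, cols)`, each at least 16.
#' @param slave [instrument_model()] used to observe the pixels.
#' @param layout `"stripes"` (default) or `"checkerboard"` (stress
#'   test: same pixel counts assigned in a rows-alternating pattern).
#' @param seed integer seed.
#' @return A [hypercube()] with `truth_map` and `truth_proportions`.
#' @export
generate_spliced_cube <- function(class_models = default_meat_models(),
                                  proportions = c(1, 1, 1),
                                  shape = c(60, 60),
                                  slave = slave_instrument(),
                                  layout = c("stripes", "checkerboard"),
                                  seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(length(proportions) == length(class_models),
            all(proportions > 0), all(shape >= 16))
  seed <- as.integer(seed)
  rows <- shape[1]; cols <- shape[2]
  npix <- rows * cols
  frac <- proportions / sum(proportions)
  counts <- largest_remainder_counts(frac, npix)
  if (any(counts == 0)) stop("region too small to realize a class")
  k <- length(class_models)
  truth <- integer(npix)
  if (layout == "stripes") {
    # column-major fill: contiguous vertical bands, ragged boundary column
    truth <- rep(seq_len(k), times = counts)
  } else {
    ord <- order(rep(seq_len(cols), each = rows) %% k,
                 seq_len(npix))   # interleave columns across classes
    truth[ord] <- rep(seq_len(k), times = counts)
  }
  truth_map <- matrix(truth, rows, cols)
  # latent spectra per pixel, then slave observation
  grid <- latent_grid()
  spectra <- matrix(0, npix, length(grid))
  labels <- character(npix)
  for (ci in seq_len(k)) {
    idx <- which(truth == ci)
    lat <- generate_latent_spectra(class_models[[ci]], length(idx),
                                   dense_grid = grid, seed = seed + 10L * ci)
    spectra[idx, ] <- lat$spectra
    labels[idx] <- class_models[[ci]]$class_name
  }
  latent <- spectrum_set(grid, spectra, labels = labels)
  obs <- apply_instrument(latent, slave,
                          seed = if (is.null(slave$seed)) seed + 5005L)
  hypercube(array(obs$spectra, dim = c(rows, cols, ncol(obs$spectra))),
            obs$wavelengths_nm, truth_map = truth_map,
            class_order = unname(vapply(class_models, `[[`, "",
                                        "class_name")))
}

# integer apportionment of n among fractions by largest remainder
largest_remainder_counts <- function(frac, n) {
  raw <- frac * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Write / read a hypercube as ENVI header + raw binary
#'
#' Writes `path` (raw binary, BIL interleave, little-endian float32)
#' and `path.hdr` (text header with the `wavelength` field populated).
#' The truth map, when present, is written alongside as
#' `path_truth` / `path_truth.hdr` (single-band 16-bit integer image).
#'
#' @param cube a [hypercube()].
#' @param path output path for the raw binary (header gets `.hdr`).
#' @return `write_envi` returns `path` invisibly; `read_envi` returns
#'   a [hypercube()].
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {hsitransfer hypercube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bil",
    "byte order = 0",
    paste0("wavelength = {",
           paste(format(cube$wavelengths_nm, trim = TRUE), collapse = ", "),
           "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  # BIL: per line, per band, all samples
  vals <- aperm(cube$data, c(2L, 3L, 1L))  # samples, bands, lines
  writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  close(con)
  if (!is.null(cube$truth_map)) {
    tpath <- paste0(path, "_truth")
    thdr <- c("ENVI", paste0("samples = ", d[2]), paste0("lines = ", d[1]),
              "bands = 1", "header offset = 0", "file type = ENVI Standard",
              "data type = 2", "interleave = bil", "byte order = 0",
              if (!is.null(cube$class_order))
                paste0("class names = {",
                       paste(cube$class_order, collapse = ", "), "}"))
    writeLines(thdr, paste0(tpath, ".hdr"))
    con <- file(tpath, "wb")
    writeBin(as.integer(t(cube$truth_map)), con, size = 2L, endian = "little")
    close(con)
  }
  invisible(path)
}

#' @rdname write_envi
#' @export
read_envi <- function(path) {
  hdr <- parse_envi_header(paste0(path, ".hdr"))
  rows <- hdr$lines; cols <- hdr$samples; bands <- hdr$bands
  stopifnot(hdr$interleave == "bil", hdr$`data type` %in% c(2, 4))
  n <- rows * cols * bands
  con <- file(path, "rb")
  if (hdr$`data type` == 4) {
    vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  } else {
    vals <- readBin(con, "integer", n = n, size = 2L, endian = "little")
  }
  close(con)
  arr <- aperm(array(vals, dim = c(cols, bands, rows)), c(3L, 1L, 2L))
  truth <- NULL
  class_order <- NULL
  tpath <- paste0(path, "_truth")
  if (file.exists(tpath)) {
    thdr <- parse_envi_header(paste0(tpath, ".hdr"))
    con <- file(tpath, "rb")
    tv <- readBin(con, "integer", n = rows * cols, size = 2L,
                  endian = "little")
    close(con)
    truth <- t(matrix(tv, cols, rows))
    if (!is.null(thdr$`class names`)) {
      class_order <- trimws(strsplit(thdr$`class names`, ",")[[1]])
    }
  }
  wl <- as.numeric(trimws(strsplit(hdr$wavelength, ",")[[1]]))
  hypercube(arr, wl, truth_map = truth, class_order = class_order)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path)
  txt <- paste(lines[-1L], collapse = "\n")
  out <- list()
  # join brace-delimited values, then split on newlines
  txt <- gsub("\\{([^}]*)\\}", "\\1", txt)
  for (ln in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", ln)) next
    key <- trimws(sub("=.*", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- val
  }
  for (k in c("samples", "lines", "bands", "data type")) {
    if (!is.null(out[[k]])) out[[k]] <- as.integer(out[[k]])
  }
  out
}
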