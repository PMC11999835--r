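#' Pixel-wise classification of a hypercube
#'
#' Flattens the cube to pixel spectra, optionally maps them into the
#' master space with a calibration transfer, predicts each pixel's
#' species with a master-trained classifier and reshapes the result
#' into a label map.
#'
#' @param cube a [hypercube()].
#' @param classifier a classifier with a `predict` method returning
#'   `$labels` ([fit_plsda()] or [fit_svm()] results).
#' @param transfer optional fitted transfer model (`NULL` = none).
#' @param grid optional wavelength grid the classifier/transfer expect;
#'   the cube is resampled to it when its own grid differs.
#' @param median_filter optional odd integer; when given, a post-hoc
#'   spatial median filter of that window size is applied to the label
#'   map (off by default: per-pixel results are reported raw).
#' @return An object of class `label_map`: list with `labels`
#'   (rows x cols integer matrix of class ids), `class_order` and
#'   `palette`.
#' @export
classify_cube <- function(cube, classifier, transfer = NULL, grid = NULL,
                          median_filter = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  px <- cube_to_spectra(cube)
  if (!is.null(grid) && (length(grid) != length(cube$wavelengths_nm) ||
                         any(grid != cube$wavelengths_nm))) {
    px <- resample_to_grid(px, grid)
  }
  X <- transfer_spectra(transfer, px$spectra)
  labels <- predict(classifier, X)$labels
  class_order <- classifier$class_order
  ids <- match(labels, class_order)
  d <- dim(cube$data)
  lab <- matrix(ids, d[1], d[2])
  if (!is.null(median_filter)) lab <- median_filter_map(lab, median_filter)
  structure(
    list(labels = lab, class_order = class_order,
         palette = default_palette(class_order)),
    class = "label_map")
}

median_filter_map <- function(lab, k) {
  stopifnot(k %% 2 == 1)
  h <- (k - 1L) / 2L
  out <- lab
  nr <- nrow(lab); nc <- ncol(lab)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      rr <- max(1, r - h):min(nr, r + h)
      cs <- max(1, cc - h):min(nc, cc + h)
      tb <- tabulate(lab[rr, cs])
      out[r, cc] <- which.max(tb)
    }
  }
  out
}

#' Default class palette
#'
#' Chicken yellow, beef blue, duck green; other class names get
#' distinct fallback colours.
#'
#' @param class_order character vector of class names.
#' @return matrix classes x 3 of RGB values in `[0, 1]`, rownames =
#'   classes.
#' @export
default_palette <- function(class_order) {
  known <- rbind(chicken = c(1, 1, 0), beef = c(0, 0, 1), duck = c(0, 1, 0))
  extras <- rbind(c(1, 0, 0), c(1, 0, 1), c(0, 1, 1), c(0.5, 0.5, 0.5))
  pal <- matrix(0, length(class_order), 3,
                dimnames = list(class_order, c("r", "g", "b")))
  e <- 1L
  for (cl in class_order) {
    if (cl %in% rownames(known)) {
      pal[cl, ] <- known[cl, ]
    } else {
      pal[cl, ] <- extras[((e - 1L) %% nrow(extras)) + 1L, ]
      e <- e + 1L
    }
  }
  pal
}

#' @export
print.label_map <- function(x, ...) {
  cnt <- tabulate(x$labels, nbins = length(x$class_order))
  cat("<label_map>", nrow(x$labels), "x", ncol(x$labels), "pixels;",
      paste(sprintf("%s=%d", x$class_order, cnt), collapse = ", "), "\n")
  invisible(x)
}

#' Predicted and true class proportions of a label map
#'
#' Class pixel counts divided by total pixels; when the cube carries a
#' ground-truth map, the per-class absolute deviation from the truth
#' fractions is included — the quantity a splicing experiment checks
#' against the known composition.
#'
#' @param map a [classify_cube()] result.
#' @param truth optional [hypercube()] carrying `truth_proportions`
#'   (classes assumed in `map$class_order`).
#' @return An object of class `proportion_report`: data.frame with
#'   columns `class`, `predicted`, and when truth is available `truth`
#'   and `abs_deviation`.
#' @export
proportions <- function(map, truth = NULL) {
  stopifnot(inherits(map, "label_map"))
  k <- length(map$class_order)
  cnt <- tabulate(map$labels, nbins = k)
  out <- data.frame(class = map$class_order, predicted = cnt / sum(cnt))
  if (!is.null(truth) && !is.null(truth$truth_proportions)) {
    tp <- truth$truth_proportions
    if (!is.null(names(tp))) tp <- tp[map$class_order]
    out$truth <- as.numeric(tp)
    out$abs_deviation <- abs(out$predicted - out$truth)
  }
  class(out) <- c("proportion_report", class(out))
  out
}

#' Render a label map to an indexed-colour PNG
#'
#' Writes the map with its palette and a plain-text legend sidecar
#' (`<out>.legend.txt`) mapping each class to its RGB colour. Colours
#' are exact 8-bit values, so labels are recoverable from the PNG via
#' the palette inverse.
#'
#' @param map a [classify_cube()] result.
#' @param out_path output PNG path.
#' @return `out_path`, invisibly.
#' @export
render_map <- function(map, out_path) {
  stopifnot(inherits(map, "label_map"))
  d <- dim(map$labels)
  img <- array(0, dim = c(d[1], d[2], 3))
  for (ch in 1:3) {
    img[, , ch] <- matrix(map$palette[map$labels, ch], d[1], d[2])
  }
  png::writePNG(img, out_path)
  legend <- sprintf("%s\t%d,%d,%d", rownames(map$palette),
                    round(map$palette[, 1] * 255),
                    round(map$palette[, 2] * 255),
                    round(map$palette[, 3] * 255))
  writeLines(c("class\trgb", legend), paste0(out_path, ".legend.txt"))
  invisible(out_path)
}

#' Recover a label map from a rendered PNG
#'
#' Inverse of [render_map()]: matches each pixel's RGB value to the
#' palette.
#'
#' @param png_path path written by [render_map()].
#' @param palette RGB palette matrix with class rownames.
#' @return Integer matrix of class ids.
#' @export
read_map_png <- function(png_path, palette) {
  img <- png::readPNG(png_path)
  d <- dim(img)
  flat <- matrix(img, d[1] * d[2], d[3])[, 1:3, drop = FALSE]
  key <- apply(round(palette * 255), 1L, paste, collapse = ",")
  pix <- apply(round(flat * 255), 1L, paste, collapse = ",")
  ids <- match(pix, key)
  if (anyNA(ids)) stop("pixel colour not found in palette")
  matrix(ids, d[1], d[2])
}
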