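#' Read a raster image into a spectral image
#'
#' Reads PNG (via the png package) or TIFF (via the tiff package, if
#' installed) rasters, 8- or 16-bit, single-channel or RGB(A); an alpha
#' channel, if present, is dropped. Values arrive in `[0, 1]` as decoded by
#' the format reader and are unfolded row-major.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return a physical [spectral_image()].
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  r <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported raster format: ", ext)
  }
  if (length(dim(r)) == 3L && dim(r)[3] == 4L) r <- r[, , 1:3, drop = FALSE]
  unfold(if (is.matrix(r)) array(r, c(dim(r), 1L)) else r)
}

#' Write a spectral image (or raster array) as PNG
#'
#' @param image a physical [spectral_image()] or an `H x W (x N)` array in
#'   `[0, 1]` with 1 or 3 channels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(image, path) {
  r <- if (inherits(image, "spectral_image")) fold(image) else image
  if (length(dim(r)) == 3L && dim(r)[3] == 1L) r <- r[, , 1]
  png::writePNG(r, target = path)
  invisible(path)
}

#' Write / read a label map as a lossless grayscale PNG
#'
#' Label maps are stored as 8-bit grayscale PNGs with pixel value
#' `label - 1` (so up to 256 components), which round-trips exactly.
#'
#' @param labels `H x W` integer label matrix with values `1..M`.
#' @param path file path.
#' @return `write_label_map`: `path` invisibly; `read_label_map`: the
#'   `H x W` integer label matrix.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 256L || min(labels) < 1L) {
    stop("labels must lie in 1..256 for 8-bit storage")
  }
  png::writePNG((labels - 1L) / 255, target = path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3L) g <- g[, , 1]
  matrix(as.integer(round(g * 255)) + 1L, nrow = nrow(g))
}

#' Default digital-staining palette
#'
#' Blue, red, green for the first three components (the conventional
#' digital-staining assignment for three tissue components), extended with
#' yellow, magenta, cyan, orange and gray for larger `M`.
#'
#' @param M number of components (up to 8).
#' @return `M x 3` matrix of RGB triples in `[0, 1]`.
#' @export
default_palette <- function(M) {
  pal <- rbind(
    c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
    c(1, 0, 1), c(0, 1, 1), c(1, 0.5, 0), c(0.5, 0.5, 0.5)
  )
  if (M > nrow(pal)) stop("default palette supports at most 8 components")
  pal[seq_len(M), , drop = FALSE]
}

#' Region-colored rendering of a segmentation
#'
#' Maps each label to an RGB display colour ("region coloring" / digital
#' staining): label `m` is drawn in `palette[m, ]`. Permuting the palette
#' permutes the display colours only, never the labels.
#'
#' @param result a `segmentation_result` from [segment()], or an `H x W`
#'   integer label matrix.
#' @param palette `>= M x 3` matrix of RGB triples in `[0, 1]`
#'   (default [default_palette()]).
#' @param path optional PNG output path.
#' @return `H x W x 3` RGB array (invisibly if `path` is given).
#' @export
colorize <- function(result, palette = NULL, path = NULL) {
  labels <- if (inherits(result, "segmentation_result")) result$labels else result
  M <- max(labels)
  if (is.null(palette)) palette <- default_palette(M)
  palette <- as.matrix(palette)
  if (nrow(palette) < M) stop("palette must have at least M colours")
  out <- array(0, dim = c(nrow(labels), ncol(labels), 3L))
  for (k in 1:3) out[, , k] <- matrix(palette[labels, k], nrow(labels))
  if (!is.null(path)) {
    png::writePNG(out, target = path)
    return(invisible(out))
  }
  out
}
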