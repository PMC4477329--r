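#' Spectral image container
#'
#' A `spectral_image` holds a multichannel raster in unfolded (matrix) form:
#' an `N x P` nonnegative matrix whose rows are spectral channels and whose
#' columns are pixels, together with the spatial extent `H x W` (`P = H * W`)
#' needed to fold pixel vectors back into a raster. Physical images (camera
#' data) are constrained to `[0, 1]`; lifted images produced by the empirical
#' kernel map live in `(0, 1]` but are marked `"lifted"` so that operations
#' restricted to physical data (noise injection, colour-space conversion)
#' can refuse them.
#'
#' Pixels are linearized row-major: pixel `p` corresponds to raster row
#' `floor((p - 1) / W) + 1` and column `(p - 1) %% W + 1`. The model is purely
#' pixelwise, so any fixed order is valid; row-major is used consistently by
#' [unfold()] and [fold()].
#'
#' @param data numeric `N x P` matrix, channels by pixels, all entries finite
#'   and nonnegative (and `<= 1` when `kind = "physical"`).
#' @param height,width spatial extent; `height * width` must equal `ncol(data)`.
#' @param kind `"physical"` or `"lifted"`.
#' @return An object of class `spectral_image`.
#' @seealso [unfold()], [fold()]
#' @export
spectral_image <- function(data, height, width, kind = c("physical", "lifted")) {
  kind <- match.arg(kind)
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data))) {
    stop("spectral image data must be finite numeric values")
  }
  if (any(data < 0)) {
    stop("spectral image data must be nonnegative")
  }
  if (kind == "physical" && any(data > 1)) {
    stop("physical spectral images must have intensities in [0, 1]")
  }
  height <- as.integer(height)
  width <- as.integer(width)
  if (height < 1L || width < 1L || height * width != ncol(data)) {
    stop("height * width must equal the number of pixel columns")
  }
  structure(
    list(data = data, height = height, width = width, kind = kind),
    class = "spectral_image"
  )
}

#' @export
print.spectral_image <- function(x, ...) {
  cat(sprintf(
    "<spectral_image> %d channel(s), %d x %d pixels (%s)\n",
    nrow(x$data), x$height, x$width, x$kind
  ))
  invisible(x)
}

#' @export
dim.spectral_image <- function(x) c(nrow(x$data), x$height, x$width)

#' Number of channels / pixels of a spectral image
#' @param image a [spectral_image()].
#' @return integer scalar.
#' @export
n_channels <- function(image) nrow(image$data)

#' @rdname n_channels
#' @export
n_pixels <- function(image) ncol(image$data)

#' Unfold a raster array into a spectral image
#'
#' Converts an `H x W x N` (or `H x W`, taken as single-channel) numeric array
#' into the channels-by-pixels matrix form used throughout the package.
#' Integer-valued 8-bit data (maximum > 1, all values <= 255) are rescaled by
#' 1/255 and 16-bit data by 1/65535; arrays already in `[0, 1]` are taken
#' as-is. Pixel order is row-major (row by row); `fold(unfold(x))` restores
#' the raster bit-exactly.
#'
#' @param raster numeric array `H x W x N` or matrix `H x W`, finite values.
#' @return A physical [spectral_image()] with `N` rows and `H * W` columns.
#' @examples
#' r <- array(runif(5 * 7 * 3), dim = c(5, 7, 3))
#' img <- unfold(r)
#' stopifnot(all.equal(fold(img), r))
#' @export
unfold <- function(raster) {
  if (is.matrix(raster)) raster <- array(raster, dim = c(dim(raster), 1L))
  if (!is.array(raster) || length(dim(raster)) != 3L) {
    stop("raster must be an H x W x N array (or an H x W matrix)")
  }
  if (anyNA(raster) || any(!is.finite(raster))) {
    stop("raster contains non-finite values")
  }
  raster <- rescale_intensities(raster)
  h <- dim(raster)[1]; w <- dim(raster)[2]; n <- dim(raster)[3]
  # row-major pixel order: channel x column x row, then flatten pixels
  x <- aperm(raster, c(3L, 2L, 1L))
  dim(x) <- c(n, w * h)
  spectral_image(x, height = h, width = w, kind = "physical")
}

#' Fold a spectral image back into a raster array
#'
#' Inverse of [unfold()] (without undoing the 8/16-bit rescaling): returns an
#' `H x W x N` array in the row-major pixel order documented there.
#'
#' @param image a [spectral_image()].
#' @return numeric array `H x W x N`.
#' @export
fold <- function(image) {
  stopifnot(inherits(image, "spectral_image"))
  n <- n_channels(image)
  x <- image$data
  dim(x) <- c(n, image$width, image$height)
  aperm(x, c(3L, 2L, 1L))
}

# 8-bit / 16-bit integer-coded rasters are mapped to [0,1]; float data that
# already fits [0,1] is passed through unchanged.
rescale_intensities <- function(raster) {
  mx <- max(raster)
  if (mx <= 1) return(raster)
  if (min(raster) < 0) stop("raster intensities must be nonnegative")
  if (any(raster != round(raster))) {
    stop("raster values exceed 1 but are not integer-coded; rescale manually")
  }
  if (mx <= 255) raster / 255 else if (mx <= 65535) raster / 65535 else
    stop("integer-coded raster exceeds 16-bit range")
}

#' Fold an assignment vector into a label map
#'
#' @param labels integer vector of length `P` (one label per pixel, row-major
#'   order) or a source matrix (see [binarize_sources()]).
#' @param height,width spatial extent with `height * width = P`.
#' @return `H x W` integer matrix of labels.
#' @export
fold_labels <- function(labels, height, width) {
  if (is.matrix(labels)) labels <- sources_to_labels(labels)
  if (length(labels) != height * width) {
    stop("label vector length must equal height * width")
  }
  matrix(as.integer(labels), nrow = height, ncol = width, byrow = TRUE)
}

#' @rdname fold_labels
#' @param label_map `H x W` integer matrix.
#' @return `unfold_labels`: integer vector of length `H * W`, row-major.
#' @export
unfold_labels <- function(label_map) {
  as.integer(t(label_map))
}
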