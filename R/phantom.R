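#' The shipped five-component mixing matrix
#'
#' Returns the 3 x 5 nonnegative mixing matrix used by the default synthetic
#' phantom: five nearly parallel RGB spectral profiles with mutual coherence
#' 0.9995 and average pairwise coherence 0.9956 (to four decimals). The
#' matrix is a synthetic reconstruction, constructed once to realize those
#' coherence statistics together with the decorrelation behaviour expected
#' of such profiles under the Gaussian empirical kernel map; it is shipped
#' as a plain-text file (`extdata/synthetic_mixing_3x5.csv`).
#'
#' @return numeric 3 x 5 matrix, rows = red/green/blue, columns = components.
#' @examples
#' A <- synthetic_mixing_matrix()
#' mutual_coherence(A)   # 0.9995
#' average_coherence(A)  # 0.9956
#' @export
synthetic_mixing_matrix <- function() {
  path <- system.file("extdata", "synthetic_mixing_3x5.csv",
                      package = "kernmix", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  A <- t(as.matrix(tab))
  dimnames(A) <- list(c("red", "green", "blue"),
                      paste0("component", seq_len(ncol(A))))
  A
}

#' Ground-truth layout for the synthetic phantom
#'
#' Builds an `H x W` integer label map with `M` components. The default
#' `"shapes"` layout (five components) places two ellipses and two rectangles
#' of comparable area on a background; the `"bands"` layout splits the image
#' into `M` vertical bands of equal width and works for any `M >= 2`. The
#' segmentation model is purely spectral and pixelwise, so results do not
#' depend on the geometry — the layout only fixes the component areas.
#'
#' @param height,width image extent in pixels.
#' @param M number of components (`"shapes"` requires `M = 5`).
#' @param layout `"shapes"` or `"bands"`.
#' @return `H x W` integer matrix with labels `1..M`, every label present.
#' @export
phantom_layout <- function(height, width, M = 5L,
                           layout = c("shapes", "bands")) {
  layout <- match.arg(layout)
  M <- as.integer(M)
  if (M < 2L) stop("a phantom needs at least 2 components")
  if (layout == "shapes") {
    if (M != 5L) stop("the \"shapes\" layout is defined for M = 5")
    r <- row(matrix(0L, height, width)) / height
    c_ <- col(matrix(0L, height, width)) / width
    lab <- matrix(1L, height, width)
    in_ellipse <- function(cy, cx, ry, rx) {
      ((r - cy) / ry)^2 + ((c_ - cx) / rx)^2 <= 1
    }
    lab[in_ellipse(0.25, 0.25, 0.23, 0.23)] <- 2L
    lab[in_ellipse(0.25, 0.75, 0.23, 0.23)] <- 3L
    lab[r >= 0.53 & r <= 0.97 & c_ >= 0.03 & c_ <= 0.47] <- 4L
    lab[r >= 0.53 & r <= 0.97 & c_ >= 0.53 & c_ <= 0.97] <- 5L
  } else {
    band <- pmin(floor((col(matrix(0L, height, width)) - 1L) * M / width) + 1L, M)
    lab <- matrix(as.integer(band), height, width)
  }
  present <- tabulate(lab, nbins = M)
  if (any(present == 0L)) {
    stop("layout does not give every component at least one pixel; enlarge the image")
  }
  lab
}

#' Generate a synthetic low-contrast phantom
#'
#' Builds the benchmark image for the segmentation study: a ground-truth
#' binary/orthogonal source matrix from a geometric layout, the mixture
#' `X = A S` whose five spectral profiles are nearly parallel (the shipped
#' mixing matrix, [synthetic_mixing_matrix()]), and per-channel additive
#' white Gaussian noise at the requested SNR. All three pieces are returned
#' so experiments can close the loop against the ground truth.
#'
#' @param height,width phantom extent in pixels (default 256 x 256).
#' @param M number of components; the default 5 uses the shipped mixing
#'   matrix, other values require `mixing` to be supplied.
#' @param mixing `N x M` nonnegative mixing matrix with entries so that
#'   `A S` stays in `[0, 1]`.
#' @param snr_db per-channel SNR of the added noise in dB (`Inf` = noiseless).
#' @param seed integer seed for the noise.
#' @param layout passed to [phantom_layout()].
#' @return list with `image` (noisy physical [spectral_image()]),
#'   `sources` (binary `M x P` ground truth), `labels` (`H x W` map),
#'   `mixing` (the matrix used), `clean` (noiseless image).
#' @examples
#' ph <- make_phantom(height = 32, width = 32, snr_db = 70, seed = 1)
#' ph$image
#' @export
make_phantom <- function(height = 256L, width = 256L, M = 5L,
                         mixing = NULL, snr_db = Inf, seed = NULL,
                         layout = "shapes") {
  M <- as.integer(M)
  if (is.null(mixing)) {
    if (M != 5L) stop("supply a mixing matrix for M != 5")
    mixing <- synthetic_mixing_matrix()
  }
  mixing <- as.matrix(mixing)
  if (ncol(mixing) != M) stop("mixing must have M columns")
  if (any(mixing < 0) || any(mixing > 1)) {
    stop("mixing entries must lie in [0, 1] for a physical phantom")
  }
  lab_map <- phantom_layout(height, width, M = M,
                            layout = if (M == 5L) layout else "bands")
  labels <- unfold_labels(lab_map)
  S <- labels_to_sources(labels, M = M)
  clean <- spectral_image(mixing %*% S, height, width, kind = "physical")
  noisy <- add_awgn(clean, snr_db = snr_db, seed = seed)
  list(image = noisy, sources = S, labels = lab_map,
       mixing = mixing, clean = clean)
}
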