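#' Estimate component spectral profiles from labeled pixels
#'
#' Under the binary/orthogonal source model each pixel's spectrum equals the
#' mixing-matrix column of its (single) component, so the profile of
#' component `m` can be estimated as the mean spectrum of the pixels assigned
#' to it. On noiseless data the mean recovers the column exactly; under
#' additive noise it is the least-squares estimate, with error shrinking as
#' the component's pixel count grows.
#'
#' @param image a [spectral_image()] (physical or lifted).
#' @param labels binary `M x P` source matrix ([validate_sources()]) or an
#'   integer label vector / `H x W` label map; every component must own at
#'   least one pixel.
#' @return numeric `N x M` matrix whose column `m` is the estimated profile
#'   of component `m`.
#' @examples
#' ph <- make_phantom(height = 32, width = 32, snr_db = Inf)
#' A_hat <- estimate_profiles(ph$image, ph$sources)
#' stopifnot(all.equal(A_hat, unname(ph$mixing)))
#' @export
estimate_profiles <- function(image, labels) {
  stopifnot(inherits(image, "spectral_image"))
  if (is.matrix(labels) && nrow(labels) != image$height) {
    S <- validate_sources(labels)
    lab <- sources_to_labels(S)
    M <- nrow(S)
  } else {
    lab <- if (is.matrix(labels)) unfold_labels(labels) else as.integer(labels)
    M <- max(lab)
  }
  if (length(lab) != n_pixels(image)) {
    stop("labels must cover every pixel of the image")
  }
  if (M < 2L) stop("profile estimation requires M >= 2 components")
  counts <- tabulate(lab, nbins = M)
  if (any(counts == 0L)) {
    stop(sprintf("component(s) %s have no assigned pixels",
                 paste(which(counts == 0L), collapse = ", ")))
  }
  A <- vapply(seq_len(M), function(m) {
    rowMeans(image$data[, lab == m, drop = FALSE])
  }, numeric(n_channels(image)))
  colnames(A) <- paste0("component", seq_len(M))
  A
}
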