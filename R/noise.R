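# Run code with a local, restored RNG state so seeded operations do not
# disturb the caller's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Add per-channel white Gaussian noise at a given SNR
#'
#' Adds zero-mean Gaussian noise independently to every spectral channel,
#' calibrated per channel so that
#' \deqn{\mathrm{SNR} = 10 \log_{10}(P_{signal} / P_{noise})}
#' holds in expectation, with the channel signal power taken as the mean of
#' its squared intensities: the noise variance is
#' `mean(x^2) * 10^(-snr_db / 10)`. Noisy values are clipped back to
#' `[0, 1]`, the domain a physical detector records. `snr_db = Inf` is the
#' noiseless sentinel and returns the image unchanged.
#'
#' @param image a physical [spectral_image()].
#' @param snr_db per-channel signal-to-noise ratio in dB (finite, or `Inf`).
#' @param seed integer seed; the same seed reproduces the noise bit-exactly
#'   and the caller's RNG state is left untouched.
#' @return a physical [spectral_image()] of the same extent.
#' @examples
#' img <- make_phantom(height = 16, width = 16, snr_db = Inf)$image
#' noisy <- add_awgn(img, snr_db = 20, seed = 1)
#' @export
add_awgn <- function(image, snr_db, seed = NULL) {
  stopifnot(inherits(image, "spectral_image"))
  if (image$kind != "physical") stop("noise injection applies to physical images")
  if (is.na(snr_db)) stop("snr_db must be a number (or Inf for noiseless)")
  if (is.infinite(snr_db)) {
    if (snr_db < 0) stop("snr_db must be finite or +Inf")
    return(image)
  }
  x <- image$data
  p_sig <- rowMeans(x^2)
  sd_n <- sqrt(p_sig * 10^(-snr_db / 10))
  noise <- with_seed(seed, {
    matrix(stats::rnorm(length(x)), nrow = nrow(x)) * sd_n
  })
  y <- pmin(pmax(x + noise, 0), 1)
  spectral_image(y, image$height, image$width, kind = "physical")
}

#' Signal-to-noise power ratio implied by a dB value
#'
#' @param snr_db SNR in decibels.
#' @return the linear power ratio `10^(snr_db / 10)`; e.g. 70 dB corresponds
#'   to noise power ten million times smaller than the signal power.
#' @export
snr_power_ratio <- function(snr_db) 10^(snr_db / 10)

#' Empirical per-channel SNR between a clean and a noisy image
#'
#' @param clean,noisy physical [spectral_image()]s of identical extent.
#' @return numeric vector, one dB value per channel.
#' @export
empirical_snr <- function(clean, noisy) {
  stopifnot(
    inherits(clean, "spectral_image"), inherits(noisy, "spectral_image"),
    all(dim(clean$data) == dim(noisy$data))
  )
  d <- noisy$data - clean$data
  10 * log10(rowMeans(clean$data^2) / rowMeans(d^2))
}
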