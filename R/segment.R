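#' Unsupervised spectral segmentation of a multichannel image
#'
#' End-to-end pipeline: optionally lift the image into `D` non-physical
#' channels with the Gaussian empirical kernel map, factorize under
#' nonnegativity and per-pixel sparsity constraints, binarize the
#' coefficients to one component per pixel, and fold the assignment back to
#' a label map. Component spectral profiles are then estimated from the
#' labeled pixels and their coherence reported in the physical space and,
#' for kernel-lifted runs, in the lifted space — the before/after
#' decorrelation diagnostic that explains when segmentation is possible.
#'
#' Methods:
#' * `"nmf_l0"`, `"nmu"` — factorize the physical image directly;
#' * `"ekm-nmf_l0"`, `"ekm-nmu"` — factorize the kernel-lifted image;
#' * `"kmeans-lab"` — baseline k-means clustering in CIE L*a*b* space.
#'
#' For the factorization methods the engine identifies the components
#' (its basis fixes the label basins); the final binary assignment is then
#' made under the physical mixture model: candidate label fields from the
#' working space are transferred to the physical space via labeled-pixel
#' mean profiles and refined by alternating exact minimization there, and
#' the candidate with the lowest physical reconstruction error wins. This
#' keeps the noise-limited decision boundaries in the space where the
#' additive noise model actually holds, while the (lifted) factorization
#' contributes what only it can: identifiability of nearly parallel
#' profiles.
#'
#' @param image a physical [spectral_image()] (or `H x W x N` raster array,
#'   which is passed through [unfold()]).
#' @param M number of components (required; typical guidance for tissue
#'   images is 4 to 6).
#' @param method one of the five methods above.
#' @param sigma2 Gaussian kernel variance for EKM methods (default 0.1, the
#'   tissue-image configuration; see [sigma2_for_snr()] to tie it to a noise
#'   estimate).
#' @param dim subspace dimension `D` for EKM methods (default 50).
#' @param anchor_strategy,seed passed to [select_anchors()]; `seed` also
#'   seeds the factorization and baseline.
#' @param iterations iteration budget of the factorization engine.
#' @param downsample optional integer block size; the image is reduced by
#'   block-mean pooling before segmentation (labels are returned at the
#'   reduced size).
#' @param fit_pixels factorization engines estimate their basis on a seeded
#'   subsample of at most this many pixels; the final constrained assignment
#'   (one component per pixel, alternating exact minimization) always runs
#'   on every pixel, so the returned sources cover the full image.
#' @param ... further arguments passed to the factorization engine.
#' @return A `segmentation_result`: list with `labels` (`H x W`, values
#'   `1..M`), `sources`, `basis_original`, `coherence_original`,
#'   `basis_lifted`/`coherence_lifted` (EKM runs only, else `NULL`),
#'   `factorization` (or `NULL` for the baseline), `empty_components`
#'   (indices left unpopulated by the factorization, if any), and
#'   `provenance` (method and parameter echo).
#' @examples
#' ph <- make_phantom(height = 48, width = 48, snr_db = Inf)
#' res <- segment(ph$image, M = 5, method = "ekm-nmu",
#'                sigma2 = 0.01, dim = 20, seed = 1)
#' segmentation_accuracy(res$sources, ph$sources)
#' @export
segment <- function(image, M,
                    method = c("ekm-nmf_l0", "ekm-nmu", "nmf_l0", "nmu",
                               "kmeans-lab"),
                    sigma2 = 0.1, dim = 50L,
                    anchor_strategy = "cluster", seed = NULL,
                    iterations = 200L, downsample = NULL,
                    fit_pixels = 16384L, ...) {
  method <- match.arg(method)
  if (is.array(image) && !inherits(image, "spectral_image")) {
    image <- unfold(image)
  }
  stopifnot(inherits(image, "spectral_image"))
  if (image$kind != "physical") stop("segment() expects a physical image")
  M <- as.integer(M)
  if (M < 2L) stop("the component count M must be at least 2")
  if (!is.null(downsample)) image <- downsample_image(image, downsample)

  kmap <- NULL
  work <- image
  if (method %in% c("ekm-nmf_l0", "ekm-nmu")) {
    kmap <- select_anchors(image, D = dim, sigma2 = sigma2,
                           strategy = anchor_strategy, seed = seed)
    work <- apply_ekm(image, kmap)
  }

  fit <- NULL
  if (method == "kmeans-lab") {
    sources <- kmeans_lab(image, M, seed = seed)
  } else {
    # The analog factorization is fitted on a seeded pixel subsample (the
    # basis is what it estimates); the final constrained assignment below
    # runs on every pixel.
    P <- n_pixels(work)
    fit_idx <- if (P > fit_pixels) {
      with_seed(seed, sort(sample.int(P, fit_pixels)))
    } else {
      seq_len(P)
    }
    Xfit <- work$data[, fit_idx, drop = FALSE]
    engine <- if (grepl("nmu", method)) {
      nmu(Xfit, M = M, seed = seed, ...)
    } else {
      nmf_l0(Xfit, M = M, iterations = iterations, seed = seed, ...)
    }
    sources <- finish_assignment(work$data, image$data, engine$basis, M)
    fit <- engine
    fit$sources <- sources
  }

  labels <- fold_labels(sources, image$height, image$width)
  occupied <- tabulate(sources_to_labels(sources), nbins = M) > 0L
  basis_original <- coherence_original <- NULL
  basis_lifted <- coherence_lifted <- NULL
  if (all(occupied)) {
    basis_original <- estimate_profiles(image, sources)
    coherence_original <- coherence_stats(basis_original)
    if (!is.null(kmap)) {
      basis_lifted <- lift_basis(basis_original, kmap)
      coherence_lifted <- coherence_stats(basis_lifted)
    }
  }
  structure(
    list(labels = labels, sources = sources,
         basis_original = basis_original,
         coherence_original = coherence_original,
         basis_lifted = basis_lifted,
         coherence_lifted = coherence_lifted,
         factorization = fit,
         empty_components = which(!occupied),
         provenance = list(
           method = method, M = M,
           sigma2 = if (!is.null(kmap)) sigma2 else NULL,
           dim = if (!is.null(kmap)) as.integer(dim) else NULL,
           anchor_strategy = if (!is.null(kmap)) anchor_strategy else NULL,
           seed = seed, iterations = iterations,
           downsample = downsample,
           package_version = as.character(utils::packageVersion("kernmix"))
         )),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s, M = %d, %d x %d pixels\n",
              x$provenance$method, x$provenance$M, nrow(x$labels),
              ncol(x$labels)))
  if (!is.null(x$coherence_original)) {
    cat("  physical space: "); print(x$coherence_original)
  }
  if (!is.null(x$coherence_lifted)) {
    cat("  lifted space:   "); print(x$coherence_lifted)
  }
  if (length(x$empty_components)) {
    cat("  empty components:", paste(x$empty_components, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Baseline: k-means clustering in CIE L*a*b* space
#'
#' Converts the RGB pixels to CIE L*a*b* (sRGB primaries, D65 reference
#' white) and clusters them with seeded k-means. This is the conventional
#' colour-clustering baseline; on near-parallel spectral profiles it fails
#' for the same reason plain factorization does — the clusters are not
#' separated in any linear colour space.
#'
#' @param image a 3-channel physical [spectral_image()].
#' @param M number of clusters.
#' @param seed integer seed (k-means initialization).
#' @param nstart random k-means restarts (best of).
#' @return binary `M x P` source matrix.
#' @export
kmeans_lab <- function(image, M, seed = NULL, nstart = 5L) {
  stopifnot(inherits(image, "spectral_image"))
  if (image$kind != "physical" || n_channels(image) != 3L) {
    stop("kmeans_lab requires a 3-channel physical RGB image")
  }
  lab <- grDevices::convertColor(t(image$data), from = "sRGB", to = "Lab")
  cl <- with_seed(seed, {
    suppressWarnings(stats::kmeans(lab, centers = M, iter.max = 100L,
                                   nstart = nstart))
  })
  labels_to_sources(cl$cluster, M = M)
}

#' Coherence diagnostic from labeled pixels
#'
#' Estimates the component spectral profiles from a labeled image
#' ([estimate_profiles()]) and reports their worst-case and average pairwise
#' coherence in the physical channel space and, when a [kernel_map()] is
#' given, after lifting the profiles into the non-physical channels — the
#' decorrelation diagnostic of the kernel lift.
#'
#' @param image a physical [spectral_image()].
#' @param labels source matrix, label vector or `H x W` label map covering
#'   every component.
#' @param kmap optional [kernel_map()].
#' @return list with `original` (a `coherence_report`) and `lifted` (ditto,
#'   or `NULL` when no map is given).
#' @export
coherence_report <- function(image, labels, kmap = NULL) {
  A <- estimate_profiles(image, labels)
  out <- list(original = coherence_stats(A), lifted = NULL)
  if (!is.null(kmap)) {
    out$lifted <- coherence_stats(lift_basis(A, kmap))
  }
  out
}

# Final binary source assignment for the segmentation pipeline.
#
# The (possibly lifted) factorization identifies the components; the binary
# model then says each physical pixel equals one component profile plus
# noise, so the final assignment is made in the physical space, where the
# additive noise model actually holds and profiles are estimated as
# labeled-pixel means. Candidate label fields are produced in the working
# (lifted) space by alternating minimization under the one-per-pixel
# constraint — with unit coefficients (nearest centroid) and with analog
# amplitudes (ray projection; more robust at small kernel variances) — from
# both the engine's basis and a deterministic farthest-point basis. Each
# candidate is transferred to the physical space (component means of its
# labels) and refined by the unit-coefficient scheme there; the candidate
# with the lowest physical reconstruction error wins.
finish_assignment <- function(X_work, X_phys, engine_basis, M) {
  inits <- list(engine_basis, farthest_point_basis(X_work, M))
  best <- NULL
  for (A0 in inits) {
    for (mode in c("unit", "analog")) {
      cand <- refine_assignment(X_work, A0, mode = mode)
      lab <- max.col(t(cand$coefficients), ties.method = "first")
      counts <- tabulate(lab, nbins = M)
      if (any(counts == 0L)) next
      cent <- vapply(seq_len(M), function(m) {
        rowMeans(X_phys[, lab == m, drop = FALSE])
      }, numeric(nrow(X_phys)))
      phys <- refine_assignment(X_phys, cent, mode = "unit")
      if (is.null(best) || phys$objective < best$objective) best <- phys
    }
  }
  if (is.null(best)) {  # every candidate degenerate: refine directly
    best <- refine_assignment(X_phys, farthest_point_basis(X_phys, M))
  }
  binarize_sources(best$coefficients)
}

# Integer-factor block-mean downsampling of a physical image.
downsample_image <- function(image, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("downsample factor must be a positive integer")
  if (factor == 1L) return(image)
  h <- (image$height %/% factor) * factor
  w <- (image$width %/% factor) * factor
  if (h < factor || w < factor) stop("image too small for this downsample factor")
  r <- fold(image)[seq_len(h), seq_len(w), , drop = FALSE]
  hh <- h %/% factor; ww <- w %/% factor
  n <- dim(r)[3]
  out <- array(0, dim = c(hh, ww, n))
  for (k in seq_len(n)) {
    m <- r[, , k]
    dim(m) <- c(factor, hh, factor, ww)
    out[, , k] <- apply(m, c(2, 4), mean)
  }
  unfold(out)
}
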