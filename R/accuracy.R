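#' Permutation-matched segmentation accuracy
#'
#' Blind decomposition recovers sources only up to a permutation of the
#' component indices, so predicted and true segmentations are compared after
#' relabeling the prediction with the permutation that maximizes pixelwise
#' agreement. The optimal permutation is found by solving the linear
#' assignment problem on the `M x M` confusion matrix (Hungarian algorithm),
#' which is exact for every `M`.
#'
#' @param predicted,truth binary `M x P` source matrices (or label vectors /
#'   `H x W` label maps) over the same pixels and the same `M`.
#' @return `segmentation_accuracy`: fraction of pixels in agreement under the
#'   best permutation, in `[0, 1]`.
#' @examples
#' truth <- labels_to_sources(c(1, 1, 2, 2, 3), M = 3)
#' pred <- labels_to_sources(c(2, 2, 3, 3, 1), M = 3)  # cyclic relabeling
#' segmentation_accuracy(pred, truth)  # 1
#' @export
segmentation_accuracy <- function(predicted, truth) {
  conf <- confusion_matrix(predicted, truth)
  perm <- match_components(conf)
  sum(conf[cbind(seq_len(nrow(conf)), perm)]) / sum(conf)
}

#' @rdname segmentation_accuracy
#' @return `dice_coefficients`: per-component Dice similarity (vector of
#'   length `M`), computed under the same optimal permutation.
#' @export
dice_coefficients <- function(predicted, truth) {
  conf <- confusion_matrix(predicted, truth)
  perm <- match_components(conf)
  M <- nrow(conf)
  vapply(seq_len(M), function(m) {
    inter <- conf[m, perm[m]]
    2 * inter / (sum(conf[m, ]) + sum(conf[, perm[m]]))
  }, numeric(1))
}

# M x M confusion counts: rows = predicted component, cols = true component.
confusion_matrix <- function(predicted, truth) {
  p <- as_label_vector(predicted)
  t_ <- as_label_vector(truth)
  if (length(p) != length(t_)) stop("predicted and truth must cover the same pixels")
  M <- max(attr(p, "M"), attr(t_, "M"))
  conf <- matrix(0, M, M)
  tab <- table(factor(p, levels = seq_len(M)), factor(t_, levels = seq_len(M)))
  conf[] <- as.numeric(tab)
  conf
}

as_label_vector <- function(x) {
  if (is.matrix(x) && all(x %in% c(0, 1)) && all(colSums(x) == 1)) {
    lab <- sources_to_labels(x)
    attr(lab, "M") <- nrow(x)
  } else {
    lab <- if (is.matrix(x)) unfold_labels(x) else as.integer(x)
    attr(lab, "M") <- max(lab)
  }
  lab
}

#' Optimal component matching on a confusion matrix
#'
#' Solves the linear assignment problem maximizing the total diagonal mass:
#' returns the permutation `perm` such that predicted component `m` is
#' matched to true component `perm[m]` and `sum(conf[cbind(1:M, perm)])` is
#' maximal. Implemented as the O(M^3) augmenting-path Hungarian algorithm
#' with row/column potentials.
#'
#' @param conf nonnegative square matrix of agreement counts.
#' @return integer permutation of `1..M`.
#' @export
match_components <- function(conf) {
  conf <- as.matrix(conf)
  n <- nrow(conf)
  if (n != ncol(conf)) stop("confusion matrix must be square")
  cost <- max(conf) - conf  # maximize agreement <=> minimize cost
  u <- numeric(n)
  v <- numeric(n + 1L)          # v[1] is the virtual column 0
  p <- integer(n + 1L)          # p[j + 1] = row currently matched to column j
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j + 1L]] <- j
  perm
}
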