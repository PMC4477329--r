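# Shared fixtures, built in code at test time.

# All permutations of 1..n (used as the brute-force matching oracle).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# Brute-force permutation-matched accuracy (independent of the Hungarian
# implementation used by segmentation_accuracy()).
brute_accuracy <- function(pred, truth) {
  M <- nrow(pred)
  lp <- apply(pred, 2L, which.max)
  lt <- apply(truth, 2L, which.max)
  best <- 0
  for (perm in all_perms(M)) {
    best <- max(best, mean(unlist(perm)[lp] == lt))
  }
  best
}

# Well-separated nonnegative mixing matrix: scaled, shifted identity-like
# columns with mutual coherence far below 1.
easy_mixing <- function(N, M, seed = 1) {
  stopifnot(M <= N)
  set.seed(seed)
  A <- diag(N)[, seq_len(M), drop = FALSE] + 0.1 * matrix(runif(N * M), N, M)
  sweep(A, 2L, apply(A, 2L, max) * 1.2, "/")
}

# Random binary/orthogonal sources with every component populated.
random_sources <- function(M, P, seed = 1) {
  set.seed(seed)
  lab <- c(seq_len(M), sample.int(M, P - M, replace = TRUE))
  labels_to_sources(sample(lab), M = M)
}
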