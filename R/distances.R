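#' Hamming distance between two genotype vectors
#'
#' The number of attributes at which two samples differ in value. For
#' minor-allele-count data this is the canonical global distance of the
#' Relief family, and equals the sum of the match-mismatch difference
#' function over all attributes.
#'
#' @param x,y Genotype vectors of equal length.
#' @return Integer count in `[0, length(x)]`.
#' @seealso [taxicab_distance()], [pairwise_distances()]
#' @export
#' @examples
#' hamming_distance(c(0, 1, 2), c(1, 1, 0))  # 2
hamming_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("genotype vectors must have equal length", call. = FALSE)
  sum(x != y)
}

#' Taxicab (Manhattan) distance between two genotype vectors
#'
#' Sum of absolute differences of minor-allele counts; unlike the Hamming
#' distance it treats a 0 vs 2 mismatch as twice a 0 vs 1 mismatch.
#'
#' @inheritParams hamming_distance
#' @return Integer count in `[0, 2 * length(x)]`.
#' @export
#' @examples
#' taxicab_distance(c(0, 1, 2), c(1, 1, 0))  # 3
taxicab_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("genotype vectors must have equal length", call. = FALSE)
  sum(abs(x - y))
}

#' All pairwise sample distances
#'
#' Materialises the full `n` by `n` distance matrix used by the weighting
#' engine to find neighbors. Computed with one-hot genotype indicator
#' products rather than sample-pair loops, which keeps datasets of a few
#' thousand SNPs fast in plain R.
#'
#' @param dataset A [genotype_dataset()].
#' @param metric `"hamming"` (default) or `"taxicab"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distances <- function(dataset, metric = c("hamming", "taxicab")) {
  stopifnot_dataset(dataset)
  metric <- match.arg(metric)
  X <- dataset$genotypes
  a <- ncol(X)
  Z <- lapply(0:2, function(v) (X == v) * 1)
  if (metric == "hamming") {
    agree <- Z[[1L]] %*% t(Z[[1L]]) + Z[[2L]] %*% t(Z[[2L]]) +
      Z[[3L]] %*% t(Z[[3L]])
    D <- a - agree
  } else {
    # sum_{v,w} |v - w| * (# attrs where s_i = v, s_j = w)
    D <- Z[[1L]] %*% t(Z[[2L]]) + Z[[2L]] %*% t(Z[[1L]]) +
      Z[[2L]] %*% t(Z[[3L]]) + Z[[3L]] %*% t(Z[[2L]]) +
      2 * (Z[[1L]] %*% t(Z[[3L]]) + Z[[3L]] %*% t(Z[[1L]]))
  }
  D <- round((D + t(D)) / 2)  # exact symmetry despite float products
  diag(D) <- 0
  dimnames(D) <- NULL
  D
}

#' Mean and standard deviation of pairwise distances
#'
#' Summarises the distance distribution over the `n(n-1)/2` unordered sample
#' pairs (diagonal excluded). These are the conventional settings for the
#' center `t` and width `u` of the global neighbor weighting kernels: `t` is
#' the mean pairwise distance and `u` the population standard deviation of
#' the pairwise distances.
#'
#' @param distances Symmetric distance matrix, e.g. from
#'   [pairwise_distances()].
#' @return List with elements `t` (mean) and `u` (population SD).
#' @export
distance_stats <- function(distances) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances))
    stop("'distances' must be a square matrix", call. = FALSE)
  n <- nrow(distances)
  if (n < 2L)
    stop("at least 2 samples are required to compute distance statistics",
         call. = FALSE)
  d <- distances[upper.tri(distances)]
  m <- mean(d)
  list(t = m, u = sqrt(mean((d - m)^2)))
}
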