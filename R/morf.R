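#' Attribute weights from the modular Relief engine
#'
#' The generic weight-update engine of the modular Relief framework. For each
#' focal sample `i` in the sample set `S`, the per-sample weight update of
#' attribute `a` is
#'
#' \deqn{\Delta W_i[a] = \frac{\sum_{j \in S, j \ne i}
#'   c(s_i, s_j)\, \mathrm{diff}(a, s_i, s_j)\, f(dist_{ij})}
#'   {\sum_{j \in S, j \ne i} |f(dist_{ij})|}}
#'
#' where `c` is the class comparator (-1 for hits, +1 for misses), `diff` the
#' local difference function, and `f` the neighbor weighting kernel. The
#' final weight is the average of the per-sample updates over `S`. The
#' denominator uses the absolute kernel values so that it normalises the
#' update into `[-1, 1]` even for signed kernels; when it is zero (no
#' neighbor has non-zero kernel weight) the update is taken as 0.
#'
#' Kernel parameters left `NULL` are resolved from the data: `t` as the mean
#' pairwise distance, `u` as the standard deviation of the pairwise
#' distances. ReliefF per-sample thresholds (distance of the `k`-th nearest
#' hit and miss) are always computed from the distance matrix; ties at the
#' `k`-th neighbor are included, and if a sample has fewer than `k` hits or
#' misses all available ones are used.
#'
#' @param dataset A [genotype_dataset()].
#' @param kernel A [neighbor_kernel()].
#' @param diff_model Local difference function: `"allelic"` (default),
#'   `"dominant"`, `"recessive"` or `"heterozygote"`.
#' @param metric Global distance: `"hamming"` (default) or `"taxicab"`.
#' @param sample_set Optional integer vector of sample indices defining `S`
#'   (both the focal samples and the neighbor pool). Default: all samples.
#'
#' @return Named numeric vector of attribute weights in `[-1, 1]`.
#' @export
#' @examples
#' ds <- genotype_dataset(matrix(c(0L, 1L), ncol = 1), labels = c(0, 1))
#' morf_weights(ds, neighbor_kernel("surf_star", t = 1))  # 1: perfect predictor
morf_weights <- function(dataset, kernel,
                         diff_model = c("allelic", "dominant", "recessive",
                                        "heterozygote"),
                         metric = c("hamming", "taxicab"),
                         sample_set = NULL) {
  stopifnot_dataset(dataset)
  if (!inherits(kernel, "neighbor_kernel"))
    stop("'kernel' must be a neighbor_kernel()", call. = FALSE)
  diff_model <- match.arg(diff_model)
  metric <- match.arg(metric)
  if (!is.null(sample_set)) {
    if (!length(sample_set)) stop("empty sample set", call. = FALSE)
    dataset <- subset_samples(dataset, sample_set)
  }

  n <- n_samples(dataset)
  labels <- dataset$labels
  D <- pairwise_distances(dataset, metric = metric)
  FK <- kernel_matrix(kernel, D, labels)

  # signed contribution and absolute-value normaliser, self-pairs excluded
  C <- matrix(1, n, n)
  same <- outer(labels, labels, "==")
  C[same] <- -1
  M <- C * FK
  A <- abs(FK)
  diag(M) <- 0
  diag(A) <- 0
  denom <- rowSums(A)

  Xc <- collapse_genotypes(dataset$genotypes, diff_model)
  vals <- if (diff_model == "allelic") 0:2 else 0:1
  # sum_j M_ij * diff(a,i,j) = rowSums(M)_i - sum_j M_ij * [X_j,a == X_i,a]
  Sagree <- 0
  for (v in vals) {
    Z <- (Xc == v) * 1
    Sagree <- Sagree + Z * (M %*% Z)
  }
  dW <- (rowSums(M) - Sagree)
  ok <- denom > 0
  dW[ok, ] <- dW[ok, , drop = FALSE] / denom[ok]
  dW[!ok, ] <- 0
  w <- colMeans(dW)
  names(w) <- dataset$attribute_names
  w
}

# Materialise the n x n kernel value matrix f(dist_ij) for a kernel spec.
# Row i holds the weights sample i assigns to each neighbor j (asymmetric
# for ReliefF, whose thresholds are per focal sample). The diagonal is
# meaningless and excluded downstream.
kernel_matrix <- function(kernel, D, labels) {
  n <- nrow(D)
  if (kernel$kind == "relieff") {
    thr <- relieff_thresholds(D, labels, kernel$k)
    hitmat <- outer(labels, labels, "==")
    # thresholds are per focal sample (row); compare row-wise
    Fh <- (D <= matrix(thr$t_hit, n, n)) * 1
    Fm <- (D <= matrix(thr$t_miss, n, n)) * 1
    return(ifelse(hitmat, Fh, Fm))
  }
  st <- NULL
  t <- kernel$t
  u <- kernel$u
  if (is.null(t) || (kernel$kind == "swrf_star" && is.null(u))) {
    st <- distance_stats(D)
    if (is.null(t)) t <- st$t
    if (is.null(u)) u <- st$u
  }
  switch(kernel$kind,
         surf = kernel_surf(D, t),
         surf_star = kernel_surf_star(D, t),
         swrf_star = kernel_swrf_star(D, t, u, kernel$scale))
}

# Per-sample ReliefF thresholds: distance of the k-th nearest hit and miss
# of each sample, self excluded. With fewer than k neighbors of a category
# the largest available distance is used; a sample with no hit (or miss) at
# all gets threshold -Inf for that category, i.e. no contribution, with a
# degenerate-class warning.
relieff_thresholds <- function(D, labels, k) {
  n <- nrow(D)
  t_hit <- numeric(n)
  t_miss <- numeric(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    hit_d <- D[i, labels == labels[i]]
    hit_d <- sort(hit_d)[-1L]  # drop self (distance 0 is always first)
    miss_d <- sort(D[i, labels != labels[i]])
    if (!length(hit_d) || !length(miss_d)) warned <- TRUE
    t_hit[i] <- if (length(hit_d)) hit_d[min(k, length(hit_d))] else -Inf
    t_miss[i] <- if (length(miss_d)) miss_d[min(k, length(miss_d))] else -Inf
  }
  if (warned)
    warning("some samples have no hit or no miss; ReliefF thresholds are undefined for the absent class",
            call. = FALSE)
  list(t_hit = t_hit, t_miss = t_miss)
}
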