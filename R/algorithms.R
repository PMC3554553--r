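#' Algorithm configuration
#'
#' Collects the tunable parameters of the named Relief-family algorithms with
#' the conventional defaults: `k = 10` nearest hits and misses for ReliefF,
#' kernel center `t` at the mean pairwise distance, width `u` at the
#' pairwise-distance standard deviation, and sigmoid scale factor 4 for
#' SWRF*.
#'
#' @param name One of `"relief"`, `"relieff"`, `"surf"`, `"surf_star"`,
#'   `"swrf_star"`.
#' @param k Neighbor count for ReliefF (default 10).
#' @param scale Sigmoid width scale factor for SWRF* (default 4).
#' @param metric Global distance, `"hamming"` (default) or `"taxicab"`.
#' @param diff_model Local difference function (default `"allelic"`).
#' @param sample_fraction Fraction of samples used as focal set, in `(0, 1]`.
#'   Default 1 (every sample, deterministic). Values below 1 require `seed`.
#' @param seed Optional integer seed for the random focal-sample subset.
#' @return An object of class `algorithm_config`.
#' @export
algorithm_config <- function(name = c("relief", "relieff", "surf", "surf_star",
                                      "swrf_star"),
                             k = 10L, scale = 4,
                             metric = c("hamming", "taxicab"),
                             diff_model = c("allelic", "dominant", "recessive",
                                            "heterozygote"),
                             sample_fraction = 1, seed = NULL) {
  name <- match.arg(name)
  metric <- match.arg(metric)
  diff_model <- match.arg(diff_model)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer", call. = FALSE)
  if (scale <= 0) stop("'scale' must be positive", call. = FALSE)
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop("'sample_fraction' must be in (0, 1]", call. = FALSE)
  if (sample_fraction < 1 && is.null(seed))
    stop("a 'seed' is required when 'sample_fraction' < 1", call. = FALSE)
  structure(list(name = name, k = k, scale = scale, metric = metric,
                 diff_model = diff_model, sample_fraction = sample_fraction,
                 seed = seed),
            class = "algorithm_config")
}

#' Original Relief attribute weighting
#'
#' The classic two-neighbor algorithm: for each focal sample the single
#' nearest hit and nearest miss are located (self excluded; distance ties
#' broken by lowest sample index) and each attribute's weight is updated by
#' `diff(a, s_i, s_miss) - diff(a, s_i, s_hit)`, then averaged over the
#' focal samples, giving weights in `[-1, 1]`.
#'
#' @param dataset A [genotype_dataset()]; both classes must be present.
#' @param config An [algorithm_config()]; its `metric`, `diff_model`,
#'   `sample_fraction` and `seed` entries are honoured.
#' @return Named numeric vector of attribute weights.
#' @export
relief_original <- function(dataset, config = algorithm_config("relief")) {
  stopifnot_dataset(dataset)
  labels <- dataset$labels
  if (length(unique(labels)) < 2L)
    stop("Relief requires both classes to be present", call. = FALSE)
  D <- pairwise_distances(dataset, metric = config$metric)
  n <- n_samples(dataset)
  focal <- focal_samples(n, config)
  Xc <- collapse_genotypes(dataset$genotypes, config$diff_model)
  W <- numeric(n_attributes(dataset))
  for (i in focal) {
    d <- D[i, ]
    hit_pool <- which(labels == labels[i])
    hit_pool <- hit_pool[hit_pool != i]
    miss_pool <- which(labels != labels[i])
    m <- miss_pool[which.min(d[miss_pool])]  # which.min: lowest index on ties
    W <- W + (Xc[i, ] != Xc[m, ])
    if (length(hit_pool)) {                  # a lone-class sample has no hit
      h <- hit_pool[which.min(d[hit_pool])]
      W <- W - (Xc[i, ] != Xc[h, ])
    }
  }
  w <- W / length(focal)
  names(w) <- dataset$attribute_names
  w
}

#' Run a named Relief-family algorithm
#'
#' Dispatch front end: resolves the kernel implied by `config$name` (with
#' `t`, `u` and per-sample ReliefF thresholds derived from the dataset) and
#' delegates to [morf_weights()], or to [relief_original()] for
#' `name = "relief"`. Identical inputs and configuration yield identical
#' output.
#'
#' @inheritParams relief_original
#' @param config An [algorithm_config()].
#' @return Named numeric vector of attribute weights in `[-1, 1]`.
#' @export
#' @examples
#' ds <- genotype_dataset(matrix(c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L), ncol = 2),
#'                        labels = c(0, 0, 1, 1))
#' run_algorithm(ds, algorithm_config("swrf_star"))
run_algorithm <- function(dataset, config) {
  stopifnot_dataset(dataset)
  if (!inherits(config, "algorithm_config"))
    stop("'config' must be an algorithm_config()", call. = FALSE)
  if (config$name == "relief") return(relief_original(dataset, config))
  n <- n_samples(dataset)
  if (config$name == "relieff" && config$k > n - 1L)
    warning(sprintf("k = %d exceeds the %d available neighbors; clamping",
                    config$k, n - 1L), call. = FALSE)
  kernel <- switch(config$name,
                   relieff = neighbor_kernel("relieff", k = min(config$k, n - 1L)),
                   surf = neighbor_kernel("surf"),
                   surf_star = neighbor_kernel("surf_star"),
                   swrf_star = neighbor_kernel("swrf_star", scale = config$scale))
  morf_weights(dataset, kernel, diff_model = config$diff_model,
               metric = config$metric,
               sample_set = focal_samples(n, config))
}

# Resolve the focal sample set: all samples (deterministic default) or a
# seeded random subset of size ceiling(fraction * n).
focal_samples <- function(n, config) {
  if (config$sample_fraction >= 1) return(seq_len(n))
  m <- max(2L, as.integer(ceiling(config$sample_fraction * n)))
  rng <- local_rng(config$seed)
  sort(rng(function() sample.int(n, m)))
}

# Run 'expr_fn' under a private RNG stream seeded with 'seed', restoring the
# caller's RNG state afterwards. Returns a closure-style runner.
local_rng <- function(seed) {
  function(expr_fn) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr_fn()
  }
}
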