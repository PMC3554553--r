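#' Rank attributes by weight
#'
#' Orders attribute indices by weight, best first; ties are broken by
#' ascending attribute index so the ranking is deterministic.
#'
#' @param weights Numeric vector of attribute weights.
#' @return Integer vector of attribute indices, highest weight first.
#' @export
#' @examples
#' rank_attributes(c(0.1, 0.9, 0.5))  # 2 3 1
rank_attributes <- function(weights) {
  if (!length(weights)) stop("'weights' must be non-empty", call. = FALSE)
  order(-as.numeric(weights), seq_along(weights))
}

#' Number of attributes examined at a percentile cutoff
#'
#' A cutoff at the `p`-th percentile examines the top `(100 - p)%` of the
#' ranked attributes; the count is rounded to the nearest integer (half away
#' from zero). On 1000 SNPs the 95th percentile examines the top 50.
#'
#' @param n_attrs Total number of attributes.
#' @param percentile Cutoff percentile in `[0, 100]`.
#' @return Integer count of examined attributes (0 at the 100th percentile).
#' @export
cutoff_count <- function(n_attrs, percentile) {
  if (n_attrs < 1L) stop("'n_attrs' must be at least 1", call. = FALSE)
  if (any(percentile < 0) || any(percentile > 100))
    stop("'percentile' must lie in [0, 100]", call. = FALSE)
  as.integer(floor(n_attrs * (100 - percentile) / 100 + 0.5))
}

#' Did a run find both functional SNPs above the cutoff?
#'
#' A dataset counts as a success when both functional attributes appear
#' within the first [cutoff_count()] positions of the weight ranking.
#'
#' @param weights Numeric vector of attribute weights for one dataset.
#' @param functional_ids Indices (or names, if `weights` is named) of the two
#'   functional attributes.
#' @param percentile Cutoff percentile.
#' @return Logical flag.
#' @export
success_at_cutoff <- function(weights, functional_ids, percentile) {
  if (is.character(functional_ids)) {
    functional_ids <- match(functional_ids, names(weights))
  }
  functional_ids <- as.integer(functional_ids)
  if (anyNA(functional_ids) || any(functional_ids < 1L) ||
      any(functional_ids > length(weights)))
    stop("unknown functional attribute id", call. = FALSE)
  top <- cutoff_count(length(weights), percentile)
  ranking <- rank_attributes(weights)
  all(match(functional_ids, ranking) <= top)
}

#' Statistical power over replicate datasets
#'
#' The proportion of replicate datasets in which both functional SNPs were
#' recovered above the cutoff.
#'
#' @param success_flags Logical vector, one flag per dataset.
#' @return Proportion in `[0, 1]`.
#' @export
detection_power <- function(success_flags) {
  if (!length(success_flags))
    stop("'success_flags' must be non-empty", call. = FALSE)
  mean(as.logical(success_flags))
}

#' Power curve across percentile cutoffs
#'
#' Computes the success rate at every integer percentile cutoff (100th down
#' to 50th by default): the proportion of datasets whose two functional SNPs
#' both rank above the cutoff. The curve is non-decreasing as the cutoff
#' percentile decreases, since lowering the cutoff can only admit more
#' successes.
#'
#' @param weight_list List of weight vectors, one per dataset.
#' @param functional_list List (or single vector, recycled) of functional
#'   attribute ids per dataset.
#' @param cutoffs Integer percentiles, default `100:50`.
#' @return A data.frame of class `power_curve` with columns `cutoff` and
#'   `success_rate`, and attribute `n_datasets`.
#' @export
power_curve <- function(weight_list, functional_list, cutoffs = 100:50) {
  if (!length(weight_list)) stop("no weight vectors supplied", call. = FALSE)
  if (!is.list(functional_list))
    functional_list <- rep(list(functional_list), length(weight_list))
  if (length(functional_list) != length(weight_list))
    stop("'weight_list' and 'functional_list' must have equal length",
         call. = FALSE)
  rates <- vapply(cutoffs, function(p) {
    detection_power(mapply(success_at_cutoff, weight_list, functional_list,
                           MoreArgs = list(percentile = p)))
  }, numeric(1))
  structure(data.frame(cutoff = cutoffs, success_rate = rates),
            class = c("power_curve", "data.frame"),
            n_datasets = length(weight_list))
}

#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' Conditional exact test on the table `rbind(c(a, b), c(c, d))`: the
#' two-sided p-value sums the hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (the probability-mass convention, with a small relative
#' tolerance guarding floating-point ties).
#'
#' @param a,b,c,d Non-negative cell counts (successes/failures of two
#'   groups).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)  # 0.0079...
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(cells) == 0)
    stop("the table must contain at least one observation", call. = FALSE)
  stats::fisher.test(matrix(cells, 2L, 2L, byrow = TRUE))$p.value
}

#' Compare the success rates of two algorithms
#'
#' Builds the 2 x 2 table of successes and failures of two algorithms over
#' the same number of replicate datasets, tests the difference with
#' Fisher's exact test, and flags significance at the Bonferroni-corrected
#' level `0.05 / n_tests`.
#'
#' @param successes_a,successes_b Success counts of the two algorithms.
#' @param n Number of datasets per algorithm.
#' @param n_tests Number of tests in the family for the Bonferroni
#'   correction (default 1, i.e. no correction).
#' @return An object of class `fisher_comparison`: list with the counts, the
#'   `p_value`, `n_tests`, the corrected `alpha` and the `significant` flag.
#' @export
compare_algorithms <- function(successes_a, successes_b, n, n_tests = 1L) {
  if (n < 1L) stop("'n' must be a positive dataset count", call. = FALSE)
  if (successes_a > n || successes_b > n || successes_a < 0 || successes_b < 0)
    stop("success counts must lie in [0, n]", call. = FALSE)
  if (n_tests < 1L) stop("'n_tests' must be at least 1", call. = FALSE)
  p <- fisher_exact_2x2(successes_a, n - successes_a,
                        successes_b, n - successes_b)
  alpha <- 0.05 / n_tests
  structure(list(successes_a = successes_a, successes_b = successes_b,
                 n_a = n, n_b = n, p_value = p, n_tests = n_tests,
                 alpha = alpha, significant = p < alpha),
            class = "fisher_comparison")
}

#' @rdname compare_algorithms
#' @param x A `fisher_comparison`.
#' @param ... Unused.
#' @export
print.fisher_comparison <- function(x, ...) {
  cat(sprintf("fisher_comparison: %d/%d vs %d/%d successes, p = %.4g (alpha = %.4g, %s)\n",
              x$successes_a, x$n_a, x$successes_b, x$n_b, x$p_value, x$alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
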