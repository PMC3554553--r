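#' Class comparator
#'
#' Compares the class values of two samples: a neighbor of the same class (a
#' *hit*) contributes with sign -1, a neighbor of the opposite class (a
#' *miss*) with sign +1. Attribute mismatches to misses therefore raise an
#' attribute's weight, mismatches to hits lower it.
#'
#' @param label_i,label_j Class labels in `{0, 1}`. Vectorised.
#' @return -1 where equal, +1 where different.
#' @export
#' @examples
#' class_comparator(0, 0)  # -1 (hit)
#' class_comparator(0, 1)  # +1 (miss)
class_comparator <- function(label_i, label_j) {
  if (!all(c(label_i, label_j) %in% c(0L, 1L)))
    stop("invalid class label: labels must be 0 or 1", call. = FALSE)
  ifelse(label_i == label_j, -1, 1)
}

#' Allelic (match-mismatch) difference function
#'
#' The simple nominal difference: 0 if two genotype values agree, 1 if they
#' differ. Treats the three genotypes as unordered categories.
#'
#' @param value_i,value_j Minor-allele counts in `{0, 1, 2}`. Vectorised.
#' @return 0 or 1.
#' @export
diff_allelic <- function(value_i, value_j) {
  if (!all(c(value_i, value_j) %in% c(0L, 1L, 2L)))
    stop("invalid genotype: values must be 0, 1 or 2", call. = FALSE)
  (value_i != value_j) * 1
}

#' Genetic-model difference functions
#'
#' Collapses genotypes to carrier status under a single-locus genetic model
#' before comparing: *dominant* (carrier iff at least one minor allele),
#' *recessive* (carrier iff homozygous minor) or *heterozygote* (carrier iff
#' exactly one minor allele). Two samples differ iff their carrier statuses
#' differ.
#'
#' @inheritParams diff_allelic
#' @param model One of `"dominant"`, `"recessive"`, `"heterozygote"`.
#' @return 0 or 1.
#' @export
#' @examples
#' diff_genetic_model(1, 2, "dominant")   # 0: both carry the minor allele
#' diff_genetic_model(1, 2, "recessive")  # 1: only one is homozygous minor
diff_genetic_model <- function(value_i, value_j,
                               model = c("dominant", "recessive", "heterozygote")) {
  model <- match.arg(model)
  if (!all(c(value_i, value_j) %in% c(0L, 1L, 2L)))
    stop("invalid genotype: values must be 0, 1 or 2", call. = FALSE)
  (collapse_genotypes(value_i, model) != collapse_genotypes(value_j, model)) * 1
}

# Map raw allele counts to the value domain of a diff model. For "allelic"
# this is the identity; the genetic models yield binary carrier status.
collapse_genotypes <- function(x, diff_model) {
  switch(diff_model,
         allelic = x,
         dominant = (x >= 1) * 1L,
         recessive = (x == 2) * 1L,
         heterozygote = (x == 1) * 1L,
         stop(sprintf("unknown diff model '%s'", diff_model), call. = FALSE))
}

#' Neighbor kernel specification
#'
#' Describes the neighbor weighting function `f(dist)` that determines how
#' much each neighbor contributes to a weight update. Kernel outputs always
#' lie in `[-1, 1]`. Four kinds are supported:
#'
#' * `relieff`: per-sample step — the `k` nearest hits and `k` nearest misses
#'   of each sample get weight 1, all others 0.
#' * `surf`: global step — all neighbors within threshold `t` get weight 1.
#' * `surf_star`: signed global step — weight +1 within `t`, -1 beyond it, so
#'   distant neighbors update weights in the opposite direction.
#' * `swrf_star`: sigmoid — a smooth version of `surf_star`,
#'   `f(d) = 2 / (1 + exp(-(t - d) / (u / scale))) - 1`.
#'
#' Leaving `t` or `u` as `NULL` lets [morf_weights()] resolve them from the
#' data: `t` becomes the mean pairwise distance and `u` the standard
#' deviation of the pairwise distances.
#'
#' @param kind One of `"relieff"`, `"surf"`, `"surf_star"`, `"swrf_star"`.
#' @param t Kernel center / distance threshold, in distance units.
#' @param u Sigmoid width, in distance units (swrf_star only).
#' @param k Neighbor count (relieff only), default 10.
#' @param scale Dimensionless sigmoid width scale factor, default 4.
#' @return An object of class `neighbor_kernel`.
#' @export
neighbor_kernel <- function(kind = c("relieff", "surf", "surf_star", "swrf_star"),
                            t = NULL, u = NULL, k = 10L, scale = 4) {
  kind <- match.arg(kind)
  if (kind == "relieff") {
    k <- as.integer(k)
    if (is.na(k) || k < 1L) stop("'k' must be a positive integer", call. = FALSE)
  }
  if (kind == "swrf_star") {
    if (!is.null(u) && u <= 0) stop("'u' must be positive", call. = FALSE)
    if (scale <= 0) stop("'scale' must be positive", call. = FALSE)
  }
  if (!is.null(t) && t < 0) stop("'t' must be non-negative", call. = FALSE)
  structure(list(kind = kind, t = t, u = u, k = k, scale = scale),
            class = "neighbor_kernel")
}

#' ReliefF per-sample step kernel
#'
#' Evaluates the sample-wise ReliefF neighbor weighting: a hit counts fully
#' iff it is no farther than the `k`-th nearest hit of the focal sample, a
#' miss iff no farther than the `k`-th nearest miss.
#'
#' @param dist Distance(s) of the neighbor from the focal sample.
#' @param is_hit Logical: is the neighbor of the same class?
#' @param t_hit,t_miss Distances of the focal sample's `k`-th nearest hit and
#'   miss (the per-sample thresholds).
#' @return 0 or 1.
#' @export
kernel_relieff <- function(dist, is_hit, t_hit, t_miss) {
  if (missing(t_hit) || missing(t_miss) || is.null(t_hit) || is.null(t_miss))
    stop("ReliefF kernel needs per-sample thresholds 't_hit' and 't_miss'",
         call. = FALSE)
  ifelse(is_hit, (dist <= t_hit) * 1, (dist <= t_miss) * 1)
}

#' SURF step kernel
#'
#' All neighbors within the distance threshold `t` receive weight 1, others
#' 0. The boundary `dist == t` counts as near.
#'
#' @param dist Distance(s); must be non-negative.
#' @param t Distance threshold.
#' @return 0 or 1.
#' @export
kernel_surf <- function(dist, t) {
  if (any(dist < 0)) stop("distances must be non-negative", call. = FALSE)
  if (t < 0) stop("'t' must be non-negative", call. = FALSE)
  (dist <= t) * 1
}

#' SURF* signed step kernel
#'
#' Near neighbors (`dist <= t`) receive weight +1 and distant neighbors
#' weight -1, so distant neighbors contribute with opposite sign.
#'
#' @inheritParams kernel_surf
#' @return +1 or -1.
#' @export
kernel_surf_star <- function(dist, t) {
  if (any(dist < 0)) stop("distances must be non-negative", call. = FALSE)
  if (t < 0) stop("'t' must be non-negative", call. = FALSE)
  ifelse(dist <= t, 1, -1)
}

#' SWRF* sigmoid kernel
#'
#' Smooth, signed neighbor weighting
#' `f(d) = 2 / (1 + exp(-(t - d) / (u / scale))) - 1`:
#' close to +1 for nearby neighbors, close to -1 for distant ones, with a
#' smooth transition of width governed by `u / scale` around the center `t`.
#' Strictly decreasing in `d`; equals 0 at `d = t`; output in `(-1, 1)`.
#' The default `scale = 4` places the onset of "full" weight
#' (`|f| > 0.95`) at roughly one pairwise-distance standard deviation from
#' the mean when `t` and `u` are set from the distance distribution.
#'
#' @param dist Distance(s).
#' @param t Sigmoid center, in distance units.
#' @param u Sigmoid width, in distance units; must be positive.
#' @param scale Positive width scale factor, default 4.
#' @return Numeric in `(-1, 1)`.
#' @export
#' @examples
#' kernel_swrf_star(10, t = 10, u = 2)      # 0 at the center
#' kernel_swrf_star(8, t = 10, u = 2)       # close to +1 one width below t
kernel_swrf_star <- function(dist, t, u, scale = 4) {
  if (is.null(u) || u <= 0) stop("'u' must be positive", call. = FALSE)
  if (scale <= 0) stop("'scale' must be positive", call. = FALSE)
  2 / (1 + exp(-(t - dist) / (u / scale))) - 1
}
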