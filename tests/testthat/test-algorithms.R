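test_that("relief_original reproduces the hand-traced toy example", {
  # attribute 1 tracks the class, attribute 2 never does: each sample's
  # nearest miss differs at attribute 1 and its nearest hit at attribute 2
  ds <- genotype_dataset(matrix(c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L), ncol = 2),
                         c(0, 0, 1, 1))
  w <- relief_original(ds)
  expect_equal(unname(w), c(1, -1))
})

test_that("relief_original zeroes constant attributes and rejects one class", {
  g <- cbind(2L, matrix(sample(0:2, 18, replace = TRUE), 6, 3))
  ds <- genotype_dataset(g, rep(c(0, 1), 3))
  expect_equal(unname(relief_original(ds)[1]), 0)
  ds1 <- genotype_dataset(g, rep(0, 6))
  expect_error(relief_original(ds1), "both classes")
})

test_that("duplicated samples make every nearest hit a zero-distance twin", {
  ds <- random_dataset(8, 5, seed = 14)
  dup <- genotype_dataset(ds$genotypes[rep(1:8, each = 2), ],
                          ds$labels[rep(1:8, each = 2)])
  # the nearest hit of every sample is its duplicate at distance 0, so only
  # miss contributions remain; recompute them naively
  D <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    D[i, j] <- naive_dist(ds$genotypes[i, ], ds$genotypes[j, ], "hamming")
  miss_only <- colMeans(t(vapply(1:8, function(i) {
    pool <- which(ds$labels != ds$labels[i])
    m <- pool[which.min(D[i, pool])]
    (ds$genotypes[i, ] != ds$genotypes[m, ]) * 1
  }, numeric(5))))
  expect_equal(unname(relief_original(dup)), unname(miss_only))
})

test_that("relief_original is the 1-nearest hit/miss engine up to its normaliser", {
  # the framework engine divides each per-sample update by the total
  # absolute kernel mass (= 2 for one hit plus one miss), whereas classic
  # Relief divides only by the number of focal samples, so its weights are
  # exactly twice the engine's
  # keep instances where every sample has at least one hit and one miss and
  # a unique nearest neighbor of each kind, so the k = 1 step kernel selects
  # exactly one hit and one miss and its normaliser is always 2
  found <- 0
  for (seed in 1:200) {
    ds <- random_dataset(7, 25, seed = 400 + seed)
    D <- pairwise_distances(ds)
    tie_free <- TRUE
    for (i in 1:7) {
      for (cls in 0:1) {
        pool <- setdiff(which(ds$labels == cls), i)
        if (!length(pool) || sum(D[i, pool] == min(D[i, pool])) > 1)
          tie_free <- FALSE
      }
    }
    if (!tie_free) next
    found <- found + 1
    w_relief <- relief_original(ds)
    w_morf <- suppressWarnings(
      morf_weights(ds, neighbor_kernel("relieff", k = 1)))
    expect_equal(w_relief, 2 * w_morf, tolerance = 1e-12)
    if (found >= 5) break
  }
  expect_gte(found, 3)
})

test_that("run_algorithm dispatches to the equivalent kernel", {
  ds <- random_dataset(16, 8, seed = 21)
  expect_equal(run_algorithm(ds, algorithm_config("swrf_star")),
               morf_weights(ds, neighbor_kernel("swrf_star")))
  expect_equal(run_algorithm(ds, algorithm_config("surf_star")),
               morf_weights(ds, neighbor_kernel("surf_star")))
  expect_equal(run_algorithm(ds, algorithm_config("relieff", k = 3)),
               morf_weights(ds, neighbor_kernel("relieff", k = 3)))
  expect_equal(run_algorithm(ds, algorithm_config("relief")),
               relief_original(ds))
})

test_that("relieff with k = n - 1 reduces to all-neighbor step weighting", {
  ds <- random_dataset(12, 6, seed = 66)
  w_k <- run_algorithm(ds, algorithm_config("relieff", k = 11))
  # with every neighbor inside both thresholds the kernel is identically 1,
  # which is SURF with an infinite radius
  w_all <- morf_weights(ds, neighbor_kernel("surf", t = 6))
  expect_equal(w_k, w_all, tolerance = 1e-12)
})

test_that("SWRF* at a very large scale matches SURF* away from the threshold", {
  checked <- 0
  for (seed in 1:40) {
    ds <- random_dataset(10, 7, seed = 700 + seed)
    D <- pairwise_distances(ds)
    t <- distance_stats(D)$t
    if (any(abs(D[upper.tri(D)] - t) < 1e-6)) next  # tie at the threshold
    checked <- checked + 1
    w_swrf <- run_algorithm(ds, algorithm_config("swrf_star", scale = 1e6))
    w_surf <- run_algorithm(ds, algorithm_config("surf_star"))
    expect_equal(w_swrf, w_surf, tolerance = 1e-9)
    if (checked >= 8) break
  }
  expect_gte(checked, 5)
})

test_that("k larger than the neighbor pool clamps with a warning", {
  set.seed(3)
  ds <- genotype_dataset(matrix(sample(0:2, 24, replace = TRUE), 6, 4),
                         rep(c(0, 1), 3))
  expect_warning(w <- run_algorithm(ds, algorithm_config("relieff", k = 50)),
                 "clamping")
  expect_true(all(w >= -1 & w <= 1))
})

test_that("subsampled runs are reproducible given the seed and need one", {
  ds <- random_dataset(20, 6, seed = 8)
  cfg <- algorithm_config("swrf_star", sample_fraction = 0.5, seed = 99)
  expect_equal(run_algorithm(ds, cfg), run_algorithm(ds, cfg))
  expect_error(algorithm_config("swrf_star", sample_fraction = 0.5),
               "seed")
})

test_that("configs validate their domains", {
  expect_error(algorithm_config("blorf"), "arg")
  expect_error(algorithm_config("relieff", k = 0), "positive integer")
  expect_error(algorithm_config("swrf_star", scale = -2), "positive")
  expect_error(algorithm_config("surf", sample_fraction = 0), "\\(0, 1]")
})
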