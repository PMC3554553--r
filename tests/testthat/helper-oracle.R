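# Independent brute-force implementations used as oracles. These are written
# as plain triple loops over samples and attributes, sharing no code with the
# package's vectorised engine.

random_dataset <- function(n, a, seed, p_case = 0.5) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * a, replace = TRUE), n, a)
  labels <- rbinom(n, 1, p_case)
  # ensure both classes are present so neighbor definitions are complete
  if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
  genotype_dataset(g, labels)
}

naive_dist <- function(x, y, metric) {
  if (metric == "hamming") sum(x != y) else sum(abs(x - y))
}

naive_collapse <- function(v, diff_model) {
  switch(diff_model,
         allelic = v,
         dominant = as.integer(v >= 1),
         recessive = as.integer(v == 2),
         heterozygote = as.integer(v == 1))
}

# Triple-loop evaluation of the per-sample weight update rule with the
# absolute-value normaliser, for any of the four kernel kinds.
naive_morf_weights <- function(dataset, kind, k = 10, scale = 4,
                               diff_model = "allelic", metric = "hamming") {
  X <- dataset$genotypes
  labels <- dataset$labels
  n <- nrow(X)
  a <- ncol(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- naive_dist(X[i, ], X[j, ], metric)
  pair <- D[upper.tri(D)]
  t <- mean(pair)
  u <- sqrt(mean((pair - t)^2))
  f_of <- function(i, j) {
    d <- D[i, j]
    switch(kind,
           surf = if (d <= t) 1 else 0,
           surf_star = if (d <= t) 1 else -1,
           swrf_star = 2 / (1 + exp(-(t - d) / (u / scale))) - 1,
           relieff = {
             same <- labels[j] == labels[i]
             pool <- setdiff(which((labels == labels[i]) == same), i)
             dd <- sort(D[i, pool])
             thr <- if (length(dd)) dd[min(k, length(dd))] else -Inf
             if (d <= thr) 1 else 0
           })
  }
  Xc <- apply(X, 2, naive_collapse, diff_model = diff_model)
  W <- numeric(a)
  for (att in seq_len(a)) {
    total <- 0
    for (i in seq_len(n)) {
      num <- 0
      den <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        fij <- f_of(i, j)
        cij <- if (labels[i] == labels[j]) -1 else 1
        dij <- if (Xc[i, att] == Xc[j, att]) 0 else 1
        num <- num + cij * dij * fij
        den <- den + abs(fij)
      }
      total <- total + if (den > 0) num / den else 0
    }
    W[att] <- total / n
  }
  W
}

# Exhaustive two-sided Fisher p-value: enumerate every table with the
# observed margins, compute its exact probability from binomial
# coefficients, and sum those not exceeding the observed probability
# (with a small relative tolerance for floating-point ties).
naive_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  nn <- r1 + r2
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  prob <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(nn, c1), numeric(1))
  obs <- prob[a - lo + 1]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# 9-cell brute-force moments of a penetrance model under HWE.
naive_model_moments <- function(table, maf) {
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  K <- 0
  for (g in 1:3) for (h in 1:3) K <- K + p[g] * p[h] * table[g, h]
  v <- 0
  for (g in 1:3) for (h in 1:3) v <- v + p[g] * p[h] * (table[g, h] - K)^2
  ma <- mb <- numeric(3)
  for (g in 1:3) for (h in 1:3) {
    ma[g] <- ma[g] + p[h] * table[g, h]
    mb[h] <- mb[h] + p[g] * table[g, h]
  }
  list(K = K, h2 = v / (K * (1 - K)), marginal_a = ma, marginal_b = mb)
}
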