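test_that("Hardy-Weinberg genotype distribution", {
  expect_equal(genotype_distribution(0.5), c(0.25, 0.5, 0.25))
  expect_equal(genotype_distribution(0.2), c(0.64, 0.32, 0.04))
  for (p in c(0.05, 0.17, 0.33, 0.5))
    expect_equal(sum(genotype_distribution(p)), 1)
  expect_error(genotype_distribution(0), "\\(0, 0.5]")
  expect_error(genotype_distribution(0.6), "\\(0, 0.5]")
})

test_that("heritability follows the variance-explained convention", {
  const <- penetrance_model(matrix(0.3, 3, 3), 0.3)
  expect_equal(const$heritability, 0)

  # fully penetrant XOR at MAF 0.5: K = 0.5 and every deviation is 0.5,
  # so the penetrance variance saturates K(1 - K) and h2 = 1
  xor <- outer(0:2, 0:2, function(g, h) ((g + h) %% 2) * 1)
  m_xor <- penetrance_model(xor, 0.5)
  expect_equal(m_xor$heritability, 1)

  # attenuating the table halfway toward 0.5 scales the variance by 0.25
  m_half <- penetrance_model(0.5 + 0.5 * (xor - 0.5), 0.5)
  expect_equal(m_half$heritability, 0.25)

  expect_error(heritability(penetrance_model(matrix(0, 3, 3), 0.3)),
               "degenerate")
})

test_that("heritability and marginals agree with 9-cell brute force", {
  set.seed(202)
  for (case in 1:25) {
    maf <- runif(1, 0.05, 0.5)
    tab <- matrix(runif(9), 3, 3)
    m <- penetrance_model(tab, maf)
    oracle <- naive_model_moments(tab, maf)
    expect_equal(m$prevalence, oracle$K)
    expect_equal(m$heritability, oracle$h2)
    me <- marginal_effects(m)
    expect_equal(me$locus_a, oracle$marginal_a)
    expect_equal(me$locus_b, oracle$marginal_b)
    expect_equal(me$main_effect_score,
                 max(diff(range(oracle$marginal_a)),
                     diff(range(oracle$marginal_b))))
  }
})

test_that("marginal effects vanish for purely epistatic tables", {
  xor <- outer(0:2, 0:2, function(g, h) ((g + h) %% 2) * 1)
  me <- marginal_effects(penetrance_model(xor, 0.5))
  expect_equal(me$locus_a, rep(0.5, 3))
  expect_equal(me$main_effect_score, 0)

  # a table depending only on g has locus-A marginal equal to the table rows
  tab <- matrix(rep(c(0.1, 0.5, 0.9), 3), 3, 3)
  me2 <- marginal_effects(penetrance_model(tab, 0.3))
  expect_equal(me2$locus_a, c(0.1, 0.5, 0.9))
  expect_equal(me2$main_effect_score, 0.8)
})

test_that("find_model hits the target heritability with flat marginals", {
  for (setting in list(c(0.4, 0.2), c(0.05, 0.4), c(0.1, 0.2))) {
    m <- find_model(setting[1], setting[2], seed = 7)
    expect_lte(abs(m$heritability - setting[1]), 0.01 * setting[1])
    expect_lte(m$main_effect_score, 0.01)
    expect_true(all(m$table >= 0 & m$table <= 1))
    # reproducible given the seed
    m2 <- find_model(setting[1], setting[2], seed = 7)
    expect_identical(m$table, m2$table)
  }
  expect_error(find_model(0, 0.2), "\\(0, 1]")
})

test_that("case-control sampling is balanced, reproducible, in-domain", {
  m <- find_model(0.2, 0.4, seed = 7)
  ds <- sample_case_control(m, 200, seed = 5)
  expect_equal(n_samples(ds), 200)
  expect_equal(n_attributes(ds), 2)
  expect_equal(sum(ds$labels == 1), 100)
  expect_equal(sum(ds$labels == 0), 100)
  expect_true(all(ds$genotypes %in% 0:2))
  expect_identical(sample_case_control(m, 200, seed = 5)$genotypes,
                   ds$genotypes)
  expect_error(sample_case_control(m, 201, seed = 1), "even")

  # a fully penetrant XOR model forces every case to odd allele-count sum
  xor <- outer(0:2, 0:2, function(g, h) ((g + h) %% 2) * 1)
  dx <- sample_case_control(penetrance_model(xor, 0.5), 100, seed = 2)
  sums <- rowSums(dx$genotypes)
  expect_true(all(sums[dx$labels == 1] %% 2 == 1))
  expect_true(all(sums[dx$labels == 0] %% 2 == 0))

  expect_error(sample_case_control(penetrance_model(matrix(1, 3, 3), 0.3), 10),
               "degenerate")
})

test_that("noise SNPs are appended independently of class", {
  m <- find_model(0.1, 0.4, seed = 3)
  ds <- sample_case_control(m, 300, seed = 4)
  for (mode in c("hw", "uniform")) {
    padded <- add_noise_snps(ds, 98, seed = 11, mode = mode)
    expect_equal(n_attributes(padded), 100)
    expect_equal(padded$labels, ds$labels)
    expect_equal(padded$genotypes[, 1:2], ds$genotypes,
                 ignore_attr = TRUE)
    expect_equal(padded$functional, 1:2)
    expect_true(all(padded$genotypes %in% 0:2))
    # point-biserial correlation of noise with class concentrates near 0
    cors <- abs(cor(padded$genotypes[, 3:100], padded$labels))
    expect_lt(mean(cors), 0.1)
    expect_lt(max(cors), 0.35)
  }
  expect_identical(add_noise_snps(ds, 10, seed = 1)$genotypes,
                   add_noise_snps(ds, 10, seed = 1)$genotypes)
})

test_that("generate_design enumerates the factorial design with a manifest", {
  design <- simulation_design(heritabilities = 0.1, mafs = 0.4,
                              sample_sizes = 50, models_per_setting = 1,
                              replicates_per_model = 3, n_noise = 8, seed = 9)
  res <- generate_design(design)
  expect_equal(nrow(res$manifest), 3)
  expect_length(res$datasets, 3)
  expect_equal(n_attributes(res$datasets[[1]]), 10)
  expect_equal(res$manifest$functional, rep("1,2", 3))

  # the paper-scale factorial enumerates 7 x 2 x 5 x 100 x 4 = 28,000
  full <- simulation_design()
  expect_equal(length(full$heritabilities) * length(full$mafs) *
                 full$models_per_setting * full$replicates_per_model *
                 length(full$sample_sizes), 28000)

  # same seed, same manifest; written form round-trips
  res2 <- generate_design(design)
  expect_identical(res$manifest, res2$manifest)
  out <- withr::local_tempdir()
  res3 <- generate_design(design, out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.tsv")))
  man <- read_manifest(file.path(out, "manifest.tsv"))
  expect_equal(man$seed_cc, res3$manifest$seed_cc)
  ds <- read_dataset(man$path[1])
  expect_identical(ds$genotypes, res$datasets[[1]]$genotypes)
})

test_that("shuffled functional positions are tracked in the manifest", {
  design <- simulation_design(heritabilities = 0.2, mafs = 0.4,
                              sample_sizes = 60, models_per_setting = 1,
                              replicates_per_model = 2, n_noise = 20, seed = 4)
  res <- generate_design(design, shuffle_positions = TRUE)
  for (i in 1:2) {
    ds <- res$datasets[[i]]
    expect_setequal(ds$attribute_names[ds$functional], c("SNP_A", "SNP_B"))
  }
})
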