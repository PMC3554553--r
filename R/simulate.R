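#' Sample a balanced case-control dataset from a penetrance model
#'
#' Draws genotype pairs at the two functional loci under Hardy-Weinberg
#' proportions and linkage equilibrium, assigns disease status with
#' probability `f_gh`, and rejection-samples until exactly `n/2` cases and
#' `n/2` controls are collected, mirroring the balanced ascertainment of the
#' synthetic epistasis benchmarks this generator emulates.
#'
#' @param model A [penetrance_model()].
#' @param n Even total sample size (cases + controls).
#' @param seed Integer seed; the draw is reproducible.
#' @return A [genotype_dataset()] with 2 attributes (`SNP_A`, `SNP_B`), both
#'   marked as functional, `n/2` samples per class.
#' @export
sample_case_control <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "penetrance_model"))
  n <- as.integer(n)
  if (is.na(n) || n < 2L || n %% 2L != 0L)
    stop("'n' must be an even sample size >= 2", call. = FALSE)
  K <- model$prevalence
  if (K <= 1e-9 || K >= 1 - 1e-9)
    stop("degenerate model: one class has probability (numerically) 0 and cannot be sampled",
         call. = FALSE)
  p <- genotype_distribution(model$maf_a)
  q <- genotype_distribution(model$maf_b)
  half <- n %/% 2L
  runner <- local_rng(seed)
  dat <- runner(function() {
    cases <- matrix(0L, 0L, 2L)
    controls <- matrix(0L, 0L, 2L)
    batch <- max(1000L, 4L * n)
    tries <- 0L
    while (nrow(cases) < half || nrow(controls) < half) {
      tries <- tries + 1L
      if (tries > 10000L)
        stop("rejection sampling failed to fill both classes; the model is (near-)degenerate",
             call. = FALSE)
      g <- sample.int(3L, batch, replace = TRUE, prob = p) - 1L
      h <- sample.int(3L, batch, replace = TRUE, prob = q) - 1L
      f <- model$table[cbind(g + 1L, h + 1L)]
      disease <- stats::runif(batch) < f
      if (nrow(cases) < half) {
        need <- half - nrow(cases)
        idx <- which(disease)
        cases <- rbind(cases, cbind(g, h)[utils::head(idx, need), , drop = FALSE])
      }
      if (nrow(controls) < half) {
        need <- half - nrow(controls)
        idx <- which(!disease)
        controls <- rbind(controls, cbind(g, h)[utils::head(idx, need), , drop = FALSE])
      }
    }
    list(cases = cases, controls = controls)
  })
  genotype_dataset(rbind(dat$cases, dat$controls),
                   labels = rep(c(1L, 0L), each = half),
                   attribute_names = c("SNP_A", "SNP_B"),
                   functional = 1:2)
}

#' Append non-informative noise SNPs
#'
#' Pads a dataset with `n_noise` attributes whose genotypes are drawn
#' independently of class, emulating the large background of irrelevant
#' markers in the synthetic epistasis benchmarks. By default each noise SNP
#' gets its own minor allele frequency drawn uniformly from `[0.05, 0.5]`
#' and Hardy-Weinberg genotypes; `mode = "uniform"` instead draws genotypes
#' uniformly from `{0, 1, 2}`. The functional-attribute metadata of the
#' input dataset is preserved.
#'
#' @param dataset A [genotype_dataset()].
#' @param n_noise Number of noise attributes to append (default 998, giving
#'   1000 SNPs on a 2-locus dataset).
#' @param seed Integer seed.
#' @param mode `"hw"` (default) or `"uniform"`.
#' @return A [genotype_dataset()] with `n_attributes + n_noise` attributes.
#' @export
add_noise_snps <- function(dataset, n_noise = 998L, seed = 1L,
                           mode = c("hw", "uniform")) {
  stopifnot_dataset(dataset)
  mode <- match.arg(mode)
  n_noise <- as.integer(n_noise)
  if (is.na(n_noise) || n_noise < 0L)
    stop("'n_noise' must be a non-negative count", call. = FALSE)
  if (n_noise == 0L) return(dataset)
  n <- n_samples(dataset)
  runner <- local_rng(seed)
  noise <- runner(function() {
    if (mode == "uniform") {
      matrix(sample(0:2, n * n_noise, replace = TRUE), n, n_noise)
    } else {
      maf <- stats::runif(n_noise, 0.05, 0.5)
      p0 <- (1 - maf)^2
      p01 <- p0 + 2 * maf * (1 - maf)
      u <- matrix(stats::runif(n * n_noise), n, n_noise)
      (u > rep(p0, each = n)) + (u > rep(p01, each = n))
    }
  })
  funct <- dataset$functional
  if (!length(funct)) funct <- seq_len(n_attributes(dataset))
  genotype_dataset(cbind(dataset$genotypes, noise),
                   labels = dataset$labels,
                   attribute_names = c(dataset$attribute_names,
                                       sprintf("N%04d", seq_len(n_noise))),
                   functional = funct)
}

#' Simulation design
#'
#' Describes a full factorial synthetic-data study: for every combination of
#' heritability and MAF, `models_per_setting` purely epistatic penetrance
#' models are searched, and `replicates_per_model` balanced case-control
#' datasets are generated from each model at every sample size, each padded
#' with `n_noise` noise SNPs. The defaults are the benchmark conditions this
#' generator emulates: heritabilities 0.01-0.40, MAFs 0.2 and 0.4, sample
#' sizes 200-1600, 5 models per setting, 100 replicates per model, 998 noise
#' SNPs (28,000 datasets in all).
#'
#' @param heritabilities Numeric vector of target heritabilities.
#' @param mafs Numeric vector of minor allele frequencies.
#' @param sample_sizes Integer vector of (even) dataset sizes.
#' @param models_per_setting Penetrance models per (h2, MAF) setting.
#' @param replicates_per_model Datasets per model per sample size.
#' @param n_noise Noise SNPs appended to each dataset.
#' @param seed Master seed from which all model-search and dataset seeds are
#'   derived.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(heritabilities = c(0.01, 0.025, 0.05, 0.1, 0.2, 0.3, 0.4),
                              mafs = c(0.2, 0.4),
                              sample_sizes = c(200L, 400L, 800L, 1600L),
                              models_per_setting = 5L,
                              replicates_per_model = 100L,
                              n_noise = 998L,
                              seed = 1L) {
  stopifnot(all(heritabilities > 0), all(heritabilities <= 1),
            all(mafs > 0), all(mafs <= 0.5),
            all(sample_sizes %% 2 == 0),
            models_per_setting >= 1, replicates_per_model >= 1, n_noise >= 0)
  structure(list(heritabilities = heritabilities, mafs = mafs,
                 sample_sizes = as.integer(sample_sizes),
                 models_per_setting = as.integer(models_per_setting),
                 replicates_per_model = as.integer(replicates_per_model),
                 n_noise = as.integer(n_noise), seed = as.integer(seed)),
            class = "simulation_design")
}

#' Generate all datasets of a simulation design
#'
#' Runs the model search and dataset generation for a [simulation_design()].
#' Every row of the returned manifest corresponds to one dataset and records
#' the setting (h2, MAF, sample size), model id and penetrance table, the
#' derived seed, the functional SNP positions, and — when `out_dir` is given
#' — the path of the written file. With `out_dir = NULL` the datasets are
#' returned in memory, which is only sensible for small designs.
#'
#' @param design A [simulation_design()].
#' @param out_dir Optional directory; datasets are written as tab-delimited
#'   genotype tables via [write_dataset()] and a `manifest.tsv` is placed
#'   alongside them.
#' @param shuffle_positions Place the two functional SNPs at random columns
#'   instead of the first two (default `FALSE`); their positions are always
#'   recorded in the manifest.
#' @return List with `manifest` (data.frame), `models` (list of
#'   [penetrance_model()]s) and, if `out_dir` is `NULL`, `datasets` (list of
#'   [genotype_dataset()]s).
#' @export
generate_design <- function(design, out_dir = NULL, shuffle_positions = FALSE) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seeds <- derive_seeds(design$seed,
                        length(design$heritabilities) * length(design$mafs) *
                          design$models_per_setting *
                          (1L + design$replicates_per_model *
                             length(design$sample_sizes) * 2L))
  sidx <- 0L
  next_seed <- function() {
    sidx <<- sidx + 1L
    seeds[sidx]
  }
  rows <- list()
  models <- list()
  datasets <- list()
  did <- 0L
  for (h2 in design$heritabilities) for (maf in design$mafs) {
    for (m in seq_len(design$models_per_setting)) {
      model_id <- sprintf("h%s_maf%s_m%d", format(h2), format(maf), m)
      model <- find_model(h2, maf, seed = next_seed())
      models[[model_id]] <- model
      for (size in design$sample_sizes) {
        for (rep in seq_len(design$replicates_per_model)) {
          did <- did + 1L
          seed_cc <- next_seed()
          seed_noise <- next_seed()
          ds <- sample_case_control(model, size, seed = seed_cc)
          ds <- add_noise_snps(ds, design$n_noise, seed = seed_noise)
          if (shuffle_positions) {
            perm <- local_rng(seed_noise + 1L)(function()
              sample.int(n_attributes(ds)))
            ds <- genotype_dataset(ds$genotypes[, perm, drop = FALSE],
                                   ds$labels,
                                   attribute_names = ds$attribute_names[perm],
                                   functional = match(ds$functional, perm))
          }
          path <- NA_character_
          if (!is.null(out_dir)) {
            path <- file.path(out_dir, paste0(model_id,
                                              sprintf("_n%d_r%03d.tsv", size, rep)))
            write_dataset(ds, path)
          } else {
            datasets[[did]] <- ds
          }
          rows[[did]] <- data.frame(
            dataset_id = did, model_id = model_id, h2 = h2, maf = maf,
            size = size, replicate = rep, seed_cc = seed_cc,
            seed_noise = seed_noise,
            functional = paste(ds$functional, collapse = ","),
            table = paste(format(model$table, digits = 15, trim = TRUE),
                          collapse = ","),
            path = path, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(manifest = manifest, models = models)
  if (is.null(out_dir)) out$datasets <- datasets
  out
}

# Deterministic stream of sub-seeds below 2^31, derived from a master seed.
derive_seeds <- function(seed, count) {
  local_rng(seed)(function() sample.int(.Machine$integer.max, count))
}
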