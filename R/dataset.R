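#' Construct a genotype dataset
#'
#' Bundles a sample-by-SNP genotype matrix with binary case-control labels.
#' Genotypes are coded as minor-allele counts (0, 1 or 2 copies) and class
#' labels as 0 (control) and 1 (case). This is the container every weighting
#' algorithm in the package operates on.
#'
#' @param genotypes Integer matrix, `n` samples by `a` attributes, entries in
#'   `{0, 1, 2}`.
#' @param labels Vector of length `n` with entries in `{0, 1}`.
#' @param attribute_names Optional character vector of `a` unique names;
#'   defaults to the column names of `genotypes`, or `SNP1 ... SNPa`.
#' @param functional Optional integer vector of column indices of the
#'   functional (disease-associated) attributes, carried as metadata so that
#'   power evaluation can locate them after noise attributes are appended.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `labels`, `attribute_names` and `functional`.
#' @export
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L), nrow = 2, byrow = TRUE)
#' ds <- genotype_dataset(g, labels = c(0, 1))
#' n_samples(ds)
genotype_dataset <- function(genotypes, labels,
                             attribute_names = NULL, functional = integer(0)) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  a <- ncol(genotypes)
  if (n < 2L) stop("a genotype dataset needs at least 2 samples", call. = FALSE)
  if (a < 1L) stop("a genotype dataset needs at least 1 attribute", call. = FALSE)
  bad <- which(!(genotypes %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% n) + 1L
    j <- ((bad[1L] - 1L) %/% n) + 1L
    stop(sprintf("invalid genotype at sample %d, attribute %d: values must be 0, 1 or 2",
                 i, j), call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("length of 'labels' must equal the number of samples", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("invalid class label: labels must be 0 or 1", call. = FALSE)
  if (is.null(attribute_names)) attribute_names <- colnames(genotypes)
  if (is.null(attribute_names)) attribute_names <- paste0("SNP", seq_len(a))
  attribute_names <- as.character(attribute_names)
  if (length(attribute_names) != a)
    stop("length of 'attribute_names' must equal the number of attributes",
         call. = FALSE)
  if (anyDuplicated(attribute_names))
    stop("attribute names must be unique", call. = FALSE)
  colnames(genotypes) <- attribute_names
  functional <- as.integer(functional)
  if (length(functional) && (any(functional < 1L) || any(functional > a)))
    stop("'functional' indices out of range", call. = FALSE)
  structure(
    list(genotypes = genotypes, labels = labels,
         attribute_names = attribute_names, functional = functional),
    class = "genotype_dataset"
  )
}

#' @rdname genotype_dataset
#' @param x,object A `genotype_dataset`.
#' @export
n_samples <- function(x) nrow(x$genotypes)

#' @rdname genotype_dataset
#' @export
n_attributes <- function(x) ncol(x$genotypes)

#' @rdname genotype_dataset
#' @param ... Unused.
#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs (%d cases / %d controls)\n",
              n_samples(x), n_attributes(x), sum(x$labels == 1L),
              sum(x$labels == 0L)))
  if (length(x$functional))
    cat("functional attributes:",
        paste(x$attribute_names[x$functional], collapse = ", "), "\n")
  invisible(x)
}

#' Subset the samples of a genotype dataset
#'
#' @param dataset A `genotype_dataset`.
#' @param idx Integer vector of sample indices to keep.
#' @return A `genotype_dataset` restricted to the selected samples.
#' @keywords internal
subset_samples <- function(dataset, idx) {
  idx <- as.integer(idx)
  if (!length(idx)) stop("empty sample set", call. = FALSE)
  genotype_dataset(dataset$genotypes[idx, , drop = FALSE],
                   dataset$labels[idx],
                   attribute_names = dataset$attribute_names,
                   functional = dataset$functional)
}

stopifnot_dataset <- function(dataset) {
  if (!inherits(dataset, "genotype_dataset"))
    stop("expected a 'genotype_dataset' (see genotype_dataset())", call. = FALSE)
  invisible(dataset)
}
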