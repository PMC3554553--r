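#' Read a tab-delimited genotype table
#'
#' Parses the plain-text dialect used by the synthetic SNP benchmarks: a
#' tab-delimited UTF-8 table whose header names the attributes followed by a
#' class column (named `Class` by default), one sample per row, genotypes
#' coded 0/1/2 and class 0/1. Domain violations are reported with the
#' offending row and column.
#'
#' @param path Path to the file.
#' @param class_column Name of the class column (default `"Class"`); it need
#'   not be the last column.
#' @return A [genotype_dataset()].
#' @export
read_dataset <- function(path, class_column = "Class") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "numeric")
  if (nrow(df) == 0L)
    stop(sprintf("%s contains a header but no samples", path), call. = FALSE)
  if (!class_column %in% names(df))
    stop(sprintf("%s: class column '%s' not found", path, class_column),
         call. = FALSE)
  ci <- match(class_column, names(df))
  labels <- df[[ci]]
  G <- as.matrix(df[, -ci, drop = FALSE])
  bad <- which(!(G %in% c(0, 1, 2)))
  if (length(bad)) {
    r <- ((bad[1L] - 1L) %% nrow(G)) + 1L
    cidx <- ((bad[1L] - 1L) %/% nrow(G)) + 1L
    stop(sprintf("%s: invalid genotype '%s' at row %d, column '%s'",
                 path, format(G[bad[1L]]), r, colnames(G)[cidx]), call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)))
    stop(sprintf("%s: invalid class label at row %d",
                 path, which(!(labels %in% c(0, 1)))[1L]), call. = FALSE)
  genotype_dataset(G, labels, attribute_names = colnames(G))
}

#' Write a genotype dataset as a tab-delimited table
#'
#' Emits the dialect read by [read_dataset()]: tab-delimited, LF newlines,
#' attribute columns followed by a final `Class` column. Byte output is
#' deterministic for identical inputs.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot_dataset(dataset)
  df <- as.data.frame(dataset$genotypes, check.names = FALSE)
  df$Class <- dataset$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write attribute weights with their ranks
#'
#' Tab-delimited output with columns `attribute`, `weight` (full double
#' precision, 17 significant digits) and `rank` from [rank_attributes()].
#'
#' @param weights Numeric weight vector.
#' @param names Attribute names aligned with `weights`; defaults to
#'   `names(weights)`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_weights <- function(weights, path, names = base::names(weights)) {
  if (is.null(names)) names <- paste0("SNP", seq_along(weights))
  if (length(names) != length(weights))
    stop("'names' and 'weights' must have equal length", call. = FALSE)
  ranking <- rank_attributes(weights)
  rank_of <- integer(length(weights))
  rank_of[ranking] <- seq_along(weights)
  lines <- c("attribute\tweight\trank",
             sprintf("%s\t%.17g\t%d", names, weights, rank_of))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weights file written by [write_weights()]
#'
#' @param path Path to the file.
#' @return Named numeric vector of weights, in file order.
#' @export
read_weights <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("attribute", "weight") %in% names(df)))
    stop(sprintf("%s is not a weights file", path), call. = FALSE)
  stats::setNames(as.numeric(df$weight), df$attribute)
}

#' Read a simulation manifest written by [generate_design()]
#'
#' @param path Path to `manifest.tsv`.
#' @return A data.frame with one row per generated dataset.
#' @export
read_manifest <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = list(functional = "character"))
}
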