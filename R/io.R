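## Plain-text I/O: TSV tables, MatrixMarket count matrices, GMT gene sets.

#' Write / read a count matrix as TSV
#'
#' Genes in rows (first column `gene_id`), samples in columns.
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path Output file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read a count matrix in MatrixMarket format
#'
#' Writes `<prefix>.mtx` plus `<prefix>.rownames.tsv` and
#' `<prefix>.colnames.tsv` sidecars.
#'
#' @param counts genes x samples (or genes x cells) matrix.
#' @param prefix Path prefix for the three files.
#' @export
write_counts_mtx <- function(counts, prefix) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, ".rownames.tsv"))
  writeLines(colnames(counts), paste0(prefix, ".colnames.tsv"))
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".rownames.tsv"))
  colnames(m) <- readLines(paste0(prefix, ".colnames.tsv"))
  storage.mode(m) <- "integer"
  m
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member gene identifiers,
#' tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "")
  out
}

#' Write a data.frame as a TSV with header
#'
#' @param df data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
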