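# UMI count matrices: container plus MatrixMarket / dense TSV storage.

#' Construct a cells x genes UMI count matrix
#'
#' @param counts non-negative integer matrix, cells in rows, genes in columns.
#' @param gene_ids,cell_ids character identifiers; duplicates are rejected.
#' @return An object of class `count_matrix` with fields `counts` (dense
#'   integer matrix with dimnames), `gene_ids`, `cell_ids` and `depth`
#'   (per-cell total count, equal to row sums by construction).
#' @export
count_matrix <- function(counts, gene_ids = colnames(counts),
                         cell_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(ncol(counts)))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%03d", seq_len(nrow(counts)))
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(counts) || length(cell_ids) != nrow(counts))
    bl_error("dim_mismatch", "id lengths (%d cells, %d genes) do not match matrix %d x %d",
             length(cell_ids), length(gene_ids), nrow(counts), ncol(counts))
  if (anyDuplicated(gene_ids)) bl_error("duplicate_ids", "duplicate gene ids")
  if (anyDuplicated(cell_ids)) bl_error("duplicate_ids", "duplicate cell ids")
  if (!all(is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    bl_error("non_integer_count", "counts must be finite non-negative integers")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 depth = rowSums(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix: %d cells x %d genes, median depth %s>\n",
              length(x$cell_ids), length(x$gene_ids),
              format(median(x$depth), big.mark = ",")))
  invisible(x)
}

#' Write counts as 10x-style MatrixMarket triplet
#'
#' Writes `matrix.mtx` (genes x cells, the on-disk convention of gene-barcode
#' matrices), `genes.tsv` and `cells.tsv` into `dir`.
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(cm$counts), sparse = TRUE)  # genes x cells on disk
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(cm$cell_ids, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a UMI count matrix
#'
#' Accepts a directory holding `matrix.mtx` + `genes.tsv` + `cells.tsv`
#' (either orientation on disk; resolved against the sidecar lengths) or a
#' dense TSV with cells in rows (first column = cell id) and genes in columns.
#' Entries must be non-negative integers.
#'
#' @param path directory or TSV file path.
#' @return A [count_matrix()], oriented cells x genes.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv"); cf <- file.path(path, "cells.tsv")
    for (f in c(mtx, gf, cf)) if (!file.exists(f))
      bl_error("file_missing", "expected %s", f)
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- readLines(gf); cells <- readLines(cf)
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- t(m)
    } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      # already cells x genes
    } else {
      bl_error("dim_mismatch",
               "matrix %d x %d does not match %d genes / %d cells",
               nrow(m), ncol(m), length(genes), length(cells))
    }
    if (any(m != round(m))) bl_error("non_integer_count", "MTX holds non-integer entries")
    return(count_matrix(m, genes, cells))
  }
  if (!file.exists(path)) bl_error("file_missing", "counts not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cell_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)) || any(m != round(m)) || any(m < 0))
    bl_error("non_integer_count", "dense TSV holds non-integer count entries")
  count_matrix(m, colnames(df)[-1], cell_ids)
}
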