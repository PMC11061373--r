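# TSV tables and Newick dendrograms.

#' Write a data frame as a deterministic TSV
#'
#' Header row, UTF-8, "." decimal separator; numerics are formatted with 12
#' significant digits (scientific notation allowed) so that a write/read
#' round trip preserves values to 12 significant digits and repeated writes
#' of the same table are byte-identical.
#'
#' @param rows a data.frame (may have zero rows).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(rows), collapse = "\t"), con, sep = "\n")
  if (nrow(rows)) {
    cols <- lapply(rows, function(col) {
      if (is.numeric(col)) format_num(col) else as.character(col)
    })
    body <- do.call(paste, c(cols, sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path file path.
#' @return A data.frame with `check.names = FALSE`.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) bl_error("file_missing", "table not found: %s", path)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Serialize an hclust dendrogram as Newick
#'
#' Branch lengths are differences of merge heights (leaves sit at height 0),
#' so a two-leaf dendrogram merged at height h serializes as `(A:h,B:h);`
#' and root-to-leaf path length equals the final merge height.
#'
#' @param dendrogram an object of class `hclust`.
#' @param path output file path.
#' @param labels leaf labels; defaults to `dendrogram$labels`.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path, labels = dendrogram$labels) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- nrow(dendrogram$merge) + 1L
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  fmt <- function(h) sprintf("%.10g", h)
  node_str <- function(idx, parent_h) {
    if (idx < 0) {
      sprintf("%s:%s", labels[-idx], fmt(parent_h))
    } else {
      h <- dendrogram$height[idx]
      kids <- dendrogram$merge[idx, ]
      sprintf("(%s,%s):%s", node_str(kids[1], h), node_str(kids[2], h),
              fmt(parent_h - h))
    }
  }
  root <- nrow(dendrogram$merge)
  h <- dendrogram$height[root]
  kids <- dendrogram$merge[root, ]
  nwk <- sprintf("(%s,%s);", node_str(kids[1], h), node_str(kids[2], h))
  writeLines(nwk, path)
  invisible(path)
}
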