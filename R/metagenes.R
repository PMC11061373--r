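# Metagenes: Ward hierarchical clustering of genes on Spearman
# dissimilarities, tree cut to k groups, and per-cell metagene expression
# (mean of member genes' z-scores).

#' Gene-gene Spearman dissimilarity
#'
#' `d_ij = 1 - rho_s(gene_i, gene_j)` with average-rank tie handling, so
#' `d` lies in `[0, 2]` with a zero diagonal. Zero-variance genes have
#' undefined correlation; their off-diagonal dissimilarity is set to 1
#' (with a warning).
#'
#' @param z a `z_matrix` (or plain cells x genes matrix).
#' @return Symmetric genes x genes dissimilarity matrix.
#' @export
spearman_dissimilarity <- function(z) {
  v <- if (inherits(z, "z_matrix")) z$values else as.matrix(z)
  suppressWarnings(rho <- cor(v, method = "spearman"))
  d <- 1 - rho
  if (anyNA(d)) {
    bl_warn("zero-variance gene(s): undefined correlations set to dissimilarity 1")
    d[is.na(d)] <- 1
  }
  diag(d) <- 0
  d
}

#' Ward agglomerative clustering of a dissimilarity matrix
#'
#' Ward's minimum-variance linkage via `stats::hclust`. The default
#' `"ward.D2"` applies the Lance-Williams update on squared dissimilarities
#' (the convention matching Ward's original criterion on Euclidean inputs);
#' `"ward.D"` is the legacy R variant provided as a compatibility flag.
#'
#' @param d symmetric non-negative dissimilarity matrix (or `dist`).
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return An `hclust` object.
#' @export
ward_cluster <- function(d, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
      bl_error("bad_dissimilarity", "dissimilarity must be symmetric")
    if (any(d < 0)) bl_error("bad_dissimilarity", "dissimilarity must be non-negative")
    d <- as.dist(d)
  }
  hclust(d, method = method)
}

#' Cut a dendrogram into k metagenes
#'
#' Cuts at the k-1 highest merges; metagene ids are numbered by first gene
#' appearance (the `stats::cutree` convention).
#'
#' @param dendrogram an `hclust` object over genes.
#' @param k number of metagenes (default 25).
#' @return A `metagene_assignment`: named integer vector gene -> metagene id
#'   in `1..k`, with the dendrogram and member counts attached as attributes.
#' @export
cut_to_metagenes <- function(dendrogram, k = 25L) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- nrow(dendrogram$merge) + 1L
  if (k > n) bl_error("bad_k", "k = %d exceeds the %d genes in the tree", k, n)
  assignment <- cutree(dendrogram, k = k)
  structure(assignment, class = c("metagene_assignment", "integer"),
            k = as.integer(k), dendrogram = dendrogram,
            member_count = as.integer(table(assignment)))
}

#' Per-cell metagene expression
#'
#' The expression of a metagene in a cell is the arithmetic mean of the
#' z-scores of its member genes in that cell.
#'
#' @param z a `z_matrix` (or plain cells x genes matrix with gene columns
#'   matching the assignment names).
#' @param assignment a `metagene_assignment` (or named integer vector).
#' @return cells x k numeric matrix, columns `metagene_01 ...`.
#' @export
metagene_expression <- function(z, assignment) {
  v <- if (inherits(z, "z_matrix")) z$values else as.matrix(z)
  ids <- sort(unique(as.integer(assignment)))
  if (!is.null(names(assignment)) && !is.null(colnames(v))) {
    if (!all(names(assignment) %in% colnames(v)))
      bl_error("dim_mismatch", "assignment names genes absent from the matrix")
    v <- v[, names(assignment), drop = FALSE]
  } else if (length(assignment) != ncol(v)) {
    bl_error("dim_mismatch", "assignment length must match gene count")
  }
  out <- vapply(ids, function(m)
    rowMeans(v[, as.integer(assignment) == m, drop = FALSE]),
    numeric(nrow(v)))
  colnames(out) <- sprintf("metagene_%02d", ids)
  rownames(out) <- rownames(v)
  out
}
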