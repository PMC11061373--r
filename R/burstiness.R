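# Bursty / non-bursty classification and the signed burstiness index.
#
# Pipeline: PCA (centering only) of the 30-bin short-ISI vectors, k-means
# (k = 2, 50 seeded restarts) on the first three principal components, then
# a Fisher linear discriminant in PC space. The burstiness index of a cell
# is its signed Euclidean distance from the discriminant hyperplane;
# positive means bursty.

#' Fisher's linear discriminant for two labelled groups
#'
#' Computes the pooled within-class scatter `S_w`, the unit direction
#' `w` proportional to `S_w^{-1} (mu_1 - mu_0)` oriented so that group 1
#' projects positive, and the offset `c` at the midpoint of the projected
#' class means. The signed distance of a point `x` is `w . x - c`.
#'
#' @param x numeric matrix (rows = observations).
#' @param labels logical or two-level vector; `TRUE` (or the second level)
#'   is the positive group.
#' @param ridge ridge added to `S_w` if it is numerically singular
#'   (a warning is emitted).
#' @return List with `w` (unit vector), `c` (offset), `index` (signed
#'   distances of the rows of `x`).
#' @export
fisher_lda <- function(x, labels, ridge = 1e-8) {
  x <- as.matrix(x)
  g <- as.logical(if (is.logical(labels)) labels else labels == sort(unique(labels))[2])
  if (length(unique(g)) != 2) bl_error("one_class", "need two non-empty classes")
  mu1 <- colMeans(x[g, , drop = FALSE])
  mu0 <- colMeans(x[!g, , drop = FALSE])
  c1 <- sweep(x[g, , drop = FALSE], 2, mu1)
  c0 <- sweep(x[!g, , drop = FALSE], 2, mu0)
  sw <- crossprod(c1) + crossprod(c0)
  w <- tryCatch(solve(sw, mu1 - mu0), error = function(e) NULL)
  if (is.null(w) || rcond(sw) < 1e-12) {
    bl_warn("within-class scatter is singular; adding ridge %g", ridge)
    w <- solve(sw + diag(ridge, ncol(sw)), mu1 - mu0)
  }
  w <- w / sqrt(sum(w^2))
  cc <- as.numeric((sum(w * mu1) + sum(w * mu0)) / 2)
  list(w = as.numeric(w), c = cc, index = as.numeric(x %*% w - cc))
}

#' Classify neurons as bursty or non-bursty from ISI vectors
#'
#' @param isi_vectors numeric matrix, one row per neuron, columns the 30
#'   short-ISI histogram bins (see [isi_vector()]). At least 4 neurons.
#' @param n_pcs number of principal components retained (default 3).
#' @param n_restarts k-means restarts (default 50; best inertia kept).
#' @param seed RNG seed controlling the k-means restarts.
#' @return An object of class `burstiness_result`: data.frame `cells`
#'   (cell_id if rownames were given, pc1..pc3, cluster, burstiness index,
#'   is_bursty), plus the fitted model: `pca_center`, `pca_rotation`,
#'   `cluster_centroids`, `discriminant_w`, `discriminant_c`. The cluster
#'   whose members carry more total short-ISI mass is labelled bursty, and
#'   `is_bursty` is exactly `index > 0`.
#' @export
fit_burstiness <- function(isi_vectors, n_pcs = 3L, n_restarts = 50L, seed = 1L) {
  x <- as.matrix(isi_vectors)
  if (nrow(x) < 4) bl_error("too_few_cells", "need at least 4 neurons")
  if (!all(is.finite(x))) bl_error("non_finite", "ISI vectors must be finite")
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pca$rotation))
  scores <- pca$x[, seq_len(k), drop = FALSE]
  km <- tryCatch(
    with_seed(seed, kmeans(scores, centers = 2L, nstart = n_restarts)),
    error = function(e) bl_error("degenerate_isi",
                                 "k-means failed (fewer than 2 distinct ISI profiles?): %s",
                                 conditionMessage(e)))
  if (min(km$size) == 0) bl_error("empty_cluster", "k-means produced an empty cluster")
  mass <- tapply(rowSums(x), km$cluster, mean)
  bursty_cluster <- as.integer(names(which.max(mass)))
  fl <- fisher_lda(scores, km$cluster == bursty_cluster)
  cells <- data.frame(
    cell_id = rownames(x) %||% sprintf("cell_%03d", seq_len(nrow(x))),
    stringsAsFactors = FALSE)
  for (j in seq_len(k)) cells[[paste0("pc", j)]] <- scores[, j]
  cells$cluster <- km$cluster
  cells$index <- fl$index
  cells$is_bursty <- fl$index > 0
  structure(list(cells = cells,
                 pca_center = pca$center,
                 pca_rotation = pca$rotation[, seq_len(k), drop = FALSE],
                 cluster_centroids = km$centers,
                 discriminant_w = fl$w, discriminant_c = fl$c,
                 n_pcs = k),
            class = "burstiness_result")
}

#' @export
print.burstiness_result <- function(x, ...) {
  cat(sprintf("<burstiness_result: %d cells, %d bursty (index > 0)>\n",
              nrow(x$cells), sum(x$cells$is_bursty)))
  invisible(x)
}

#' Project a new ISI vector onto a fitted burstiness model
#'
#' Centers by the stored PCA mean, projects onto the retained principal
#' components and applies the fitted discriminant.
#'
#' @param model a `burstiness_result` from [fit_burstiness()].
#' @param new_isi_vector numeric vector with the same number of bins the
#'   model was fitted on.
#' @return The signed burstiness index (positive = bursty).
#' @export
project_burstiness <- function(model, new_isi_vector) {
  stopifnot(inherits(model, "burstiness_result"))
  v <- as.numeric(new_isi_vector)
  if (length(v) != length(model$pca_center))
    bl_error("dim_mismatch", "expected %d bins, got %d",
             length(model$pca_center), length(v))
  sc <- (v - model$pca_center) %*% model$pca_rotation
  as.numeric(sc %*% model$discriminant_w - model$discriminant_c)
}
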