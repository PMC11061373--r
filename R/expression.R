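# Cell QC, normalization and per-gene z-scoring of UMI counts.

#' Drop low-depth cells
#'
#' Removes cells whose total UMI count is strictly below `min_reads`
#' (default 5,000, the working QC cutoff for these single-cell libraries).
#' Optionally drops genes left with zero total count.
#'
#' @param cm a [count_matrix()].
#' @param min_reads depth threshold; cells with `depth < min_reads` go.
#' @param drop_zero_genes also remove all-zero genes (default FALSE).
#' @return A [count_matrix()] with attributes `dropped_cells` and
#'   `dropped_genes` listing removed ids. Idempotent.
#' @export
qc_filter <- function(cm, min_reads = 5000, drop_zero_genes = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- cm$depth >= min_reads
  if (!any(keep)) bl_error("all_cells_dropped", "QC removed every cell")
  out <- cm$counts[keep, , drop = FALSE]
  dropped_genes <- character(0)
  if (drop_zero_genes) {
    gkeep <- colSums(out) > 0
    dropped_genes <- colnames(out)[!gkeep]
    out <- out[, gkeep, drop = FALSE]
  }
  res <- count_matrix(out)
  attr(res, "dropped_cells") <- cm$cell_ids[!keep]
  attr(res, "dropped_genes") <- dropped_genes
  res
}

#' Normalize a UMI count matrix
#'
#' Two methods with the same intent (variance stabilization against depth):
#' * `"logdepth"` (default): `ln(1 + x * median(depth) / depth_cell)` —
#'   depth-scaled shifted log.
#' * `"pearson"`: analytic Pearson residuals under a negative-binomial null
#'   with fixed dispersion `theta`: `mu = depth_cell * p_gene` with
#'   `p_gene` = gene total / grand total, residual
#'   `(x - mu)/sqrt(mu + mu^2/theta)`, clipped to `+/- sqrt(n_cells)`.
#'   All-zero genes get residual 0.
#'
#' @param cm a [count_matrix()].
#' @param method `"logdepth"` or `"pearson"`.
#' @param theta NB dispersion for the Pearson method (default 100).
#' @return An object of class `normalized_matrix`: `values` (cells x genes),
#'   `method`, `params`.
#' @export
normalize_counts <- function(cm, method = c("logdepth", "pearson"), theta = 100) {
  stopifnot(inherits(cm, "count_matrix"))
  method <- match.arg(method)
  if (any(cm$depth == 0)) bl_error("zero_depth", "cells with zero depth cannot be normalized")
  x <- cm$counts
  if (method == "logdepth") {
    target <- median(cm$depth)
    vals <- log1p(x * (target / cm$depth))
    params <- list(target_depth = target, pseudocount = 1)
  } else {
    p_g <- colSums(x) / sum(x)
    mu <- outer(cm$depth, p_g)
    denom <- sqrt(mu + mu^2 / theta)
    vals <- (x - mu) / denom
    vals[, p_g == 0] <- 0
    clip <- sqrt(nrow(x))
    vals <- pmin(pmax(vals, -clip), clip)
    params <- list(theta = theta, clip = clip)
  }
  structure(list(values = vals, method = method, params = params,
                 gene_ids = cm$gene_ids, cell_ids = cm$cell_ids),
            class = "normalized_matrix")
}

#' Per-gene z-scores across cells
#'
#' Each gene column is centered and scaled by its population standard
#' deviation (divisor n) across all cells. Zero-variance genes become
#' all-zero columns with a warning.
#'
#' @param norm a `normalized_matrix` (or a plain cells x genes matrix).
#' @return An object of class `z_matrix`: `values` (cells x genes; each
#'   column has mean 0 and population SD 1 unless zero-variance),
#'   `zero_variance` (logical per gene).
#' @export
zscore_genes <- function(norm) {
  v <- if (inherits(norm, "normalized_matrix")) norm$values else as.matrix(norm)
  n <- nrow(v)
  mu <- colMeans(v)
  sd_pop <- sqrt(colMeans(v^2) - mu^2)
  sd_pop[sd_pop < 0] <- 0  # guard against negative rounding
  zero_var <- sd_pop <= .Machine$double.eps^0.5 * pmax(1, abs(mu))
  if (any(zero_var))
    bl_warn("%d zero-variance gene(s) set to all-zero z-scores", sum(zero_var))
  z <- sweep(v, 2, mu)
  z[, !zero_var] <- sweep(z[, !zero_var, drop = FALSE], 2, sd_pop[!zero_var], "/")
  z[, zero_var] <- 0
  structure(list(values = z, zero_variance = zero_var,
                 gene_ids = colnames(v), cell_ids = rownames(v)),
            class = "z_matrix")
}
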