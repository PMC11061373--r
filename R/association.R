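# Associating spike features with expression: Spearman correlations with
# BH q-values, and multiple regression with AIC-based subset selection.

#' Spearman association of a feature with each predictor column
#'
#' Rank correlation with average-rank ties; two-sided p from the
#' t-approximation `t = rs * sqrt((n-2)/(1-rs^2))` on n-2 df (an exact
#' permutation mode is available for small panels); q-values by
#' Benjamini-Hochberg across the tested family (the columns supplied).
#'
#' @param feature numeric vector (one value per cell), n >= 5.
#' @param predictors numeric matrix, cells x predictors.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations for the exact mode.
#' @param seed seed for the permutation mode.
#' @return data.frame: predictor, rs, p_rs, q_rs. Constant predictors get
#'   rs = 0, p = 1 with a warning.
#' @export
spearman_assoc <- function(feature, predictors, method = c("t", "permutation"),
                           n_perm = 1e5, seed = 1L) {
  method <- match.arg(method)
  p_mat <- as.matrix(predictors)
  n <- length(feature)
  if (n < 5) bl_error("too_few_cells", "need at least 5 cells")
  if (nrow(p_mat) != n) bl_error("dim_mismatch", "predictor rows must match feature length")
  if (!all(is.finite(feature)) || !all(is.finite(p_mat)))
    bl_error("non_finite", "feature and predictors must be finite")
  const <- apply(p_mat, 2, function(v) max(v) == min(v))
  if (any(const)) bl_warn("%d constant predictor(s): rs set to 0, p to 1", sum(const))
  rs <- rep(0, ncol(p_mat))
  suppressWarnings(
    rs[!const] <- as.numeric(cor(feature, p_mat[, !const, drop = FALSE],
                                 method = "spearman")))
  if (method == "t") {
    tv <- rs * sqrt((n - 2) / pmax(1 - rs^2, .Machine$double.eps))
    pv <- 2 * pt(-abs(tv), df = n - 2)
  } else {
    fr <- rank(feature, ties.method = "average")
    pv <- with_seed(seed, vapply(seq_len(ncol(p_mat)), function(j) {
      if (const[j]) return(1)
      obs <- abs(rs[j])
      pr <- rank(p_mat[, j], ties.method = "average")
      hits <- sum(vapply(seq_len(n_perm), function(i)
        abs(cor(sample(fr), pr)) >= obs - 1e-12, logical(1)))
      (hits + 1) / (n_perm + 1)
    }, numeric(1)))
  }
  pv[const] <- 1
  pv <- pmin(pv, 1)
  data.frame(predictor = colnames(p_mat) %||% sprintf("x%02d", seq_len(ncol(p_mat))),
             rs = rs, p_rs = pv, q_rs = bh_adjust(pv),
             row.names = NULL, stringsAsFactors = FALSE)
}

# AIC of an OLS fit: n ln(RSS/n) + 2 (k + 1), k = number of predictors.
# `floor` is a numerical tie threshold: fits whose RSS is below it (an
# essentially exact fit at machine precision) are treated as equal, so the
# smaller model wins rather than chasing rounding noise.
ols_aic <- function(rss, n, k, floor = 0) n * log(max(rss, floor) / n) + 2 * (k + 1)

ols_rss <- function(y, xmat) {
  if (is.null(xmat) || ncol(xmat) == 0L) return(sum((y - mean(y))^2))
  fit <- .lm.fit(cbind(1, xmat), y)
  sum(fit$residuals^2)
}

#' Select a predictor subset by AIC and report the OLS fit
#'
#' Ordinary least squares with intercept; `AIC = n ln(RSS/n) + 2(k+1)`.
#' Strategy `"exhaustive"` enumerates all subsets (candidates <= 15),
#' `"stepwise"` runs bidirectional search from the intercept-only model
#' until no move improves AIC; `"auto"` picks exhaustive when feasible.
#' Ties in AIC go to the smaller model, then lexicographic order. Collinear
#' selected designs are repaired by dropping aliased columns (smallest
#' index kept, warning).
#'
#' @param response numeric vector.
#' @param candidates numeric matrix, cells x candidate predictors.
#' @param strategy `"auto"`, `"exhaustive"` or `"stepwise"`.
#' @return List of class `aic_fit`: `selected` (character), `coefficients`
#'   (data.frame predictor/beta/p_beta incl. intercept), `aic`, `r2_adj`,
#'   `f_stat`, `p_model`, `n`.
#' @export
aic_select <- function(response, candidates, strategy = c("auto", "exhaustive", "stepwise")) {
  strategy <- match.arg(strategy)
  xmat <- as.matrix(candidates)
  if (is.null(colnames(xmat))) colnames(xmat) <- sprintf("x%02d", seq_len(ncol(xmat)))
  y <- as.numeric(response)
  n <- length(y); m <- ncol(xmat)
  if (nrow(xmat) != n) bl_error("dim_mismatch", "candidate rows must match response")
  if (strategy == "auto") strategy <- if (m <= 15L) "exhaustive" else "stepwise"
  if (strategy == "exhaustive" && m > 15L)
    bl_error("too_many_candidates", "exhaustive search supports at most 15 candidates")
  if (strategy == "exhaustive" && n <= m + 2L) strategy <- "stepwise"
  rss_floor <- sum((y - mean(y))^2) * 1e-20

  best <- list(subset = integer(0),
               aic = ols_aic(ols_rss(y, NULL), n, 0, rss_floor))
  if (strategy == "exhaustive") {
    for (sz in seq_len(m)) {
      combs <- utils::combn(m, sz)
      for (ci in seq_len(ncol(combs))) {
        s <- combs[, ci]
        if (n <= length(s) + 2L) next
        a <- ols_aic(ols_rss(y, xmat[, s, drop = FALSE]), n, length(s), rss_floor)
        if (a < best$aic - 1e-10) best <- list(subset = s, aic = a)
      }
    }
  } else {
    current <- integer(0)
    current_aic <- best$aic
    repeat {
      moves <- list()
      for (j in setdiff(seq_len(m), current))
        if (n > length(current) + 3L)
          moves[[length(moves) + 1L]] <- sort(c(current, j))
      for (j in current)
        moves[[length(moves) + 1L]] <- setdiff(current, j)
      if (!length(moves)) break
      aics <- vapply(moves, function(s)
        ols_aic(ols_rss(y, if (length(s)) xmat[, s, drop = FALSE] else NULL),
                n, length(s), rss_floor), numeric(1))
      k <- which.min(aics)
      if (aics[k] < current_aic - 1e-10) {
        current <- moves[[k]]; current_aic <- aics[k]
      } else break
    }
    best <- list(subset = current, aic = current_aic)
  }
  fit_ols_report(y, xmat, best$subset)
}

fit_ols_report <- function(y, xmat, subset) {
  n <- length(y)
  sel_names <- colnames(xmat)[subset]
  if (length(subset)) {
    df <- as.data.frame(xmat[, subset, drop = FALSE])
    names(df) <- sel_names
    df$.y <- y
    fit <- lm(.y ~ ., data = df)
    if (anyNA(coef(fit))) {
      bl_warn("collinear selected design; dropping aliased predictor(s)")
      keep <- sel_names[!is.na(coef(fit))[-1]]
      subset <- subset[sel_names %in% keep]
      sel_names <- keep
      df <- as.data.frame(xmat[, subset, drop = FALSE]); names(df) <- sel_names
      df$.y <- y
      fit <- lm(.y ~ ., data = df)
    }
    sm <- summary(fit)
    coefs <- data.frame(predictor = rownames(sm$coefficients),
                        beta = sm$coefficients[, 1],
                        p_beta = sm$coefficients[, 4],
                        row.names = NULL, stringsAsFactors = FALSE)
    coefs$predictor[coefs$predictor == "(Intercept)"] <- "intercept"
    k <- length(subset)
    f_stat <- unname(sm$fstatistic[1])
    p_model <- pf(f_stat, k, n - k - 1, lower.tail = FALSE)
    r2_adj <- sm$adj.r.squared
    rss <- sum(fit$residuals^2)
  } else {
    coefs <- data.frame(predictor = "intercept", beta = mean(y),
                        p_beta = NA_real_, stringsAsFactors = FALSE)
    rss <- sum((y - mean(y))^2)
    r2_adj <- 0; f_stat <- NA_real_; p_model <- NA_real_
  }
  structure(list(selected = sel_names,
                 coefficients = coefs,
                 aic = ols_aic(rss, n, length(subset)),
                 r2_adj = r2_adj, f_stat = f_stat, p_model = p_model,
                 n = n),
            class = "aic_fit")
}

#' @export
print.aic_fit <- function(x, ...) {
  cat(sprintf("<aic_fit: %d predictor(s) selected, AIC %.3f, R2_adj %.3f, F %.3g, p %.3g>\n",
              length(x$selected), x$aic, x$r2_adj, x$f_stat, x$p_model))
  if (length(x$selected)) cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Associate a spike feature with a set of expression predictors
#'
#' Combines the per-predictor Spearman screen (with BH q-values over the
#' supplied family) and the AIC subset regression into one report.
#'
#' @param feature numeric per-cell feature (firing rate, rise time, ...).
#' @param predictors cells x predictors matrix (metagene expressions or
#'   gene z-scores).
#' @param strategy passed to [aic_select()].
#' @return An `association_result`: data.frame `table` (predictor, rs, p_rs,
#'   q_rs, selected, beta, p_beta) plus `model` (the `aic_fit`).
#' @export
feature_association <- function(feature, predictors, strategy = "auto") {
  sp <- spearman_assoc(feature, predictors)
  fit <- aic_select(feature, predictors, strategy = strategy)
  tab <- sp
  tab$selected <- tab$predictor %in% fit$selected
  bmap <- setNames(fit$coefficients$beta, fit$coefficients$predictor)
  pmap <- setNames(fit$coefficients$p_beta, fit$coefficients$predictor)
  tab$beta <- unname(bmap[tab$predictor])
  tab$p_beta <- unname(pmap[tab$predictor])
  structure(list(table = tab, model = fit), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  m <- x$model
  cat(sprintf("<association_result: %d predictors, %d selected; R2_adj %.3f, F %.3g, p %.3g>\n",
              nrow(x$table), length(m$selected), m$r2_adj, m$f_stat, m$p_model))
  top <- x$table[order(x$table$p_rs), ][seq_len(min(5, nrow(x$table))), ]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Gene-panel association of a spike feature
#'
#' Restricts the analysis to a named gene panel (e.g. the voltage-gated
#' sodium channel genes for spike rise times): Spearman screen with the BH
#' family equal to the panel size, plus AIC subset regression on the panel
#' columns. Panel genes missing from the matrix are listed and excluded
#' with a warning.
#'
#' @param feature numeric per-cell feature.
#' @param z a `z_matrix` (or cells x genes matrix with gene column names).
#' @param panel_gene_ids character vector of panel gene ids.
#' @param strategy passed to [aic_select()].
#' @return An `association_result` over the matched panel genes.
#' @export
gene_panel_association <- function(feature, z, panel_gene_ids, strategy = "auto") {
  v <- if (inherits(z, "z_matrix")) z$values else as.matrix(z)
  present <- panel_gene_ids %in% colnames(v)
  if (any(!present))
    bl_warn("panel gene(s) absent and excluded: %s",
            paste(panel_gene_ids[!present], collapse = ", "))
  panel <- panel_gene_ids[present]
  if (!length(panel)) bl_error("empty_panel", "no panel gene matches the matrix")
  feature_association(feature, v[, panel, drop = FALSE], strategy = strategy)
}
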