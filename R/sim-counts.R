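# Synthetic UMI counts with planted module-feature structure.

# Latent module score with exact sample-level coupling to a feature.
# u = standardized normal scores of the feature's ranks; the returned score
# has sample Pearson correlation with u equal to 2*sin(pi*rho/6) exactly
# (Gram-Schmidt), which pins the sample Spearman correlation with the
# feature at rho up to rank-discretisation error.
plant_module_score <- function(feature, rho) {
  n <- length(feature)
  if (n < 3) bl_error("too_few_cells", "need at least 3 cells to plant a correlation")
  u <- qnorm(rank(feature, ties.method = "average") / (n + 1))
  u <- u - mean(u); u <- u / sqrt(sum(u^2))
  e <- rnorm(n)
  e <- e - mean(e)
  e <- e - u * sum(u * e)
  e <- e / sqrt(sum(e^2))
  r <- 2 * sin(pi * rho / 6)
  z <- r * u + sqrt(1 - r^2) * e
  as.numeric(scale(z))
}

marker_classes <- c("housekeeping", "excitatory", "inhibitory", "non_neuronal")

# Gene table: ids, module assignment (a partition of all genes) and marker
# flags. Markers occupy the first rows, are spread round-robin over modules,
# and carry no module loading.
build_gene_table <- function(cfg) {
  n_mark <- cfg$n_marker_genes * length(marker_classes)
  if (n_mark >= cfg$n_genes)
    bl_error("bad_config", "marker genes (%d) must be fewer than n_genes", n_mark)
  marker_class <- rep(NA_character_, cfg$n_genes)
  if (cfg$n_marker_genes > 0)
    marker_class[seq_len(n_mark)] <- rep(marker_classes, each = cfg$n_marker_genes)
  is_marker <- !is.na(marker_class)
  module <- integer(cfg$n_genes)
  module[is_marker] <- rep_len(seq_len(cfg$n_modules), n_mark)
  n_rest <- cfg$n_genes - n_mark
  module[!is_marker] <- sort(rep_len(seq_len(cfg$n_modules), n_rest))
  ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))
  if (n_mark > 0) {
    short <- c(housekeeping = "Hk", excitatory = "Exc", inhibitory = "Inh",
               non_neuronal = "NonNeur")
    ids[is_marker] <- paste0(short[marker_class[is_marker]],
                             sequence(rep(cfg$n_marker_genes, length(marker_classes))))
  }
  data.frame(gene_id = ids, module = module, is_marker = is_marker,
             marker_class = marker_class, stringsAsFactors = FALSE)
}

#' Simulate a UMI count matrix with planted feature-expression structure
#'
#' Per-cell depths are lognormal (matched to `depth_mean`/`depth_sd`,
#' truncated at 1). Baseline gene abundances are lognormal. Each gene module
#' has a per-cell latent score; for modules named in `planted_assoc` the
#' score is coupled to the named spike feature by a Gaussian copula with
#' exact sample-level control of the planted rank correlation, otherwise it
#' is independent standard normal. Gene means are the per-cell depth times
#' softmax-normalized `abundance * exp(loading * score)`; counts are
#' negative binomial. Housekeeping/excitatory marker genes are high in all
#' cells; inhibitory/non-neuronal markers are near zero.
#'
#' @param features data.frame with columns `cell_id` and one column per
#'   feature named in `planted_assoc` (e.g. `firing_rate_hz`, `rise_ms`).
#' @param cfg a [sim_config()].
#' @param seed optional local seed.
#' @return A list with elements `counts` (a [count_matrix()]), `gene_info`
#'   (gene id, module, marker flags) and `module_scores` (cells x modules).
#' @export
simulate_counts <- function(features, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(features))
  n <- nrow(features)
  for (pa in cfg$planted_assoc)
    if (!pa$feature %in% names(features))
      bl_error("unknown_feature",
               "planted association names feature '%s' absent from ground truth",
               pa$feature)
  with_seed(seed, {
    cv2 <- (cfg$depth_sd / cfg$depth_mean)^2
    sdl <- sqrt(log(1 + cv2))
    depth <- pmax(1, round(rlnorm(n, log(cfg$depth_mean) - sdl^2 / 2, sdl)))
    genes <- build_gene_table(cfg)
    abun <- rlnorm(cfg$n_genes, 0, cfg$gene_abundance_sdlog)
    abun[which(genes$marker_class %in% c("housekeeping", "excitatory"))] <-
      abun[which(genes$marker_class %in% c("housekeeping", "excitatory"))] * 50
    abun[which(genes$marker_class %in% c("inhibitory", "non_neuronal"))] <-
      abun[which(genes$marker_class %in% c("inhibitory", "non_neuronal"))] * 1e-4
    planted_mod <- vapply(cfg$planted_assoc, function(p) as.integer(p$module), 1L)
    scores <- matrix(rnorm(n * cfg$n_modules), n, cfg$n_modules)
    for (pa in cfg$planted_assoc)
      scores[, pa$module] <- plant_module_score(features[[pa$feature]], pa$rho)
    loading <- ifelse(genes$is_marker, 0, cfg$module_loading)
    logmean <- matrix(log(abun), n, cfg$n_genes, byrow = TRUE) +
      scores[, genes$module, drop = FALSE] *
      matrix(loading, n, cfg$n_genes, byrow = TRUE)
    w <- exp(logmean)
    mu <- w / rowSums(w) * depth
    x <- matrix(rnbinom(n * cfg$n_genes, mu = mu, size = cfg$nb_dispersion),
                n, cfg$n_genes)
    cm <- count_matrix(x, genes$gene_id, as.character(features$cell_id))
    colnames(scores) <- sprintf("module_%02d", seq_len(cfg$n_modules))
    rownames(scores) <- cm$cell_ids
    list(counts = cm, gene_info = genes, module_scores = scores)
  })
}

#' Generate a full ground-truthed cohort
#'
#' Draws per-cell classes (exactly `round(frac_bursty * n_cells)` bursty
#' cells, shuffled), true firing rates (log-uniform over `rate_range_hz`)
#' and true rise times (uniform over `rise_range_ms`), simulates spike
#' trains, plants the module-feature correlations into a simulated count
#' matrix, and (optionally) synthesizes and writes voltage traces. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir if non-NULL, artifacts are written here: traces as
#'   `traces/cell_<k>.f32` + `.json` (when `write_traces`), counts as
#'   `matrix.mtx`/`genes.tsv`/`cells.tsv`, ground truth as `truth.tsv`.
#' @param write_traces whether to synthesize and write voltage traces
#'   (defaults to TRUE when `out_dir` is given; traces are never kept in
#'   memory for the whole cohort).
#' @return A list of class `cohort`: `truth` (per-cell data.frame with class,
#'   true rate, true rise, spike count), `spike_trains` (list), `counts`,
#'   `gene_info`, `module_scores`, `config`, and `trace_paths` (or NULL).
#' @export
generate_cohort <- function(cfg, out_dir = NULL,
                            write_traces = !is.null(out_dir)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (write_traces && is.null(out_dir))
    bl_error("bad_config", "write_traces requires out_dir")
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    n_bursty <- round(cfg$frac_bursty * n)
    classes <- sample(rep(c("bursty", "non_bursty"), c(n_bursty, n - n_bursty)))
    rates <- exp(runif(n, log(cfg$rate_range_hz[1]), log(cfg$rate_range_hz[2])))
    rises <- runif(n, cfg$rise_range_ms[1], cfg$rise_range_ms[2])
    cell_ids <- sprintf("cell_%03d", seq_len(n))
    trains <- vector("list", n)
    for (i in seq_len(n)) {
      trains[[i]] <- simulate_spike_train(classes[i], rates[i], cfg$duration_s,
                                          cfg$burst, cell_id = cell_ids[i])
    }
    names(trains) <- cell_ids
    truth <- data.frame(cell_id = cell_ids, class = classes,
                        firing_rate_hz = rates, rise_ms = rises,
                        n_spikes = vapply(trains, function(tr) tr$n_spikes, 1L),
                        stringsAsFactors = FALSE)
    sim <- simulate_counts(truth, cfg)
    trace_paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_counts(sim$counts, out_dir)
      write_table(truth, file.path(out_dir, "truth.tsv"))
      write_table(sim$gene_info, file.path(out_dir, "gene_truth.tsv"))
      if (write_traces) {
        tr_dir <- file.path(out_dir, "traces")
        dir.create(tr_dir, showWarnings = FALSE)
        trace_paths <- character(n)
        for (i in seq_len(n)) {
          tr <- synthesize_trace(trains[[i]], rises[i], cfg$spike_amp_mv,
                                 cfg$noise_sd_mv, cfg$fs_hz)
          trace_paths[i] <- file.path(tr_dir, paste0(cell_ids[i], ".f32"))
          write_trace(tr, trace_paths[i])
        }
      }
    }
    structure(list(truth = truth, spike_trains = trains, counts = sim$counts,
                   gene_info = sim$gene_info, module_scores = sim$module_scores,
                   config = cfg, trace_paths = trace_paths),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d cells (%d bursty), %d genes, %s traces>\n",
              nrow(x$truth), sum(x$truth$class == "bursty"),
              length(x$gene_info$gene_id),
              if (is.null(x$trace_paths)) "no" else length(x$trace_paths)))
  invisible(x)
}
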