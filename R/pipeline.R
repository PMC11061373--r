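# End-to-end pipeline: simulate (or load) -> spike features -> burstiness ->
# normalize -> differential expression -> metagenes -> association.
# Every stage writes a TSV so each step is independently re-runnable, plus a
# JSON provenance record (parameters, seeds, input hashes, package version).

#' Default pipeline configuration
#'
#' @param simulate a [sim_config()] (set to NULL to analyze existing inputs).
#' @param traces_dir,counts_path inputs when not simulating.
#' @param threshold_mv spike detection threshold.
#' @param cutoff_hz high-pass cutoff.
#' @param min_reads QC depth cutoff.
#' @param normalization `"logdepth"` or `"pearson"`.
#' @param k_metagenes number of metagenes.
#' @param strategy AIC search strategy.
#' @param panel gene ids for the rise-time panel association; NULL picks the
#'   first 11 genes of the modules planted against rise time when
#'   simulating (emulating an 11-gene channel panel), else skips the stage.
#' @param seed pipeline seed (burstiness restarts etc.).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(), traces_dir = NULL,
                            counts_path = NULL, threshold_mv = 0.5,
                            cutoff_hz = 500, min_reads = 5000,
                            normalization = "logdepth", k_metagenes = 25L,
                            strategy = "auto", panel = NULL, seed = 1L) {
  structure(list(simulate = simulate, traces_dir = traces_dir,
                 counts_path = counts_path, threshold_mv = threshold_mv,
                 cutoff_hz = cutoff_hz, min_reads = min_reads,
                 normalization = normalization,
                 k_metagenes = as.integer(k_metagenes),
                 strategy = strategy, panel = panel, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown fields are rejected with the offending field path; the
#' `simulate:` block takes [sim_config()] arguments (`planted_assoc` as a
#' list of module/feature/rho mappings).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "simulate")
  extra <- setdiff(names(raw), c(known, "simulate"))
  if (length(extra))
    bl_error("bad_config", "unknown config field(s): %s", paste(extra, collapse = ", "))
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$simulate)) {
    sim_known <- names(formals(sim_config))
    sim_extra <- setdiff(names(raw$simulate), sim_known)
    if (length(sim_extra))
      bl_error("bad_config", "unknown simulate field(s): %s",
               paste0("simulate.", sim_extra, collapse = ", "))
    sa <- raw$simulate
    for (nm in c("rate_range_hz", "rise_range_ms"))
      if (!is.null(sa[[nm]])) sa[[nm]] <- as.numeric(unlist(sa[[nm]]))
    args$simulate <- do.call(sim_config, sa)
  } else if (is.null(raw$counts_path)) {
    bl_error("bad_config", "config must set either 'simulate' or 'counts_path'")
  } else {
    args$simulate <- NULL
  }
  do.call(pipeline_config, args)
}

stage_provenance <- function(run_dir, stage, params, inputs = character(0)) {
  rec <- list(stage = stage, params = params,
              inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                                        basename(inputs))),
              package_version = as.character(utils::packageVersion("burstlink")))
  jsonlite::write_json(rec, file.path(run_dir, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: cohort simulation (or input loading),
#' per-neuron spike feature extraction, burstiness classification,
#' expression QC/normalization/z-scoring, bursty-vs-non-bursty differential
#' expression, metagene construction, and feature-expression association
#' (firing rate vs metagenes; rise time vs the gene panel). Each stage
#' writes its TSV and a JSON provenance record into `out_dir`. The run is a
#' pure function of (inputs, config, seeds): re-running with the same
#' configuration yields byte-identical outputs.
#'
#' @param config a `pipeline_config` or path to a YAML file.
#' @param out_dir run directory (created).
#' @return Invisibly, a list with the main in-memory results (`features`,
#'   `burstiness`, `de`, `assignment`, `metagenes`, `assoc_rate`,
#'   `assoc_rise`, `out_dir`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- stage 1: cohort ---------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate, out_dir = out_dir)
    trace_paths <- cohort$trace_paths
    counts <- cohort$counts
    stage_provenance(out_dir, "simulate",
                     params = list(seed = config$simulate$seed,
                                   n_cells = config$simulate$n_cells,
                                   n_genes = config$simulate$n_genes))
  } else {
    if (is.null(config$counts_path))
      bl_error("bad_config", "counts_path is required when not simulating")
    counts <- read_counts(config$counts_path)
    trace_paths <- if (!is.null(config$traces_dir))
      sort(list.files(config$traces_dir, pattern = "\\.f32$", full.names = TRUE))
    else NULL
    cohort <- NULL
  }

  # --- stage 2: spike features -------------------------------------------
  if (is.null(trace_paths)) bl_error("bad_config", "no traces available")
  feats <- lapply(trace_paths, function(p) {
    tr <- read_trace(p)
    extract_spike_features(tr, threshold_mv = config$threshold_mv,
                           cutoff_hz = config$cutoff_hz)$features
  })
  features <- do.call(rbind, feats)
  write_table(features, file.path(out_dir, "features.tsv"))
  stage_provenance(out_dir, "spikes",
                   params = list(threshold_mv = config$threshold_mv,
                                 cutoff_hz = config$cutoff_hz),
                   inputs = trace_paths)

  # --- stage 3: burstiness ------------------------------------------------
  isi_cols <- grep("^isi_bin_", names(features), value = TRUE)
  isi_mat <- as.matrix(features[, isi_cols])
  rownames(isi_mat) <- features$cell_id
  ok <- stats::complete.cases(isi_mat)
  bres <- fit_burstiness(isi_mat[ok, , drop = FALSE], seed = config$seed)
  btab <- bres$cells
  write_table(btab, file.path(out_dir, "burstiness.tsv"))
  stage_provenance(out_dir, "burst", params = list(seed = config$seed),
                   inputs = file.path(out_dir, "features.tsv"))

  # --- stage 4: expression ------------------------------------------------
  qc <- qc_filter(counts, min_reads = config$min_reads, drop_zero_genes = TRUE)
  norm <- normalize_counts(qc, method = config$normalization)
  z <- zscore_genes(norm)
  zdf <- data.frame(cell_id = qc$cell_ids, as.data.frame(z$values),
                    check.names = FALSE)
  write_table(zdf, file.path(out_dir, "zmat.tsv"))
  stage_provenance(out_dir, "normalize",
                   params = list(min_reads = config$min_reads,
                                 method = config$normalization))

  # align cells present in both modalities
  common <- intersect(qc$cell_ids, btab$cell_id)
  idx_expr <- match(common, qc$cell_ids)
  idx_feat <- match(common, features$cell_id)
  idx_b <- match(common, btab$cell_id)

  # --- stage 5: differential expression ------------------------------------
  qc_common <- count_matrix(qc$counts[idx_expr, , drop = FALSE])
  de <- de_test(qc_common, btab$is_bursty[idx_b])
  write_table(de, file.path(out_dir, "de.tsv"))
  stage_provenance(out_dir, "de", params = list(test = "poisson_lrt"))

  # --- stage 6: metagenes ---------------------------------------------------
  zc <- z$values[idx_expr, , drop = FALSE]
  d <- spearman_dissimilarity(zc)
  hc <- ward_cluster(d)
  assignment <- cut_to_metagenes(hc, k = config$k_metagenes)
  mg <- metagene_expression(zc, assignment)
  write_table(data.frame(gene_id = names(assignment),
                         metagene = as.integer(assignment),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "metagene_assignment.tsv"))
  write_table(data.frame(cell_id = common, as.data.frame(mg), check.names = FALSE),
              file.path(out_dir, "metagenes.tsv"))
  write_newick(hc, file.path(out_dir, "dendrogram.nwk"))
  stage_provenance(out_dir, "metagene", params = list(k = config$k_metagenes))

  # --- stage 7: association -------------------------------------------------
  rate <- features$firing_rate_hz[idx_feat]
  assoc_rate <- feature_association(rate, mg, strategy = config$strategy)
  tab_rate <- assoc_rate$table
  write_table(tab_rate, file.path(out_dir, "assoc_firing_rate.tsv"))
  panel <- config$panel
  if (is.null(panel) && !is.null(cohort)) {
    rise_modules <- vapply(Filter(function(p) p$feature == "rise_ms",
                                  config$simulate$planted_assoc),
                           function(p) as.integer(p$module), 1L)
    if (length(rise_modules)) {
      pool <- cohort$gene_info$gene_id[cohort$gene_info$module %in% rise_modules &
                                         !cohort$gene_info$is_marker]
      panel <- head(pool, 11L)
    }
  }
  assoc_rise <- NULL
  rise <- features$rise_ms[idx_feat]
  rise_ok <- is.finite(rise)
  if (!is.null(panel) && sum(rise_ok) >= 5) {
    assoc_rise <- gene_panel_association(rise[rise_ok],
                                         zc[rise_ok, , drop = FALSE], panel,
                                         strategy = config$strategy)
    write_table(assoc_rise$table, file.path(out_dir, "assoc_rise_panel.tsv"))
  }
  model_summaries <- list(
    firing_rate = assoc_rate$model[c("selected", "aic", "r2_adj", "f_stat", "p_model", "n")],
    rise_panel = if (!is.null(assoc_rise))
      assoc_rise$model[c("selected", "aic", "r2_adj", "f_stat", "p_model", "n")])
  jsonlite::write_json(model_summaries, file.path(out_dir, "assoc_models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_provenance(out_dir, "assoc",
                   params = list(strategy = config$strategy,
                                 panel = panel %||% NA))

  invisible(list(features = features, burstiness = bres, de = de,
                 assignment = assignment, metagenes = mg,
                 assoc_rate = assoc_rate, assoc_rise = assoc_rise,
                 out_dir = out_dir))
}
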