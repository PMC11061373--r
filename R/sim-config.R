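# Simulation configuration for ground-truthed synthetic cohorts.

#' Default burst parameters
#'
#' Within-burst inter-spike intervals follow a gamma distribution (shape 4,
#' mean 4 ms) truncated to 2-12 ms; burst sizes are geometric with mean 3
#' spikes; the absolute refractory period is 2 ms. These choices make the
#' short-ISI histogram of bursty cells clearly bimodal against tonic firing
#' at CA1-like rates.
#'
#' @return A named list of burst parameters.
#' @export
burst_params <- function() {
  list(isi_shape = 4, isi_mean_ms = 4, isi_min_ms = 2, isi_max_ms = 12,
       size_mean = 3, refractory_ms = 2)
}

#' Simulation configuration
#'
#' Defaults reproduce the study regime this package targets: 40 CA1
#' pyramidal neurons (17.5% bursty), firing rates spanning 0.019-1.87 Hz,
#' spike rise times 0.22-0.54 ms, 20 kHz traces, and a transcriptome of
#' 8,462 genes at a per-cell UMI depth of 50,457 +/- 13,599 grouped into 25
#' gene modules. Planted module-feature rank correlations default to the
#' reported regime: module 1 vs firing rate (rho 0.54), module 21 vs firing
#' rate (0.39), module 2 vs rise time (0.44), module 3 vs rise time (-0.42).
#'
#' @param n_cells,n_genes cohort dimensions.
#' @param fs_hz trace sampling rate (Hz).
#' @param duration_s trace length per cell in seconds.
#' @param frac_bursty fraction of bursty cells in `[0, 1]`.
#' @param rate_range_hz,rise_range_ms (low, high) bounds for true firing
#'   rates (drawn log-uniformly) and true rise times (uniform).
#' @param depth_mean,depth_sd per-cell total UMI depth (lognormal, truncated
#'   at 1).
#' @param n_modules number of planted gene modules.
#' @param planted_assoc list of `list(module=, feature=, rho=)` entries;
#'   `feature` is `"firing_rate_hz"` or `"rise_ms"`, `rho` in (-1, 1).
#' @param nb_dispersion negative-binomial size parameter for counts.
#' @param gene_abundance_sdlog lognormal sd of baseline gene abundance.
#' @param module_loading log-scale expression shift per unit module score.
#' @param n_marker_genes marker genes per class (housekeeping, excitatory,
#'   inhibitory, non-neuronal) emulating standard cell-type QC panels.
#' @param noise_sd_mv trace noise standard deviation (mV), band-limited
#'   below 5 kHz.
#' @param spike_amp_mv spike peak amplitude (mV); recordings are kept only
#'   while spikes exceed 1.5 mV, so the default is 2.
#' @param burst within-burst firing parameters, see [burst_params()].
#' @param seed integer RNG seed.
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_cells = 40L, n_genes = 8462L, fs_hz = 20000,
                       duration_s = 600, frac_bursty = 0.175,
                       rate_range_hz = c(0.019, 1.87),
                       rise_range_ms = c(0.22, 0.54),
                       depth_mean = 50457, depth_sd = 13599,
                       n_modules = 25L,
                       planted_assoc = list(
                         list(module = 1L,  feature = "firing_rate_hz", rho = 0.54),
                         list(module = 21L, feature = "firing_rate_hz", rho = 0.39),
                         list(module = 2L,  feature = "rise_ms",        rho = 0.44),
                         list(module = 3L,  feature = "rise_ms",        rho = -0.42)),
                       nb_dispersion = 10,
                       gene_abundance_sdlog = 0.75,
                       module_loading = 1.0,
                       n_marker_genes = 5L,
                       noise_sd_mv = 0.05, spike_amp_mv = 2.0,
                       burst = burst_params(), seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              fs_hz = fs_hz, duration_s = duration_s,
              frac_bursty = frac_bursty, rate_range_hz = rate_range_hz,
              rise_range_ms = rise_range_ms, depth_mean = depth_mean,
              depth_sd = depth_sd, n_modules = as.integer(n_modules),
              planted_assoc = planted_assoc, nb_dispersion = nb_dispersion,
              gene_abundance_sdlog = gene_abundance_sdlog,
              module_loading = module_loading,
              n_marker_genes = as.integer(n_marker_genes),
              noise_sd_mv = noise_sd_mv, spike_amp_mv = spike_amp_mv,
              burst = burst, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$frac_bursty < 0 || cfg$frac_bursty > 1)
    bl_error("bad_config", "frac_bursty must be in [0, 1]")
  for (nm in c("rate_range_hz", "rise_range_ms")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || r[1] > r[2] || any(r <= 0))
      bl_error("bad_config", "%s must be positive with low <= high", nm)
  }
  if (cfg$n_modules > cfg$n_genes)
    bl_error("bad_config", "n_modules must not exceed n_genes")
  if (cfg$n_cells < 1 || cfg$n_genes < 1)
    bl_error("bad_config", "n_cells and n_genes must be positive")
  for (pa in cfg$planted_assoc) {
    if (abs(pa$rho) >= 1) bl_error("bad_config", "planted rho must lie in (-1, 1)")
    if (pa$module < 1 || pa$module > cfg$n_modules)
      bl_error("bad_config", "planted module %s out of range", pa$module)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config: %d cells (%.1f%% bursty) x %d genes, %g s @ %g Hz,\n",
                     "  depth %g +/- %g, %d modules, %d planted associations, seed %d>\n"),
              x$n_cells, 100 * x$frac_bursty, x$n_genes, x$duration_s, x$fs_hz,
              x$depth_mean, x$depth_sd, x$n_modules, length(x$planted_assoc), x$seed))
  invisible(x)
}
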