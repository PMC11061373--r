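# Spike detection and per-neuron spike features.
#
# Detection follows the juxtacellular convention: high-pass filter at
# 500 Hz, take the Hilbert envelope, threshold its local maxima (0.25-1 mV
# by policy), and snap each detection to the filtered-trace peak nearby.

#' Detect spikes by Hilbert-envelope thresholding
#'
#' Candidate spikes are local maxima of the envelope of the analytic signal
#' of the (already high-pass filtered) trace that exceed `threshold_mv`.
#' Within any refractory window only the largest envelope peak is kept. The
#' reported spike peak time is the time of the maximum of the filtered trace
#' within +/-0.5 ms of the envelope peak.
#'
#' @param filtered a high-pass filtered [voltage_trace()] (see [highpass()]).
#' @param threshold_mv detection threshold in mV; the working policy range
#'   for these recordings is 0.25-1 mV.
#' @param refractory_ms minimal separation between detections (default 2 ms).
#' @param snap_ms half-width of the envelope-to-filtered-peak snap window.
#' @param envelope_method passed to [hilbert_envelope()].
#' @return A [spike_train()] with `threshold_mv` recorded.
#' @export
detect_spikes <- function(filtered, threshold_mv, refractory_ms = 2,
                          snap_ms = 0.5, envelope_method = "fir") {
  filtered <- as_voltage_trace(filtered)
  if (length(filtered$samples) == 0)
    bl_error("empty_trace", "cannot detect spikes in an empty trace")
  if (threshold_mv <= 0) bl_error("bad_threshold", "threshold must be positive")
  fs <- filtered$fs_hz
  env <- hilbert_envelope(filtered$samples, method = envelope_method)
  cand <- cpp_local_maxima(env, threshold_mv)
  if (length(cand) == 0)
    return(spike_train(numeric(0), trace_duration(filtered),
                       filtered$cell_id, threshold_mv))
  refr_n <- refractory_ms / 1000 * fs
  # keep-the-largest within any refractory window: visit by envelope height
  ord <- cand[order(env[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= refr_n)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  snap_n <- round(snap_ms / 1000 * fs)
  x <- filtered$samples
  peaks <- vapply(kept, function(i) {
    lo <- max(1L, i - snap_n); hi <- min(length(x), i + snap_n)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) > 1) {
    d <- diff(peaks)
    while (any(d < refr_n)) {  # snapping can collapse neighbours below refractory
      j <- which(d < refr_n)[1]
      drop <- if (env[peaks[j]] >= env[peaks[j + 1]]) j + 1L else j
      peaks <- peaks[-drop]
      if (length(peaks) < 2) break
      d <- diff(peaks)
    }
  }
  spike_train((peaks - 1L) / fs, trace_duration(filtered),
              filtered$cell_id, threshold_mv)
}

#' Average raw spike waveforms aligned on detected peaks
#'
#' Raw (unfiltered) segments are cut around each spike peak time, aligned on
#' the peak sample, and averaged arithmetically. Spikes closer to the trace
#' edges than the window are skipped.
#'
#' @param raw_trace the unfiltered [voltage_trace()].
#' @param train a [spike_train()] of detected peak times.
#' @param window_ms `(pre, post)` window around the peak in ms.
#' @return An object of class `averaged_waveform`: `mean_trace`,
#'   `window_ms`, `n_spikes_averaged`, `fs_hz`, `peak_index`.
#' @export
average_waveform <- function(raw_trace, train, window_ms = c(3, 3)) {
  raw_trace <- as_voltage_trace(raw_trace)
  stopifnot(inherits(train, "spike_train"))
  if (train$n_spikes < 1) bl_error("no_spikes_in_window", "spike train is empty")
  fs <- raw_trace$fs_hz
  pre_n <- round(window_ms[1] / 1000 * fs)
  post_n <- round(window_ms[2] / 1000 * fs)
  n <- length(raw_trace$samples)
  pk <- round(train$peak_times_s * fs) + 1L
  usable <- pk - pre_n >= 1L & pk + post_n <= n
  if (!any(usable))
    bl_error("no_spikes_in_window", "no spike fits the %g/%g ms window",
             window_ms[1], window_ms[2])
  pk <- pk[usable]
  acc <- numeric(pre_n + post_n + 1L)
  for (p in pk) acc <- acc + raw_trace$samples[(p - pre_n):(p + post_n)]
  structure(list(mean_trace = acc / length(pk), window_ms = window_ms,
                 n_spikes_averaged = length(pk), fs_hz = fs,
                 peak_index = pre_n + 1L, cell_id = raw_trace$cell_id),
            class = "averaged_waveform")
}

#' Spike rise time from an averaged waveform
#'
#' Baseline voltage statistics are taken 0.5-2.0 ms before the peak
#' (half-open window `[-2.0, -0.5)` ms). The onset is the first sample at or
#' after -0.5 ms, scanning forward toward the peak, whose value strictly
#' exceeds baseline mean + 1 SD; the rise time is peak time minus onset
#' time, reported at sample resolution.
#'
#' @param avg an `averaged_waveform` whose window covers at least 2 ms
#'   before the peak.
#' @param baseline_ms `(far, near)` baseline bounds in ms before the peak.
#' @return A list of class `rise_time_result`: `rise_ms`, `onset_index`,
#'   `baseline_mean_mv`, `baseline_sd_mv`, `threshold_mv`.
#' @export
rise_time <- function(avg, baseline_ms = c(2.0, 0.5)) {
  stopifnot(inherits(avg, "averaged_waveform"))
  fs <- avg$fs_hz
  pk <- avg$peak_index
  t_rel_ms <- (seq_along(avg$mean_trace) - pk) / fs * 1000
  if (min(t_rel_ms) > -baseline_ms[1])
    bl_error("window_too_short", "waveform window must cover %g ms before the peak",
             baseline_ms[1])
  base_idx <- which(t_rel_ms >= -baseline_ms[1] & t_rel_ms < -baseline_ms[2])
  bmean <- mean(avg$mean_trace[base_idx])
  bsd <- sd(avg$mean_trace[base_idx])
  thr <- bmean + bsd
  scan_idx <- which(t_rel_ms >= -baseline_ms[2] & t_rel_ms < 0)
  above <- avg$mean_trace[scan_idx] > thr
  if (!any(above))
    bl_error("onset_not_found", "no sample exceeds baseline mean + 1 SD before the peak")
  onset <- scan_idx[which(above)[1]]
  structure(list(rise_ms = (pk - onset) / fs * 1000, onset_index = onset,
                 baseline_mean_mv = bmean, baseline_sd_mv = bsd,
                 threshold_mv = thr),
            class = "rise_time_result")
}

#' Mean firing rate of a spike train
#'
#' @param train a [spike_train()].
#' @return Spike count divided by duration, in Hz.
#' @export
firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (train$duration_s <= 0) bl_error("bad_duration", "duration must be positive")
  train$n_spikes / train$duration_s
}

#' Short-ISI histogram vector
#'
#' Histogram of consecutive inter-spike intervals below `max_isi_ms`
#' (half-open bins of width `bin_ms`, default 30 bins over `[0, 15)` ms),
#' normalized by the neuron's total ISI count so that the vector sums to the
#' fraction of ISIs shorter than `max_isi_ms` (set `normalize = FALSE` for
#' raw counts).
#'
#' @param train a [spike_train()] with at least 2 spikes.
#' @param max_isi_ms,bin_ms histogram range and bin width in ms.
#' @param normalize divide by the total number of ISIs (default TRUE).
#' @return Numeric vector of length `max_isi_ms / bin_ms`.
#' @export
isi_vector <- function(train, max_isi_ms = 15, bin_ms = 0.5, normalize = TRUE) {
  stopifnot(inherits(train, "spike_train"))
  if (train$n_spikes < 2)
    bl_error("too_few_spikes", "need at least 2 spikes for an ISI vector")
  isi_ms <- diff(train$peak_times_s) * 1000
  n_bins <- as.integer(round(max_isi_ms / bin_ms))
  idx <- floor(isi_ms / bin_ms) + 1L
  idx <- idx[isi_ms >= 0 & isi_ms < max_isi_ms]
  v <- tabulate(idx, nbins = n_bins)
  if (normalize) v <- v / length(isi_ms)
  as.numeric(v)
}

#' Per-neuron spike features from a raw trace
#'
#' Convenience wrapper running the full spike-analysis chain on one neuron:
#' high-pass filter, envelope detection, raw-waveform averaging, rise time,
#' firing rate and the 30-bin short-ISI vector.
#'
#' @param raw_trace a raw [voltage_trace()].
#' @param threshold_mv detection threshold (mV).
#' @param cutoff_hz high-pass cutoff.
#' @param refractory_ms detection refractory period.
#' @param envelope_method passed to [hilbert_envelope()].
#' @return A list with `spike_train`, `features` (one-row data.frame:
#'   cell_id, n_spikes, firing_rate_hz, rise_ms, isi_bin_00..29; rise is NA
#'   when fewer than one usable spike) .
#' @export
extract_spike_features <- function(raw_trace, threshold_mv = 0.5,
                                   cutoff_hz = 500, refractory_ms = 2,
                                   envelope_method = "fir") {
  raw_trace <- as_voltage_trace(raw_trace)
  filt <- highpass(raw_trace, cutoff_hz)
  train <- detect_spikes(filt, threshold_mv, refractory_ms,
                         envelope_method = envelope_method)
  rate <- firing_rate(train)
  rise <- NA_real_
  if (train$n_spikes >= 1) {
    avg <- tryCatch(average_waveform(raw_trace, train), bl_error = function(e) NULL)
    if (!is.null(avg))
      rise <- tryCatch(rise_time(avg)$rise_ms, bl_error = function(e) NA_real_)
  }
  iv <- if (train$n_spikes >= 2) isi_vector(train) else rep(NA_real_, 30L)
  feat <- data.frame(cell_id = raw_trace$cell_id, n_spikes = train$n_spikes,
                     firing_rate_hz = rate, rise_ms = rise,
                     stringsAsFactors = FALSE)
  feat[sprintf("isi_bin_%02d", 0:29)] <- as.list(iv)
  list(spike_train = train, features = feat)
}
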