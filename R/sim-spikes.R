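# Spike train and voltage trace synthesis.

#' Construct a spike train
#'
#' @param peak_times_s strictly increasing spike peak times in seconds,
#'   all in `[0, duration_s)`.
#' @param duration_s recording duration in seconds.
#' @param cell_id identifier.
#' @param threshold_mv detection threshold that produced the train (NA for
#'   simulated ground truth).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(peak_times_s, duration_s, cell_id = "cell",
                        threshold_mv = NA_real_) {
  peak_times_s <- as.numeric(peak_times_s)
  if (is.unsorted(peak_times_s, strictly = TRUE))
    bl_error("unsorted_spikes", "spike times must be strictly increasing")
  if (length(peak_times_s) &&
      (peak_times_s[1] < 0 || peak_times_s[length(peak_times_s)] >= duration_s))
    bl_error("spikes_out_of_range", "spike times must lie in [0, duration_s)")
  structure(list(cell_id = as.character(cell_id),
                 peak_times_s = peak_times_s,
                 threshold_mv = threshold_mv,
                 n_spikes = length(peak_times_s),
                 duration_s = as.numeric(duration_s)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s: %d spikes over %g s (%.3g Hz)>\n",
              x$cell_id, x$n_spikes, x$duration_s, x$n_spikes / x$duration_s))
  invisible(x)
}

#' Simulate a spike train of a bursty or non-bursty neuron
#'
#' Non-bursty neurons fire as a homogeneous Poisson process thinned by an
#' absolute refractory period. Bursty neurons fire bursts whose onsets form
#' a Poisson process with rate `rate_hz / mean burst size`; each burst holds
#' a geometric number of spikes (mean `size_mean`) separated by gamma
#' within-burst ISIs (mean 4 ms, truncated to 2-12 ms). The realized overall
#' rate is within 20% of `rate_hz` in expectation.
#'
#' @param class_label `"bursty"` or `"non_bursty"`.
#' @param rate_hz target overall firing rate (> 0).
#' @param duration_s recording duration (seconds).
#' @param burst burst parameters, see [burst_params()].
#' @param cell_id identifier.
#' @param seed optional local seed (see [with_seed()]).
#' @return A [spike_train()] with sorted times in `[0, duration_s)`.
#' @export
simulate_spike_train <- function(class_label = c("non_bursty", "bursty"),
                                 rate_hz, duration_s, burst = burst_params(),
                                 cell_id = "cell", seed = NULL) {
  class_label <- match.arg(class_label)
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    bl_error("bad_rate", "rate_hz must be positive")
  refr_s <- burst$refractory_ms / 1000
  if (duration_s <= refr_s)
    bl_error("duration_too_short",
             "duration %g s cannot hold one refractory period (%g s)",
             duration_s, refr_s)
  with_seed(seed, {
    if (class_label == "non_bursty") {
      n <- rpois(1, rate_hz * duration_s)
      times <- sort(runif(n, 0, duration_s))
    } else {
      onset_rate <- rate_hz / burst$size_mean
      n_on <- rpois(1, onset_rate * duration_s)
      onsets <- sort(runif(n_on, 0, duration_s))
      scale_ms <- burst$isi_mean_ms / burst$isi_shape
      times <- unlist(lapply(onsets, function(t0) {
        sz <- rgeom(1, 1 / burst$size_mean) + 1L
        if (sz == 1L) return(t0)
        isi <- rgamma(sz - 1L, shape = burst$isi_shape, scale = scale_ms)
        isi <- pmin(pmax(isi, burst$isi_min_ms), burst$isi_max_ms)
        t0 + c(0, cumsum(isi)) / 1000
      }))
      times <- sort(times)
    }
    times <- thin_refractory(times, refr_s)
    times <- times[times >= 0 & times < duration_s]
    spike_train(times, duration_s, cell_id)
  })
}

thin_refractory <- function(times, refr_s) {
  if (length(times) < 2) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refr_s) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

# Continuous spike shape relative to the peak (t_rel in ms): linear rise
# from 0 over rise_ms up to amp, exponential decay (tau_ms) after the peak
# with a small negative Gaussian afterwave.
spike_shape <- function(t_rel_ms, rise_ms, amp_mv, tau_ms = 0.5,
                        after_frac = 0.15, after_center_ms = 1.5,
                        after_sd_ms = 0.4) {
  v <- numeric(length(t_rel_ms))
  rising <- t_rel_ms >= -rise_ms & t_rel_ms <= 0
  v[rising] <- amp_mv * (1 + t_rel_ms[rising] / rise_ms)
  post <- t_rel_ms > 0
  v[post] <- amp_mv * exp(-t_rel_ms[post] / tau_ms)
  v[post] <- v[post] - after_frac * amp_mv *
    exp(-0.5 * ((t_rel_ms[post] - after_center_ms) / after_sd_ms)^2)
  v
}

#' Synthesize a raw voltage trace from a spike train
#'
#' Each spike is rendered as a piecewise template: baseline, monotone linear
#' rise of duration `rise_ms` to a peak of `amp_mv` that falls exactly on
#' the sample grid (spike time rounded to the nearest sample), exponential
#' decay (tau 0.5 ms) with a small negative afterwave. Additive Gaussian
#' noise is band-limited below 5 kHz and rescaled to `noise_sd_mv`.
#'
#' @param train a [spike_train()].
#' @param rise_ms true rise time in ms (must be resolvable: at least two
#'   sample periods).
#' @param amp_mv peak amplitude in mV.
#' @param noise_sd_mv noise standard deviation in mV (0 for noiseless).
#' @param fs_hz sampling rate.
#' @param tau_ms decay time constant.
#' @param seed optional local seed.
#' @return A [voltage_trace()] of `round(duration_s * fs_hz)` samples.
#' @export
synthesize_trace <- function(train, rise_ms, amp_mv = 2.0, noise_sd_mv = 0.05,
                             fs_hz = 20000, tau_ms = 0.5, seed = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (rise_ms < 2000 / fs_hz)
    bl_error("rise_unresolvable",
             "rise_ms = %g is below two sample periods (%g ms) at %g Hz",
             rise_ms, 2000 / fs_hz, fs_hz)
  n <- round(train$duration_s * fs_hz)
  with_seed(seed, {
    x <- if (noise_sd_mv > 0) {
      w <- rnorm(n)
      lp <- butter_coefs(5000, fs_hz, "low")
      w <- iir_once(lp, w)
      w * (noise_sd_mv / sd(w))
    } else numeric(n)
    pre_n <- ceiling(rise_ms / 1000 * fs_hz)
    post_n <- ceiling(6 / 1000 * fs_hz)  # decay + afterwave support
    for (t in train$peak_times_s) {
      pk <- round(t * fs_hz) + 1L
      i0 <- max(1L, pk - pre_n); i1 <- min(n, pk + post_n)
      if (i0 > n || i1 < 1L) next
      idx <- i0:i1
      t_rel_ms <- (idx - pk) / fs_hz * 1000
      x[idx] <- x[idx] + spike_shape(t_rel_ms, rise_ms, amp_mv, tau_ms)
    }
    voltage_trace(x, fs_hz, train$cell_id)
  })
}
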