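test_that("high-pass filter rejects DC and low frequencies, passes spike band", {
  fs <- 20000
  t <- seq(0, 1, by = 1 / fs)[-1]

  const <- voltage_trace(rep(0.7, 4000), fs)
  expect_lt(max(abs(highpass(const)$samples)), 1e-9)

  mid <- 2000:18000  # interior samples, away from filter edges
  s50 <- voltage_trace(sin(2 * pi * 50 * t), fs)
  g50 <- sqrt(mean(highpass(s50)$samples[mid]^2)) / sqrt(0.5)
  expect_lt(20 * log10(g50), -40)

  s2k <- voltage_trace(sin(2 * pi * 2000 * t), fs)
  g2k <- sqrt(mean(highpass(s2k)$samples[mid]^2)) / sqrt(0.5)
  expect_gt(20 * log10(g2k), -1)

  expect_error(highpass(voltage_trace(rnorm(100), 1000), cutoff_hz = 600),
               class = "bad_cutoff")
})

test_that("high-pass is idempotent within 1% energy on filtered signals", {
  x <- with_seed(2, voltage_trace(rnorm(20000), 20000))
  once <- highpass(x)
  twice <- highpass(once)
  mid <- 2000:18000
  e1 <- sum(once$samples[mid]^2)
  e2 <- sum(twice$samples[mid]^2)
  expect_lt(abs(e2 - e1) / e1, 0.01)
})

test_that("FIR and FFT envelopes agree on band-limited signals", {
  x <- with_seed(3, {
    tr <- simulate_spike_train("non_bursty", 5, 5)
    synthesize_trace(tr, 0.3, 2, 0.05)
  })
  f <- highpass(x)$samples
  e_fir <- hilbert_envelope(f, "fir")
  e_fft <- hilbert_envelope(f, "fft")
  mid <- 300:(length(f) - 300)
  expect_lt(max(abs(e_fir[mid] - e_fft[mid])) / max(e_fft), 5e-3)
  # envelope dominates the rectified signal
  expect_true(all(e_fft >= abs(f) - 1e-9))
})

test_that("detection finds planted spikes and applies the refractory rule", {
  z <- voltage_trace(numeric(20000), 20000)
  expect_equal(detect_spikes(highpass(z), 0.5)$n_spikes, 0)
  expect_error(detect_spikes(voltage_trace(numeric(0), 20000), 0.5),
               class = "empty_trace")

  truth <- seq(0.1, 1.9, by = 0.2)  # 10 spikes
  tr <- spike_train(truth, 2)
  v <- synthesize_trace(tr, 0.3, 2, 0.05, seed = 11)
  det <- detect_spikes(highpass(v), 0.5)
  expect_equal(det$n_spikes, 10)
  expect_true(all(abs(det$peak_times_s - truth) <= 1e-4))

  # two spikes 1 ms apart collapse to one detection (2 ms refractory)
  close2 <- synthesize_trace(spike_train(c(0.05, 0.051), 0.1), 0.3, 2, 0, seed = 1)
  expect_equal(detect_spikes(highpass(close2), 0.5)$n_spikes, 1)
})

test_that("averaged waveform equals the template for identical noiseless spikes", {
  truth <- seq(0.05, 0.95, by = 0.1)
  v <- synthesize_trace(spike_train(truth, 1), 0.4, 2, 0)
  det <- detect_spikes(highpass(v), 0.5)
  avg <- average_waveform(v, det)
  expect_equal(avg$n_spikes_averaged, length(truth))
  # the mean equals any single aligned raw segment
  pk <- round(det$peak_times_s[4] * 20000) + 1
  seg <- v$samples[(pk - avg$peak_index + 1):(pk - avg$peak_index + length(avg$mean_trace))]
  expect_equal(avg$mean_trace, seg, tolerance = 1e-12)
  # peak sits at the alignment sample
  expect_lte(abs(which.max(avg$mean_trace) - avg$peak_index), 1)

  # a spike too close to the edge is skipped
  v2 <- synthesize_trace(spike_train(c(0.001, 0.5), 1), 0.4, 2, 0)
  det2 <- detect_spikes(highpass(v2), 0.5)
  avg2 <- average_waveform(v2, det2)
  expect_equal(avg2$n_spikes_averaged, det2$n_spikes - 1)

  expect_error(average_waveform(v, spike_train(numeric(0), 1)),
               class = "no_spikes_in_window")
})

test_that("averaging suppresses noise at the 1/sqrt(n) rate", {
  sigma <- 0.1
  truth <- seq(0.05, 9.95, by = 0.1)  # 100 spikes
  v <- synthesize_trace(spike_train(truth, 10), 0.4, 2, sigma, seed = 12)
  v0 <- synthesize_trace(spike_train(truth, 10), 0.4, 2, 0)
  det <- detect_spikes(highpass(v), 0.5)
  avg <- average_waveform(v, det)
  avg0 <- average_waveform(v0, spike_train(truth, 10))
  resid_sd <- sd(avg$mean_trace - avg0$mean_trace)
  expect_equal(resid_sd, sigma / sqrt(avg$n_spikes_averaged), tolerance = 0.3)
})

test_that("rise time follows the onset definition at sample resolution", {
  fs <- 20000
  # linear ramp starting at -0.4 ms, zero baseline: estimate = 0.4 - 0.05 ms
  n <- 121; pk <- 81
  w <- numeric(n)
  ramp <- (pk - 8):pk  # 8 samples = 0.4 ms
  w[ramp] <- seq(0, 2, length.out = 9)
  w[pk:n] <- 2 * exp(-((pk:n) - pk) / 10)
  avg <- structure(list(mean_trace = w, window_ms = c(4, 2), fs_hz = fs,
                        peak_index = pk, n_spikes_averaged = 1, cell_id = "x"),
                   class = "averaged_waveform")
  rt <- rise_time(avg)
  expect_equal(rt$rise_ms, 0.35)

  flat <- structure(list(mean_trace = numeric(n), window_ms = c(4, 2), fs_hz = fs,
                         peak_index = pk, n_spikes_averaged = 1, cell_id = "x"),
                    class = "averaged_waveform")
  expect_error(rise_time(flat), class = "onset_not_found")

  short <- structure(list(mean_trace = w[61:n], window_ms = c(1, 2), fs_hz = fs,
                          peak_index = 21, n_spikes_averaged = 1, cell_id = "x"),
                     class = "averaged_waveform")
  expect_error(rise_time(short), class = "window_too_short")
})

test_that("rise-time estimates on noiseless templates err by at most one sample", {
  for (rise in c(0.2, 0.22, 0.31, 0.4, 0.47, 0.54, 0.6)) {
    v <- synthesize_trace(spike_train(0.05, 0.1), rise, 2, 0)
    det <- detect_spikes(highpass(v), 0.5)
    est <- rise_time(average_waveform(v, det))$rise_ms
    expect_lte(abs(est - min(rise, 0.5)), 0.05 + 1e-9,
               label = sprintf("rise %g est %g", rise, est))
  }
})

test_that("firing rate is count over duration", {
  tr <- spike_train(seq(0.5, 59.5, by = 1), 60)
  expect_equal(firing_rate(tr), 1)
  expect_equal(firing_rate(spike_train(numeric(0), 600)), 0)
  expect_error(firing_rate(spike_train(numeric(0), 0)), class = "bad_duration")

  # Poisson train at the top of the study range: estimate within 3 SE
  tr2 <- simulate_spike_train("non_bursty", 1.87, 600, seed = 13)
  se <- sqrt(1.87 / 600)
  expect_lt(abs(firing_rate(tr2) - 1.87), 3 * se)
})

test_that("ISI vector bins, normalizes and bounds correctly", {
  tr <- spike_train(seq(0, 0.9, by = 0.1), 1)  # all ISIs 100 ms
  expect_equal(isi_vector(tr), rep(0, 30))

  # ISIs 1, 1, 14.9, 20 ms
  tms <- cumsum(c(0, 1, 1, 14.9, 20)) / 1000
  tr2 <- spike_train(tms, 1)
  v <- isi_vector(tr2)
  expect_equal(v[3], 0.5)    # two 1 ms ISIs in [1.0, 1.5)
  expect_equal(v[30], 0.25)  # 14.9 ms in [14.5, 15)
  expect_equal(sum(v), 0.75)
  expect_equal(sum(isi_vector(tr2, normalize = FALSE)), 3)

  # exactly 15 ms is excluded (half-open bins)
  tr3 <- spike_train(c(0, 0.015, 0.03), 1)
  expect_equal(sum(isi_vector(tr3)), 0)

  expect_error(isi_vector(spike_train(0.1, 1)), class = "too_few_spikes")

  # property: non-negative, sums to at most 1
  v4 <- isi_vector(simulate_spike_train("bursty", 1, 300, seed = 14))
  expect_true(all(v4 >= 0))
  expect_lte(sum(v4), 1)
})

test_that("extract_spike_features assembles the per-neuron feature row", {
  tr <- simulate_spike_train("non_bursty", 1, 30, seed = 15)
  v <- synthesize_trace(tr, 0.35, 2, 0.05, seed = 16)
  out <- extract_spike_features(v)
  expect_equal(out$spike_train$n_spikes, tr$n_spikes)
  expect_equal(out$features$firing_rate_hz, tr$n_spikes / 30)
  # the 1-SD onset rule can trigger early on baseline noise, so the estimate
  # is bounded by [true - one sample, scan window end]
  expect_gte(out$features$rise_ms, 0.35 - 0.05)
  expect_lte(out$features$rise_ms, 0.5)
  expect_length(grep("^isi_bin_", names(out$features)), 30)
})
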