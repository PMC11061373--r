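test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_bursty = 1.2), class = "bad_config")
  expect_error(sim_config(rate_range_hz = c(2, 1)), class = "bad_config")
  expect_error(sim_config(n_modules = 50, n_genes = 10), class = "bad_config")
  expect_error(sim_config(planted_assoc = list(list(module = 1, feature = "firing_rate_hz",
                                                    rho = 1.0))),
               class = "bad_config")
})

test_that("spike train simulation hits the requested rate and respects bounds", {
  expect_error(simulate_spike_train("non_bursty", 0, 600), class = "bad_rate")
  expect_error(simulate_spike_train("non_bursty", 1, 0.001), class = "duration_too_short")

  # determinism
  a <- simulate_spike_train("bursty", 1, 60, seed = 42)
  b <- simulate_spike_train("bursty", 1, 60, seed = 42)
  expect_identical(a$peak_times_s, b$peak_times_s)

  # law of large numbers: realized rate within 5% over 100 trains
  for (cls in c("non_bursty", "bursty")) {
    n <- with_seed(99, sum(vapply(1:100, function(i)
      simulate_spike_train(cls, 1.0, 100)$n_spikes, 1L)))
    expect_gt(n / (100 * 100), 0.95)
    expect_lt(n / (100 * 100), 1.05)
  }

  tr <- simulate_spike_train("bursty", 1.5, 300, seed = 7)
  expect_false(is.unsorted(tr$peak_times_s, strictly = TRUE))
  expect_true(all(tr$peak_times_s >= 0 & tr$peak_times_s < 300))
  expect_true(all(diff(tr$peak_times_s) >= 0.002 - 1e-12))
})

test_that("short-ISI content separates the two firing phenotypes", {
  # non-bursty at 1 Hz: exponential ISIs give P(ISI < 15 ms) = 1 - e^-0.015
  nb <- with_seed(3, {
    isi <- unlist(lapply(1:50, function(i)
      diff(simulate_spike_train("non_bursty", 1, 600)$peak_times_s)))
    mean(isi < 0.015)
  })
  expect_equal(nb, 1 - exp(-0.015), tolerance = 0.35)  # ~1.5%, thinning-adjusted
  expect_lt(nb, 0.05)

  # bursty: geometric bursts of mean 3 with 2-12 ms ISIs put >= 40% of ISIs
  # under 15 ms at any onset rate <= 1 Hz
  bf <- with_seed(4, vapply(1:20, function(i)
    sum(isi_vector(simulate_spike_train("bursty", 1, 600))), numeric(1)))
  expect_true(all(bf >= 0.4))
})

test_that("trace synthesis renders templates exactly on the sample grid", {
  # empty train, zero noise -> all-zero trace
  empty <- spike_train(numeric(0), 0.05)
  v0 <- synthesize_trace(empty, 0.4, 2, 0)
  expect_true(all(v0$samples == 0))

  # single spike: peak value = amplitude at the rounded sample
  tr <- spike_train(0.0251, 0.06)
  v1 <- synthesize_trace(tr, 0.4, 2, 0)
  expect_equal(max(v1$samples), 2)
  expect_equal(which.max(v1$samples), round(0.0251 * 20000) + 1)

  expect_error(synthesize_trace(tr, 0.05, 2, 0), class = "rise_unresolvable")

  # determinism with noise
  tn1 <- synthesize_trace(tr, 0.4, 2, 0.05, seed = 5)
  tn2 <- synthesize_trace(tr, 0.4, 2, 0.05, seed = 5)
  expect_identical(tn1$samples, tn2$samples)
  expect_equal(sd(tn1$samples[1:400]), 0.05, tolerance = 0.3)
})

test_that("simulated depths match the depth model and markers behave", {
  set.seed(101)
  cfg <- sim_config(n_cells = 1000, n_genes = 120, n_modules = 10,
                    n_marker_genes = 5, duration_s = 60,
                    planted_assoc = list(list(module = 1, feature = "firing_rate_hz",
                                              rho = 0.54)))
  feats <- data.frame(cell_id = sprintf("c%04d", 1:1000),
                      firing_rate_hz = exp(runif(1000, log(0.019), log(1.87))),
                      rise_ms = runif(1000, 0.22, 0.54))
  sim <- simulate_counts(feats, cfg, seed = 8)
  expect_equal(mean(sim$counts$depth), 50457, tolerance = 0.05)

  inh <- sim$gene_info$gene_id[sim$gene_info$marker_class %in%
                                 c("inhibitory", "non_neuronal")]
  expect_gt(mean(sim$counts$counts[, inh] == 0), 0.95)
  hk <- sim$gene_info$gene_id[sim$gene_info$marker_class %in%
                                c("housekeeping", "excitatory")]
  expect_true(all(colMeans(sim$counts$counts[, hk]) >
                    median(colMeans(sim$counts$counts))))
})

test_that("planted correlations are recovered and nulls stay null", {
  # planted rho = 0.6 at n = 200: module score vs feature within +/- 0.1
  cfg <- sim_config(n_cells = 200, n_genes = 100, n_modules = 5,
                    n_marker_genes = 0, duration_s = 60,
                    planted_assoc = list(list(module = 2, feature = "firing_rate_hz",
                                              rho = 0.6)))
  set.seed(102)
  feats <- data.frame(cell_id = sprintf("c%03d", 1:200),
                      firing_rate_hz = exp(rnorm(200)),
                      rise_ms = runif(200, 0.22, 0.54))
  sim <- simulate_counts(feats, cfg, seed = 9)
  rs <- cor(sim$module_scores[, 2], feats$firing_rate_hz, method = "spearman")
  expect_equal(rs, 0.6, tolerance = 0.1 / 0.6)

  # all-null modules at n = 40: median |sample Spearman| below 0.35
  cfg0 <- sim_config(n_cells = 40, n_genes = 100, n_modules = 10,
                     n_marker_genes = 0, duration_s = 60, planted_assoc = list())
  feats0 <- feats[1:40, ]
  sim0 <- simulate_counts(feats0, cfg0, seed = 10)
  rs0 <- abs(cor(sim0$module_scores, feats0$firing_rate_hz, method = "spearman"))
  expect_lt(median(rs0), 0.35)

  expect_error(simulate_counts(feats0[, 1:2],
                               sim_config(planted_assoc = list(
                                 list(module = 1, feature = "rise_ms", rho = 0.5))),
                               seed = 1),
               class = "unknown_feature")
})

test_that("cohorts are deterministic and carry the expected bursty count", {
  cfg <- sim_config(n_cells = 6, n_genes = 60, n_modules = 5, duration_s = 20,
                    frac_bursty = 1 / 3, n_marker_genes = 2, seed = 21,
                    planted_assoc = list(list(module = 1, feature = "firing_rate_hz",
                                              rho = 0.54)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- generate_cohort(cfg, out_dir = d1)
  c2 <- generate_cohort(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  expect_equal(nrow(c1$truth), 6)
  expect_equal(nrow(c1$counts$counts), 6)
  expect_equal(sum(c1$truth$class == "bursty"), 2)

  # study regime: 40 cells at 17.5% -> exactly 7 bursty
  cfg40 <- sim_config(n_cells = 40, n_genes = 50, n_modules = 5,
                      duration_s = 20, n_marker_genes = 0, planted_assoc = list())
  c40 <- generate_cohort(cfg40)
  expect_equal(sum(c40$truth$class == "bursty"), 7)
})
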