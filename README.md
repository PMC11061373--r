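# burstlink

Links the *in vivo* spike phenotype of single hippocampal CA1 pyramidal
neurons to their single-cell transcriptomes. Juxtacellular recording gives
one raw 20 kHz voltage trace per neuron; the same neuron is then collected
and profiled by single-cell RNA-seq (UMI counts). `burstlink` implements the
full analysis chain between the two modalities, plus a ground-truthed
synthetic cohort generator so that every stage can be validated without any
recordings:

* **Spike analysis** — zero-phase 500 Hz Butterworth high-pass, spike
  detection by thresholding the Hilbert envelope of the filtered trace
  (threshold policy 0.25–1 mV, 2 ms refractory), averaged raw waveforms,
  and spike **rise time**: baseline statistics 0.5–2.0 ms before the peak,
  onset at the first sample exceeding baseline mean + 1 SD, rise = peak −
  onset.
* **Burstiness** — 30-bin histogram of inter-spike intervals < 15 ms
  (0.5 ms bins, normalized by total ISI count), PCA (3 PCs), k-means
  (k = 2, 50 seeded restarts), then a Fisher linear discriminant; the
  **burstiness index** is the signed distance from the discriminant
  (positive = bursty, a hard invariant).
* **Expression** — cell QC (drop < 5,000 total UMIs), depth-scaled
  shifted-log or analytic-Pearson-residual normalization, per-gene
  z-scores (population SD).
* **Differential expression** — per-gene Poisson likelihood-ratio test
  (log link, ln-depth offset, closed-form MLEs, χ²₁), log2 fold changes
  with pseudocount, Benjamini–Hochberg q-values.
* **Metagenes** — gene–gene dissimilarity 1 − Spearman ρ, Ward (ward.D2)
  hierarchical clustering, tree cut into k = 25 metagenes; metagene
  expression = mean of member genes' z-scores.
* **Association** — Spearman screen (t-approximation p, BH q over the
  tested family) and AIC subset regression (`AIC = n ln(RSS/n) + 2(k+1)`;
  exhaustive ≤ 15 candidates, bidirectional stepwise otherwise) of firing
  rate on metagenes and rise time on a gene panel (e.g. voltage-gated
  sodium channel genes).
* **Synthetic cohorts** — Poisson/burst spike trains, template spike
  traces with band-limited noise, negative-binomial UMI counts with
  lognormal depths (50,457 ± 13,599) and 25 gene modules whose latent
  scores are coupled to spike features by a Gaussian copula with exact
  sample-level control of the planted rank correlation.

See the methods vignette (`vignettes/burstlink-methods.Rmd`) for the model
details, parameter choices, and known limitations.

## Worked example

Simulate one bursty neuron, render its trace, and recover its spike
features from the raw voltage:

```r
library(burstlink)

train <- simulate_spike_train("bursty", rate_hz = 0.8, duration_s = 120, seed = 7)
trace <- synthesize_trace(train, rise_ms = 0.35, amp_mv = 2, noise_sd_mv = 0.05, seed = 7)
feat  <- extract_spike_features(trace, threshold_mv = 0.5)
feat$features[, c("cell_id", "n_spikes", "firing_rate_hz", "rise_ms")]
#>   cell_id n_spikes firing_rate_hz rise_ms
#> 1    cell      120              1     0.3
```

All 120 planted spikes are detected (1 Hz realized rate for a 0.8 Hz
target with mean burst size 3) and the 0.35 ms rise time is recovered to
one sample (0.05 ms at 20 kHz).

A full ground-truthed cohort at the study size — 40 cells, 17.5% bursty,
with module 1 planted against firing rate at Spearman ρ = 0.54:

```r
cfg    <- sim_config(n_genes = 2000, duration_s = 120, seed = 1)
cohort <- generate_cohort(cfg)
cohort
#> <cohort: 40 cells (7 bursty), 2000 genes, no traces>

ok   <- vapply(cohort$spike_trains, function(tr) tr$n_spikes >= 2, logical(1))
isi  <- t(vapply(cohort$spike_trains[ok], isi_vector, numeric(30)))
fit_burstiness(isi, seed = 1)
#> <burstiness_result: 40 cells, 7 bursty (index > 0)>
```

The classifier calls exactly the 7 planted bursty cells. Differential
expression between the classes and the metagene–rate association:

```r
qc <- qc_filter(cohort$counts, drop_zero_genes = TRUE)
z  <- zscore_genes(normalize_counts(qc))
de <- de_test(qc, cohort$truth$class == "bursty")
head(de[, c("gene", "lr_stat", "p", "q", "log2fc")], 3)
#>         gene lr_stat         p         q log2fc
#> 1 gene_01537     858 1.23e-188 2.45e-185   1.82
#> 2 gene_01592     713 3.58e-157 3.56e-154   1.72
#> 3 gene_01584     653 4.88e-144 3.24e-141   1.66

mg    <- metagene_expression(z, setNames(
           cohort$gene_info$module[match(z$gene_ids, cohort$gene_info$gene_id)],
           z$gene_ids))
assoc <- feature_association(cohort$truth$firing_rate_hz, mg, strategy = "stepwise")
head(assoc$table[order(assoc$table$p_rs), c("predictor", "rs", "p_rs", "q_rs")], 3)
#>      predictor    rs     p_rs    q_rs
#> 1  metagene_01 0.562 0.000161 0.00403
#> 21 metagene_21 0.411 0.008479 0.10599
#> 10 metagene_10 0.376 0.016802 0.14002
```

The planted associations come back on top: metagene 1 at rs = 0.56
(q = 0.004) and metagene 21 at rs = 0.41, matching the planted 0.54/0.39
regime within sampling error. (The Poisson LRT finds many genes DE between
the classes here because module-structured counts are overdispersed
relative to Poisson — a documented property of this test on single-cell
data; its type-I error is exactly calibrated on Poisson-null counts, which
the test suite checks.)

The full pipeline — simulate, detect spikes, classify burstiness,
normalize, test DE, build metagenes, associate — runs from one config and
writes a TSV plus a JSON provenance record per stage:

```r
res <- run_pipeline(pipeline_config(), "runs/demo")   # ~3 min, fully seeded
```

A thin command-line wrapper over the same functions lives at
`inst/cli/burstlink.R`
(`Rscript burstlink.R pipeline --config run.yaml --out DIR`).

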