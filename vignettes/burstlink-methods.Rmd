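---
title: "Linking in vivo spike features to single-neuron transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking in vivo spike features to single-neuron transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstlink)
```

## The problem

Juxtacellular recording yields large (> 1.5 mV) single-unit spikes from one
hippocampal CA1 pyramidal neuron at a time; the same neuron can afterwards be
labelled, collected from an acute slice, and profiled by single-cell RNA-seq.
A cohort built this way pairs, for each neuron, a raw 20 kHz voltage trace
with a UMI count vector over the transcriptome. `burstlink` implements the
analysis chain that relates the electrophysiological phenotype of each
neuron — burstiness, mean firing rate, and the sub-millisecond rise time of
its spike waveform — to its expression profile, together with a
ground-truthed synthetic cohort generator used to validate every stage.

The package operates at desk scale on cohorts of a few dozen neurons
(the regime it targets is 40 cells, ~8,500 genes, ~50,000 UMIs per cell,
firing rates 0.019–1.87 Hz, rise times 0.22–0.54 ms, about 17.5% bursty
cells).

## Spike analysis

**Filtering.** Traces are high-pass filtered at 500 Hz with a 4th-order
Butterworth filter applied forward and backward (`highpass()`). The
two-pass scheme has exactly zero phase, so spike peak times are not
displaced; the trace mean is subtracted first so constant inputs map to
exactly zero. The effective magnitude response is the square of the
single-pass response (~160 dB rejection at 50 Hz, < 1 dB loss at 2 kHz).

**Detection.** The spike envelope is the modulus of the analytic signal of
the filtered trace (`hilbert_envelope()`). Two routes are provided: an
exact FFT construction of the analytic signal, and a 201-tap
Blackman-windowed FIR Hilbert transformer evaluated in compiled code. The
FIR route is the default because it scales linearly in trace length
(minutes of 20 kHz data per neuron); on signals band-limited away from DC
and Nyquist — which filtered spike traces are — the two envelopes agree to
well below 0.1% relative error, and the tests assert this agreement.
Candidate spikes are local maxima of the envelope above a user threshold
(working policy 0.25–1 mV; default 0.5 mV). Within any refractory window
(default 2 ms) only the largest envelope peak is kept, and each detection
is snapped to the maximum of the filtered trace within ±0.5 ms. The 2 ms
refractory and ±0.5 ms snap window are engineering choices: they resolve
the shortest plausible CA1 within-burst intervals without double-counting
one spike.

**Averaged waveform and rise time.** Raw (unfiltered) segments are cut
around each detected peak, aligned on the peak sample, and averaged
(`average_waveform()`). Detection and alignment happen on the filtered
trace, but the average is taken over raw segments: onset and baseline
statistics are physically meaningful on the unfiltered voltage, and the
zero-phase filter guarantees the two time bases coincide. Baseline
statistics are computed 0.5–2.0 ms before the peak (half-open window
`[-2.0, -0.5)` ms); the onset is the first sample at or after −0.5 ms that
strictly exceeds baseline mean + 1 SD, scanning forward toward the peak;
the rise time is peak time minus onset time (`rise_time()`).

Two numerical consequences are worth stating explicitly. First, the
estimate is reported at sample resolution, so on noiseless templates the
error is at most one sample period (0.05 ms at 20 kHz); rise times longer
than the 0.5 ms scan window are truncated to 0.5 ms, which still keeps the
error within one sample for the 0.22–0.54 ms operating range. Second, with
a 1-SD threshold the probability that any single pre-onset baseline sample
of the averaged trace exceeds it is roughly 16% regardless of how many
sweeps were averaged, so onsets can trigger early on baseline noise; rise
estimates on noisy data are therefore upper-bounded by the scan window and
carry a modest positive bias, while the noiseless recovery is exact. An
alternative onset convention (last sub-threshold sample before the peak)
would shift estimates by one sample and is not exposed.

**Firing rate and ISI vector.** The rate is spike count over duration. The
burstiness feature vector is a histogram of consecutive inter-spike
intervals below 15 ms in 30 half-open 0.5 ms bins, normalized by the
neuron's total ISI count (`isi_vector()`), so the vector sums to the
fraction of short ISIs and encodes burst propensity rather than recording
length; a counts mode is available via `normalize = FALSE`.

## Burstiness classification

`fit_burstiness()` applies PCA (column centering only, no scaling — the
bins share units, and scaling would inflate empty high-ISI bins), takes the
first three principal components, and runs k-means with k = 2 and 50 seeded
restarts. The cluster whose members carry the larger mean total short-ISI
mass is labelled bursty: bursty cells by definition have more short ISIs.
A Fisher linear discriminant with pooled within-class scatter is then fit
in PC space; the discriminant direction is normalized to unit length so
that the **burstiness index** — the signed distance of each cell from the
discriminant hyperplane — is a Euclidean distance, positive for bursty
cells. `is_bursty` is defined as `index > 0`, which makes the sign
convention a hard invariant rather than an artifact of cluster labels. A
ridge of 1e-8 is added to the scatter matrix only when it is numerically
singular (warning emitted). Fitting the discriminant in 3-PC space rather
than the raw 30-bin space mirrors where the clustering lives; both the PCA
convention (centering only) and this choice are recorded here because the
procedure is otherwise underdetermined.

## Expression processing

Cells with fewer than 5,000 total UMIs are dropped (`qc_filter()`, strict
inequality); the pipeline also drops genes never observed in any retained
cell, since undetected genes carry no information and would otherwise form
degenerate singleton metagenes. Two normalizations are provided
(`normalize_counts()`):

* `logdepth` (default): `ln(1 + x · median(depth)/depth_cell)` — a
  depth-scaled shifted log. Cells with identical composition at different
  depths normalize identically.
* `pearson`: analytic Pearson residuals `(x − μ)/sqrt(μ + μ²/θ)` under a
  negative-binomial null with fixed θ = 100, `μ = depth_cell · p_gene`,
  clipped to ±sqrt(n_cells). On Poisson-null data the per-gene residual
  variance is ≈ 1 when per-gene means are well below θ, which the tests
  verify in the single-cell regime.

A full regularized NB regression with per-gene smoothed dispersions (the
sctransform model) is intentionally not reproduced: the downstream
statistics are rank-based correlations and metagene averages, and a
documented, dependency-free transform with the same variance-stabilizing
intent keeps the pipeline self-contained; the method is a config switch so
either can feed downstream stages. Gene z-scores (`zscore_genes()`) use the
population SD (divisor n) — the choice is asserted in tests — with
zero-variance genes mapped to all-zero columns under a warning.

## Differential expression

`poisson_lrt()` tests each gene between bursty and non-bursty cells with a
Poisson GLM, log link, `ln(depth)` offset: the null model is
intercept-only, the alternative adds the group indicator. For this design
the MLEs are closed form (group rate = group total / group depth), so the
LR statistic is computed analytically and the suite cross-checks it against
an iteratively fitted GLM to 1e-8. All-zero genes are defined to have
LR = 0, p = 1. Depth offsets can be supplied explicitly; by default the
realized library sizes are used, which is the only option on real data but
carries composition bias in simulations where many genes shift in one
group — the calibration checks therefore pass the known exposures. A
no-offset compatibility mode (`offset_depth = FALSE`) mimics testing on
depth-agnostic values.

Two caveats documented by the tests: the test is exactly calibrated when
counts are conditionally Poisson (type-I error ≈ 5% at α = 0.05, realized
FDR under BH ≈ nominal), and it is anti-conservative when biological
overdispersion is present — on synthetic cohorts with NB counts and
module-structured heterogeneity, arbitrary groupings yield many small
p-values. This mirrors the known behavior of Poisson-likelihood tests on
single-cell data and is a property of the method being replicated, not of
the implementation.

Fold changes are `log2((mean_bursty + 1)/(mean_nonbursty + 1))` on linearly
depth-normalized counts (pseudocount 1 on that scale);
`bh_adjust()` is the Benjamini–Hochberg step-up adjustment (delegating to
`stats::p.adjust`, verified against hand-computed vectors).

## Metagenes

Gene–gene dissimilarity is `1 − ρ_s` with average-rank ties
(`spearman_dissimilarity()`); zero-variance genes get dissimilarity 1 under
a warning. Clustering is Ward's minimum-variance method via
`stats::hclust`; the default `ward.D2` convention applies the
Lance–Williams update on squared dissimilarities, and the legacy `ward.D`
variant is available as a flag because R historically offered both. The
merge order is verified against a brute-force Lance–Williams oracle on
small instances. The tree is cut into k = 25 metagenes (`cut_to_metagenes()`,
`stats::cutree` numbering by first appearance), and each metagene's
expression in a cell is the arithmetic mean of its member genes' z-scores
(`metagene_expression()`), which makes the member-count-weighted sum of
metagene columns equal the z-matrix row sums exactly.

## Association of spike features with expression

`spearman_assoc()` screens each predictor (metagene or panel gene) against
a spike feature with Spearman's ρ (average-rank ties), a two-sided p from
the t-approximation `t = r_s sqrt((n−2)/(1−r_s²))` on n−2 df, and BH
q-values over the tested family — 25 metagenes for firing rate, the gene
panel (e.g. 11 voltage-gated sodium channel genes) for rise time. An exact
permutation mode (seeded) is available for small panels; at n = 40 the two
agree closely and the t-approximation is the default.

`aic_select()` performs subset regression with
`AIC = n ln(RSS/n) + 2(k+1)`: exhaustive enumeration up to 15 candidates,
seeded bidirectional stepwise search otherwise (with 25 metagene candidates
exhaustive search would be 2^25 fits). Ties prefer the smaller model. Two
numerical policies matter. First, fits whose RSS falls below 1e-20 of the
response's total sum of squares are treated as exact ties, so in the σ → 0
limit the search returns the true support instead of chasing rounding
noise; this is also the regime in which exhaustive and stepwise are
guaranteed to agree. With genuine noise AIC's well-known liberality is
scale-free — each irrelevant candidate improves AIC with probability
P(F(1, n−2) > ~2) ≈ 0.17 at n = 40 regardless of signal strength — so the
selected set typically contains spurious extras and greedy and exhaustive
searches may differ in which extras they carry; users should read the
selected set as "maximum contribution" in the AIC sense, not as a
controlled-error discovery list. Second, aliased columns in a selected
design are dropped (smallest index kept) under a warning. Model-level
statistics (adjusted R², F, model p) come from the standard OLS summary.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions so that every stage is
testable without any recordings:

* **Classes and features.** Exactly `round(frac_bursty · n)` cells are
  bursty (default 17.5% of 40 = 7), true firing rates are log-uniform over
  0.019–1.87 Hz, true rise times uniform over 0.22–0.54 ms.
* **Spike trains.** Non-bursty cells are homogeneous Poisson processes
  thinned by a 2 ms refractory period. Bursty cells draw burst onsets as a
  Poisson process at `rate / 3`, geometric burst sizes (mean 3), and
  gamma within-burst ISIs (shape 4, mean 4 ms, truncated to 2–12 ms); the
  recorded literature does not model firing, so these forms were chosen to
  make the 30-bin ISI vector bimodal between phenotypes while keeping the
  realized overall rate within 20% of the target in expectation.
* **Traces.** Spikes are piecewise templates — linear rise to a 2 mV peak
  on the sample grid, 0.5 ms exponential decay, small negative afterwave —
  plus Gaussian noise band-limited below 5 kHz with SD 0.05 mV. Only the
  rise segment is touched by the rise-time estimator, which is why its
  shape is the configurable part.
* **Counts.** Per-cell depths are lognormal matched to 50,457 ± 13,599 and
  truncated at 1; baseline gene abundances are lognormal (sdlog 0.75,
  giving a realistic spread of per-gene means around depth/n_genes); genes
  are partitioned into 25 modules; counts are negative binomial (size 10)
  around softmax-normalized means `abundance · exp(loading · score)` with
  loading 1.0 for module genes. Marker blocks emulate standard QC panels:
  housekeeping/excitatory genes high in all cells,
  inhibitory/non-neuronal markers near zero (> 95% zero entries).
* **Planted associations.** For each planted (module, feature, ρ) the
  module's latent score is built by a Gaussian copula with *exact
  sample-level control*: the score has exactly the target Pearson
  correlation `2 sin(πρ/6)` with the normal scores of the feature's ranks
  (Gram–Schmidt construction), pinning the sample Spearman correlation at
  ρ up to rank-discretisation error. Exact control is the point of the
  copula choice: a population-level draw would add ±0.17 of pure sampling
  noise at n = 40 and make recovery statements about the generator itself
  untestable. Defaults plant the reported regime: module 1 vs firing rate
  (0.54), module 21 vs firing rate (0.39), module 2 vs rise time (0.44),
  module 3 vs rise time (−0.42).

What the generator does **not** emulate: theta/ripple LFP oscillations,
electroporation artifacts, spatially correlated recording noise, ambient
RNA or doublets, and gene–gene correlation structure beyond the planted
modules. Passing tests therefore demonstrate that the analysis chain
recovers what it claims under its own stated model at the study's sizes —
not that the biological findings would replicate.

## Problem sizes, seeds and determinism

Every stochastic operation takes a seed (`with_seed()` restores the
caller's RNG state), and the pipeline is a pure function of
(inputs, config, seeds): the determinism test runs the default 40-cell,
8,462-gene, 600 s cohort end to end twice and asserts byte-identical
outputs. Validation problem sizes were chosen to exercise the study regime
while staying desk-scale: 100 noiseless spikes for rise-time recovery, 100
× 600 s traces for detection, 200 neurons for classification, 10,000 genes
for LRT calibration, 40 × 2,500 genes with 25 planted blocks for metagene
recovery, and 200 replicate cohorts for association recovery (the
`scripts/acceptance.R` summary uses 100 cohorts and 20 traces for its
quicker, reportable rerun). Trace durations default to 600 s — long enough
that the slowest neurons (0.019 Hz) still yield ISI vectors, an order of
magnitude below the ~29 min real recordings.

## Known limitations

* The Poisson LRT inherits anti-conservativeness under overdispersion (see
  above); a negative-binomial test is out of scope because the replicated
  procedure is the Poisson one.
* Rise-time estimates on noisy averages are biased toward the 0.5 ms scan
  bound by early onset triggers; this is intrinsic to the 1-SD onset rule.
* AIC subset selection admits spurious predictors at a scale-free rate and
  is reported as such, not as an error-controlled selection.
* The FIR envelope degrades near Nyquist (type III transformer); content
  above ~9 kHz contributes mostly through the rectified real part. The FFT
  route is exact and available wherever that matters.
* ABF/NWB ingestion and FASTQ-level processing are out of scope; traces
  are raw f32 + JSON sidecar, counts MatrixMarket or dense TSV.
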