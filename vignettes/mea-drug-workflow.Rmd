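---
title: "Detecting drug effects in MEA recordings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting drug effects in MEA recordings: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microelectrode arrays (MEAs) record extracellular spikes from cultured
neuronal networks at up to 64 electrodes. A classic pharmacology design
records each culture ("chip") twice: 600 s of spontaneous activity before
and after applying a compound. Disinhibiting drugs such as bicuculline, a
GABA~A~ antagonist, push such networks into hypersynchronous, epileptiform
firing. `meadrug` implements a workflow that (i) detects whether a compound
changed network activity, and (ii) characterizes *how*, in terms of
interpretable network properties, while respecting the paired,
repeated-measures structure of the design.

```{r, eval = FALSE}
library(meadrug)
run <- run_pipeline(synth_cfg = synth_config(seed = 1),
                    models = c("svm", "nb"), seed = 2)
glance(run)
```

## The procedure, stage by stage

1. **Spike tables** (`read_spike_table()`, `spike_tbl()`). A long CSV with
   `chip_id, condition, electrode, time_s` is the interchange format.
   Electrodes without rows are inactive. Raw-trace utilities
   (`remove_artifacts()`, `detect_spikes()`) cover the preprocessing used
   to produce such tables: blanking from 6 ms before to 25 ms after
   supra-threshold positive artifacts (interval mapped outward onto sample
   indices, so blanking is conservative and idempotent), then detection at
   −5 × SD of the cleaned trace with a 1 ms dead time. The spike time is
   the leading edge of the threshold crossing — the simplest convention
   that is monotone in the threshold. The SD includes blanked zeros by
   default (`exclude_blanked = FALSE` flips the convention).

2. **Sliding windows** (`segment_windows()`). Each recording is cut into
   windows of 60/120/240 s with 0–75 % overlap. Windows are half-open
   `[start, start + w)`; only fully contained windows are emitted, giving
   `floor((D − w)/step) + 1` of them. Windowing is a data-augmentation
   device: it multiplies training instances without pretending they are
   independent — independence is restored downstream by grouping whole
   chips in cross-validation and by the mixed model.

3. **Binary binning** (`bin_binary()`). Within a window every electrode
   becomes a 0/1 vector over bins of 1/10/100 ms (`1` = at least one
   spike). Bins are half-open; a trailing partial bin is dropped so all
   windows have identical dimensionality.

4. **Connectivity** (`correlate()`, `binarize()`). Pairwise correlation of
   the binary rows gives a symmetric functional-connectivity matrix. On
   0/1 data the Pearson coefficient *is* the phi coefficient of the 2×2
   contingency table, which is how it is computed (sparse cross-products;
   numerically exact). Spearman coincides with Pearson on binary data
   because ranking a binary vector is affine. The "canonical" method is a
   sparse CCA between lag-embedded copies of the two trains (lags 0–5
   bins, soft-threshold penalty 0.1): the published workflow names sparse
   CCA without fixing a pairwise construction, so this lag-embedding is
   our documented stand-in — it keeps a genuinely multivariate statistic
   while remaining pairwise, and it is pluggable. Zero-variance electrodes
   get correlation 0 with all partners, keeping silent channels isolated
   instead of undefined. Edges are drawn where the *raw* signed
   correlation is ≥ 0.5. We binarize raw values rather than z-scored ones
   deliberately: a fixed threshold on standardized values would be
   data-dependent (the same absolute coupling would gain or lose edges
   depending on the batch it was standardized with); standardization
   happens later, on the feature matrix, where it belongs to the
   classifier's preprocessing.

5. **Graph features** (`scalar_measures()`, `community_apl()`,
   `graph_features()`). Seventeen graph-level measures (degree moments,
   entropy of the degree distribution, density, transitivity, distances,
   efficiency, centralities, coreness, assortativity) plus the average
   path length of the largest community under eight community-detection
   algorithms (fast-greedy, Infomap, leading eigenvector, label
   propagation, edge betweenness, spinglass, multilevel, spanning tree).
   Conventions for awkward graphs are fixed and tested: distance measures
   are computed on the largest connected component; efficiency uses
   1/∞ = 0 over all pairs; an edgeless graph scores 0 on path-based
   measures; assortativity of a regular graph is 0. "Complexity" is
   defined as ⟨k²⟩/⟨k⟩ — consistent with the second moment ⟨k²⟩ being a
   separate feature — and per-node measures are reduced by the arithmetic
   mean; both choices are configurable because the literature the feature
   set descends from does not pin them down. Eigenvector centrality (and
   the hub score, which equals it on undirected graphs) is computed as a
   componentwise Perron vector: deterministic and invariant under node
   relabeling even when disconnected components tie. The spanning-tree
   community method is likewise a documented stand-in: grow a spanning
   forest, repeatedly delete the forest edge of highest betweenness, and
   keep the split sequence that maximizes modularity in the original
   graph. Stochastic community methods run under a per-window seed derived
   from (chip, condition, window), so feature tables are bit-reproducible.

6. **Spike-Contrast** (`spike_contrast()`). A time-scale-adaptive synchrony
   index in [0, 1]: half-overlapping bins shrink geometrically (factor
   0.9) from half the window length down to 10 ms; at each scale,
   *Contrast* is the total variation of the pooled spike-count profile
   normalized by twice the binned spike count, and *ActiveST* is the
   spike-weighted fraction of co-active trains beyond the first,
   `(⟨n⟩ − 1)/(N − 1)`. Synchrony is the maximum over scales of their
   product. Perfectly synchronous trains (events isolated at the smallest
   scale and away from the interval edges) attain exactly 1; the theta
   differences are deliberately *not* zero-padded, because padding would
   add the first and last bin totals to the numerator and push independent
   Poisson trains to ≈ 0.5 at the coarsest scales. The `(N − 1)`
   normalization means ActiveST is not exactly invariant to duplicating
   all trains (the drift is O(1/N) and vanishes at perfect synchrony);
   the alternative `⟨n⟩/N` would be exactly invariant but would not
   vanish for a single active train. We keep the published form.

7. **Paired standardization** (`paired_standardize()`). For each chip and
   feature, the mean and sample SD of that chip's *pre-drug* windows
   standardize both conditions. Post-drug values are thus expressed in
   units of the chip's own baseline variability. The source protocol
   contains two standardization descriptions (a pooled per-chip one stated
   with the connectivity matrices, and the pre-drug-referenced one stated
   with the features); we default to the pre-drug-referenced scheme — it
   preserves the paired logic (the drug shift survives standardization
   instead of being partly absorbed) — and treat the pooled variant as a
   config alternative.

8. **Grouped LOO-CV** (`grouped_loocv()`). One outer split per chip: all
   windows of the held-out chip (both conditions) form the validation
   set. Hyperparameters are tuned by an inner grouped LOO over the
   training chips, maximizing mean AUC over a small fixed grid (the
   original study publishes none): SVM cost {0.1, 1, 10} with the
   variance-scale gamma heuristic; RF depth {∞, 8} at 500 trees; XGBoost
   depth {3, 6} at 200 rounds; kNN k {3, 5, 9}; ridge-logistic lambda
   {0.1, 0.01, 0.001}; Gaussian NB; MLP with one hidden layer of 100 and
   decay {0.1, 0.01}. Decision scores (margins or probabilities, never
   hard labels) feed the per-split ROC AUC. The model's headline score is
   the 2.5th percentile of 1000 bootstrap resamples of the split AUCs —
   a deliberately conservative summary. A leakage guard asserts disjoint
   train/validation chip sets on every split of every run.

9. **SHAP attribution** (`shap_attribute()`, `rank_features()`,
   `model_similarity()`). Shapley values with the interventional value
   function: features outside the coalition are replaced by background
   rows (a seeded subsample of the training windows) and scores averaged.
   Exact enumeration for ≤ 12 features; otherwise permutation sampling,
   whose telescoping sums keep the additivity identity exact at any draw
   count. The reporting population is the post-drug validation windows,
   the pipeline uses 120 permutations per window (medianing over windows
   and splits smooths the sampling noise; the operation's own default is
   2000), and features are ranked by the median across splits of the
   median absolute attribution, with min/max whiskers and the sign of the
   post-drug shift. Pearson correlation between models' importance
   vectors quantifies cross-model agreement.

10. **Mixed-model validation** (`lmm_test()`, `lmm_screen()`). Per
    feature, `value ~ condition + (1 | chip)` fitted by maximum
    likelihood against the condition-free null, compared by likelihood
    ratio. Window-level rows enter directly — the random intercept
    absorbs the repeated-measures dependence that would invalidate a
    Wilcoxon test. The LRT (rather than a Wald test) was chosen because
    it is estimator-agnostic and easy to verify by simulation; type-I
    calibration at the design scale (9 chips × 7 windows × 2 conditions)
    is part of the test suite. Significance codes use the five
    conventional bins (`****` at p ≤ 1e−4, boundaries to the stricter
    bin); Benjamini–Hochberg q-values are emitted as supplementary
    output, since the per-feature codes themselves follow the
    uncorrected reporting convention.

## The synthetic-data generator

Real paired MEA recordings of this design are not redistributable, so
`synth_config()`/`generate_dataset()` emulate the study conditions: 9
chips, 600 s per condition, 60 electrodes of which a random 10 % are
silent, 0.5 Hz Poisson background firing, and Poisson-timed network
bursts (0.2 Hz) joined by each electrode with probability 0.4, emitting 5
spikes with 50 ms Gaussian jitter. The "drug" raises burst rate to 0.4 Hz
and participation to 0.9 and tightens jitter to 10 ms — the
hypersynchrony signature of disinhibition. Both conditions of a chip
share one log-normal multiplicative random effect on rates (SD 0.2),
mirroring the random-intercept assumption of the LMM. Near-coincident
spikes within an electrode are merged at 0.1 ms resolution.

What the generator does *not* emulate: bursty background (non-Poisson
inter-spike intervals), electrode cross-talk, slow drift of excitability
over the session, waveform-level noise, or partial/graded burst
propagation. Passing tests therefore demonstrate that the pipeline
recovers a synchrony-mediated effect under controlled conditions — not
that it detects every pharmacological signature in real cultures.

One consequence worth knowing: under these conditions the *pre-drug*
windows (participation 0.4, 50 ms jitter) have binary-coincidence
correlations below the 0.5 edge threshold at every bin size, so their
connectivity graphs are empty; post-drug windows produce structured
graphs at 10–100 ms bins but sparse ones at 1 ms. Because paired
standardization divides by the pre-drug SD, graph features with a
constant (empty-graph) baseline are zeroed, and classification on the
synthetic data is carried by Spike-Contrast. That is a property of the
simulated synchrony scale, not of the pipeline — real cortical cultures
fire far more densely — and the graph-feature stack is therefore
exercised directly against closed forms and brute-force oracles in the
test suite rather than through the simulator. We kept the generator
parameters as stated rather than tuning them to make any particular
feature family look better.

## Numerical choices and degenerate inputs

* Half-open intervals everywhere (windows, bins, overlapping synchrony
  bins): a spike on a boundary belongs to the next unit, never to two.
* Zero-variance anything — silent electrodes, constant features,
  degenerate traces — maps to an explicit convention (correlation 0,
  standardized value 0, detection refusal) with a warning, never to NaN.
* All stochastic stages (generator, community detection, model fits,
  bootstrap, SHAP sampling, background subsampling) draw their seeds
  deterministically from one master seed via a string-hash fan-out, so
  any stage can be re-run in isolation and full runs are bit-identical.
* Ties: the largest community is the one containing the smallest node
  index among equal-sized ones; bootstrap quantiles use R's type-7.

## Problem sizes used by the shipped tests

The test suite and acceptance script run entirely on generated data: unit
tests use 3–6 chips at 45–120 s; the end-to-end checks use the full
design (9 chips × 600 s, 240 s windows at 75 % overlap → 126 windows of
26 features) once with the drug effect and once with a null twin, with
SHAP for the two headline models and all seven families on the null run.
LMM calibration uses 150–200 simulated null features at the 126-row
design. These sizes were chosen so the whole suite completes comfortably
on a laptop-class single core.

## Known limitations

* Connectivity is undirected correlation; directed or sign-resolved
  methods (transfer entropy, Granger, spiking-probability edges) are out
  of scope, as are weighted-graph variants of the measures.
* The pairwise sparse-CCA construction is a stand-in (see above) and
  deliberately pluggable.
* `nnet`'s MLP uses weight decay and a fixed iteration cap rather than
  validation-based early stopping.
* The LMM uses a single random intercept — no random slopes, crossed
  effects, or Satterthwaite corrections — matching the design it serves.
* Exact SHAP is capped at 12 features; beyond that the permutation
  estimator's per-feature values carry sampling noise (the additivity
  identity stays exact).
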