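---
title: "SHERPA: SHAP-driven ERP analysis — methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SHERPA: SHAP-driven ERP analysis — methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Event-related potential (ERP) analysis must reduce a trials × electrodes
× time-samples voltage block to a handful of coordinates — *which time
windows* and *which electrodes* carry a condition effect.  The
researcher-driven route picks both from the literature (e.g. mean N170
amplitude at P7/P8, PO7/PO8, P9/P10 in 165–205 ms); the data-driven
route runs a cluster-based permutation test and reads coordinates off
the significant clusters.  SHERPA is a third route: train a
convolutional network to classify single epochs by condition, attribute
its decisions to every (electrode, time) input with SHAP values, and
distill the attribution mass into peaks, windows and ranked electrode
sets.  This package implements all three routes plus a synthetic ERP
generator, so the whole pipeline is testable end to end with no
recordings.

## Data model and time-grid conventions

`EpochedData` holds a `trials × channels × times` array in microvolts
with per-trial condition labels and subject identifiers.  The package
consumes *preprocessed* epochs; filtering, re-referencing, ICA and
baseline correction belong upstream and are out of scope.

Two conventions matter enough to state explicitly:

* **Half-open crops.** `cropEpochs(x, t0, t1)` keeps samples with
  `t0 <= t < t1`.  Cropping a −500…1500 ms epoch to `[0, 1500)` at
  512 Hz yields exactly 768 samples.
* **0-based sample offsets.** `indexToTime(i, sfreq)` returns
  `t0 + i · 1000/sfreq`, so offset 80 at 512 Hz is 156.25 ms and offset
  83 is 162.109375 ms (printed 162.11).  These are the latencies a
  512-Hz grid produces; the sampling rate is a package default, chosen
  because it is the rate at which a 0–1500 ms epoch has 768 samples and
  peak latencies fall on values such as 156.25, 148.44, 162.11 and
  292.97 ms.

The on-disk container is a directory with a raw little-endian float32
array (time fastest, then channel, then trial) and a JSON sidecar —
language-neutral and diff-able.  Note that float64 input is stored at
float32 precision.

## The classifier

`buildModel()` constructs a 1-D CNN that convolves along time with the
EEG channels as input feature maps:

    BatchNorm → 4 × (Conv1D → GELU → MaxPool) → BatchNorm
             → flatten → Dense(ReLU) × 3 → softmax

Defaults: ascending filter counts 16/32/64/128, kernel 50 samples, L2
on the conv kernels, Glorot-normal init for the first conv layer
(Glorot-uniform elsewhere), descending dense widths 128/64/32, Adam on
categorical cross-entropy, batch size 64, at most 200 epochs with early
stopping after 50 epochs without validation-*loss* improvement, while
the retained weights are those of the epoch with the best
validation-*accuracy* — the two criteria deliberately differ, matching
the stated protocol.  `splitData()` builds the hold-out test set as all
trials of a configurable number of fully held-out subjects plus a
class-stratified sample of the remaining trials; `trainCrossval()` runs
stratified five-fold cross-validation over the training set.

Where the protocol leaves gaps, the package chooses and exposes the
choice as a config field: pool size 2 per block (the largest
power-of-two schedule keeping 768 → 48 samples before flattening), L2
coefficient `1e-4`, learning rate `1e-3`, batch-norm momentum 0.9 (a
lower momentum stabilises the inference statistics within the short
training runs used here; the conventional 0.99 needs many more update
steps before validation metrics are meaningful).

The network engine itself is written in base R on BLAS matrix products
(im2col unrolling for the convolutions, the transposed convolution
expressed as a flipped-kernel correlation), with exact GELU
(`x·Φ(x)`) and standard batch-norm backpropagation.  All gradients are
verified against central finite differences in the test suite at
`1e-9` relative error.

`deskModelSpec()` scales the architecture to the reduced preset
(kernel `50 · 256/768 ≈ 17`, filters 8/16/32/64, dense 64/32/16) so the
full protocol runs on one CPU in minutes.

## Expected-gradients attribution

For input `x` and class output `f_c`, the attribution of feature `i` is

    φ_i(x, c) = E_{b ~ background, α ~ U(0,1)}
                [ ∂f_c/∂x_i (b + α (x − b)) · (x_i − b_i) ]

estimated by Monte Carlo over `nPathSamples` draws.  It satisfies the
SHAP completeness identity `Σ_i φ_i ≈ f_c(x) − E_b f_c(b)` in the
limit.  Two variance-reduction choices are built in, both unbiased:
background samples are drawn in a balanced rotation (each background
trial appears a near-equal number of times), and each background's
interpolation coefficients are a jittered stratification of (0, 1).
With these, a linear model recovers its closed form
`w_i (x_i − mean_b b_i)` to better than `1e-3` at 2000 path samples,
and completeness holds within a few percent on a trained CNN.

Defaults: a background of 100 training trials sampled with a fixed
seed; 200 path samples for pipeline runs (2000 for oracle-grade
checks); attribution in units of the softmax class probability.

Aggregation follows the absolute-value convention: the
`ImportanceMatrix` is the mean over trials of the class-summed
`|φ|` per (channel, time); the per-class `ImportanceCurve` sums `|φ|`
over electrodes per time point.  The mean (not sum) over trials keeps
scales comparable across dataset sizes.  Whether per-class curves
should average over all trials or only that class's trials is not fixed
by the protocol; both are implemented (`trialScope`), with `all_trials`
the default.

## SHERPA distillation

* **Peaks.** A sample is a local maximum iff it *strictly* exceeds
  every other sample within `extremumOrder` samples (default 10 ≈
  19.5 ms at 512 Hz).  Flat plateaus therefore yield no peak, and curve
  endpoints are never peaks — a deliberate tie policy that can diverge
  from neighbour-comparison implementations that emit plateau edges.
  Peaks are ranked by height and truncated to `topKPeaks`.
* **Windows.** A window of `windowLength` ms (default 40) is centred on
  each peak — a 40-ms window on a 156.25-ms peak spans
  136.25–176.25 ms — and clipped to the grid with a flag when the peak
  sits near an edge.
* **Electrodes.** Each electrode's score is the *mean* importance over
  the window samples (comparable across window lengths); the electrode
  sets are those reaching the 0.75 and 0.9 empirical quantiles of the
  score distribution, nested by construction.

`sherpaReport()` runs curve → peaks → windows → electrode ranking per
class and serialises to JSON.

## Comparator analyses

**Cluster-based permutation test.**  Per (channel, time) sample the
dependent (repeated-measures) F statistic
`MS_condition / MS_(condition × subject)` with df `(k−1, (k−1)(n−1))`
is computed on subject-condition averages.  Samples exceeding the
F quantile at the cluster-forming α (default 0.05) are clustered by
temporal adjacency on the same channel and spatial adjacency at the
same time point; a cluster is kept only if, at some time point, it
spans at least `minChannelNeighbors` (default 2) mutually adjacent
channels.  Cluster mass is the summed F.  The null distribution
relabels conditions independently within every subject — the
exchangeability-preserving scheme for a dependent design — and records
the maximum qualifying cluster mass per permutation; each observed
cluster gets `p = (1 + #(null ≥ mass)) / (nPermutations + 1)`,
including the observed statistic for validity.  The permutation loop
exploits the fact that the within-subject total sum of squares is
invariant under per-subject relabeling, so only condition means are
recomputed.

Spatial adjacency is a distance-threshold graph on unit-sphere
electrode positions.  The curated neighbourhood used with the original
128-channel recordings is not public, so the threshold graph is a
documented stand-in; the default threshold is 1.85 × the median
nearest-neighbour spacing, which gives minimum degree 2 on the packaged
BioSemi-128 layout and proportionate neighbourhoods on sparser
simulated montages (a fixed absolute threshold would leave sparse
layouts with no neighbours at all and silently disable the spatial
rule).

**Conventional rmANOVA.**  Mean amplitude per subject × condition over
literature electrodes (P7/P8, PO7/PO8, P9/P10 by default, resolved to
ABC labels through a packaged nearest-position alias table) in an
inclusive 165–205 ms window, then a one-way repeated-measures ANOVA
(uncorrected df, partial η² = SS_cond/(SS_cond+SS_err)) and all
pairwise paired t-tests.  Identical condition data degenerate to
`F = 0` and `t = 0` by definition rather than erroring.

## The synthetic generator

Each ERP component is a Gaussian time course (unit peak at its latency,
SD `width` ms) times a fixed scalp topography (a Gaussian weight map on
the electrode positions), scaled by a per-condition gain and the signed
amplitude; trials add multiplicative amplitude jitter, latency jitter,
1/f ("pink") noise synthesized in the frequency domain with random
phases, white noise, and optionally neighbour-mixed (spatially
correlated) noise.  With equal gains the labels are exchangeable —
`nullDataset()` enforces this — which is the substrate for the
type-I-error checks.

Two presets define the standard conditions:

* `presetN170()` — 3 conditions × 26 subjects × 60 trials, the packaged
  128-channel layout, 0–1500 ms at 512 Hz; an equal-gain P100-like
  component at 100 ms, an N170-like occipito-temporal component at
  170 ms with gains face 1.0 / scrambled 0.9 / blurred 0.5 (blurred
  weakest), and a late 300-ms face-selective component.  The gains are
  generator parameters chosen to mirror the qualitative ordering of the
  motivating findings, not measured values.
* `presetDesk()` — the same structure at desk scale: 8 subjects × 30
  trials, 32 synthetic electrodes, 0–500 ms (256 samples), with
  `effect = "strong"` (gains 1.0/0.2/0.6 and a strongly face-selective
  late component) giving cleanly separable classes, `"moderate"`
  mirroring the typical ordering (blurred weakest), and `"null"`
  equalising all gains.

What the generator does *not* emulate: volume-conducted source
geometry (topographies are abstract weight maps, per design), ocular
and muscular artifacts, between-subject topography variability, and
trial-to-trial autocorrelation beyond 1/f noise.  Passing tests on
synthetic data therefore demonstrate the *machinery* — recovery of
implanted coordinates under realistic SNR — not performance on any real
recording.

## Problem sizes used by the test suite

The suite exercises the full protocol at sizes a laptop CPU handles in
minutes, chosen once as the package's standard desk-scale conditions:

* classifier recovery: `presetDesk("strong")` (720 trials), 5 folds,
  8 epochs, three seeds, attribution of 96 stratified test trials at
  100 path samples;
* permutation calibration: 200 exchangeable-null datasets of 8
  subjects × 16 channels × 64 samples with spatially smoothed noise,
  200 permutations each — family-wise rejection at α = 0.05 is checked
  against its binomial band;
* attribution oracles: 2000 path samples against the linear closed
  form and the completeness identity.

## Numerical choices and degenerate inputs

* F statistics: samples with zero effect *and* zero error variance are
  defined as `F = 0`; zero error with nonzero effect is `Inf`.
  Relative tolerances (`1e-18` of the mean square) guard against
  floating-point residues in exactly-degenerate fixtures.
* Peak finding on an all-constant curve returns an empty set, not an
  error; an attribution tensor of zeros produces an empty report.
* Quantile electrode sets use the `≥ empirical quantile` rule (type-7
  quantiles), so uniform scores include every channel.
* Serialized JSON uses fixed formatting so identical computations are
  byte-identical — the property the determinism checks assert.

## Known limitations

* The network engine targets small/medium geometries; full-scale
  (128 × 768) training is possible but slow on one CPU, and the
  published accuracy of the original recordings is not reproducible
  from synthetic data in any case.
* The adjacency graph is a stand-in for the original curated
  neighbourhood (see above).
* Expected gradients assumes the model is differentiable everywhere
  along the interpolation paths; max-pool argmax switching makes the
  gradient piecewise constant, which the Monte-Carlo average smooths
  but does not eliminate.
* `η²` is reported as partial eta squared; other flavours differ when
  subject variance is large.
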