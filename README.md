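# sherpa

SHAP-driven ERP analysis for epoched EEG.

Experimental EEG work has to reduce a `trials × electrodes × time`
voltage block to a few interpretable coordinates: *which time windows*
and *which electrodes* separate the experimental conditions.  This
package implements SHERPA, a pipeline that answers that question with a
classifier instead of a hypothesis: it

1. trains a 1-D convolutional network to classify single epochs by
   condition (`BatchNorm → 4×(Conv→GELU→MaxPool) → BatchNorm → dense →
   softmax`, five-fold cross-validation, mixed held-out-subject test
   set);
2. attributes the classifier's decisions to every `(electrode, time)`
   input with expected-gradients SHAP values
   `φ_i = E_{b,α}[∂f_c/∂x_i(b + α(x−b)) · (x_i − b_i)]`;
3. distills the absolute attribution mass into objective ERP
   coordinates — local importance maxima, fixed-length windows centred
   on them (40 ms by default), and the electrodes above the 0.75/0.9
   score quantiles in each window.

It also ships the two analyses SHERPA is validated against — the
spatio-temporal cluster-based permutation test on the dependent
(repeated-measures) F statistic and the conventional rmANOVA on mean
amplitudes at literature electrodes — plus a seedable synthetic ERP
generator (N170-style designs: face / blurred / scrambled conditions,
P100-like, N170-like and late face-selective components, pink + white
noise, amplitude/latency jitter) so everything is testable without any
recordings.  It is aimed at EEG methodologists and ERP researchers who
want data-driven window/electrode selection with a statistical safety
net.

No deep-learning framework is required: the network engine (forward,
backprop, Adam, input gradients) is written in base R on BLAS matrix
products and is verified against finite differences in the test suite.

## Worked example

Desk-scale run (8 subjects × 3 conditions × 30 trials, 32 electrodes,
0–500 ms at 512 Hz, strongly face-selective 170-ms implant):

```r
library(sherpa)

cfg    <- presetDesk("strong", seed = 1)
epochs <- simulateEpochs(cfg)

tc  <- trainingConfig(maxEpochs = 8, earlyStopPatience = 8, seed = 1)
sp  <- splitData(epochs, tc)
fit <- trainCrossval(deskModelSpec(), sp$train, tc)
evaluateModels(fit, sp$test)

bg     <- backgroundSet(sp$train, size = 100, seed = 1)
attr   <- expectedGradients(fit$models[[5]], sp$test, bg,
                            nPathSamples = 100, seed = 1)
report <- sherpaReport(attr, sherpaConfig())
report
```

prints (about four minutes on one CPU):

```
EvaluationReport: test accuracy 0.867 (SD 0.037) over 5 states
           predicted
actual       face blurred scrambled
  face      0.933   0.017     0.050
  blurred   0.000   0.800     0.200
  scrambled 0.017   0.150     0.833

SherpaReport
  face: peaks at 296.88, 160.16, 103.52 ms (summed importance 0.037, 0.0148, 0.01)
  blurred: peaks at 169.92, 304.69, 341.80, 457.03 ms (summed importance 0.07, 0.0302, 0.0284, 0.0198)
  scrambled: peaks at 169.92, 304.69, 457.03 ms (summed importance 0.0634, 0.0522, 0.0211)
```

The classifier separates the three conditions well above the ⅓ chance
level, and the attribution mass concentrates exactly where the
generator implanted signal: near 170 ms (the N170-like component, whose
gain differs across all three conditions) and near 300 ms (the late
face-selective component, which is why it dominates the *face* curve).
The window report around the 160-ms face peak then names the electrodes
that carried the decision:

```
WindowReport [face]: 140.16..180.16 ms
  top electrodes: E20=0.007736, E18=0.007051, E03=0.006108, ...
  q0.75 set (8): E02 E03 E04 E07 E12 E18 E20 E27
  q0.9 set (4): E03 E07 E18 E20
```

The comparator confirms the same coordinates independently:

```r
erp <- subjectConditionAverages(epochs)
clusterPermutationTest(erp, permConfig(nPermutations = 200),
                       buildAdjacency(cfg$layout), seed = 1)
#> ClusterResult: 36 cluster(s), threshold F(2,14) > 3.7389, 200 permutations
#>   #1: 823 samples, 28 channels, 246.09..355.47 ms, mass 26948.31, p = 0.00995
#>   #2: 469 samples, 28 channels, 132.81..207.03 ms, mass 22606.64, p = 0.00995
#>   ...
```

— two significant clusters, one spanning the 170-ms implant and one the
300-ms implant.  `conventionalAnalysis()` runs the rmANOVA route
(e.g. `F(2, 14)`, partial η², pairwise paired t-tests) on the same
epochs, and `runPipeline(runConfig(...), "out/")` executes the whole
chain — simulation, training, attribution, SHERPA report, both
comparators, a cross-method comparison table and figure-ready CSV
exports — into one run directory with a single global seed.

A thin command-line front end lives at `inst/cli/sherpa-cli.R`
(`simulate`, `run-all`, `export-figures`, `permtest`, `anova`).

## Documentation

The methods vignette (`vignettes/sherpa-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with units and
defaults, the synthetic generator's scope, numerical edge-case policies
and known limitations.
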