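# Shared fixtures, all generated in code.

# A tiny valid EpochedData block with float32-representable values so the
# container roundtrip is bit-exact.
tinyEpochs <- function(nTrials = 6, nCh = 4, nT = 16, sfreq = 512,
                       t0 = 0, nSubjects = 3) {
  set.seed(99)
  data <- array(round(rnorm(nTrials * nCh * nT) * 256) / 256, # 2^-8 grid
                c(nTrials, nCh, nT))
  EpochedData(data,
              labels = rep(c("face", "blurred", "scrambled"),
                           length.out = nTrials),
              sfreq = sfreq, t0 = t0,
              subjectIds = rep(sprintf("S%02d", seq_len(nSubjects)),
                               length.out = nTrials))
}

# Small separable 3-condition simulation (6 channels, 32 samples) used
# for quick classifier and attribution checks.
smallSepConfig <- function(seed = 2, nSubjects = 4, trialsPerCondition = 25,
                           noise = noiseSpec(pinkSD = 1, whiteSD = 0.5)) {
  cond <- c("a", "b", "c")
  lay <- sphericalLayout(6)
  comps <- list(
    componentSpec(20, 6, 5, stats::setNames(c(1, .5, 0, 0, 0, 0), lay$name),
                  stats::setNames(c(1, 0.2, 0.6), cond), name = "early"),
    componentSpec(45, 8, -4, stats::setNames(c(0, 0, 0, .3, 1, .6), lay$name),
                  stats::setNames(c(0.1, 1, 0.4), cond), name = "late"))
  simulationConfig(cond, nSubjects = nSubjects,
                   trialsPerCondition = trialsPerCondition, layout = lay,
                   sfreq = 512, tStart = 0, tEnd = 62.5,
                   components = comps, noise = noise, seed = seed)
}

# Reduced-geometry exchangeable-null config: 16 channels, 64 samples,
# spatially smoothed noise (EEG noise is spatially correlated; without
# that the 2-adjacent-channel cluster rule would be vacuous).
nullSmallConfig <- function(seed = 1) {
  cond <- c("face", "blurred", "scrambled")
  lay <- sphericalLayout(16)
  eq <- stats::setNames(c(1, 1, 1), cond)
  comps <- list(
    componentSpec(40, 10, 3, sherpa:::.gaussTopo(lay, c(0, -0.8, 0.6), 0.6),
                  eq, name = "p1"),
    componentSpec(80, 12, -4,
                  sherpa:::.gaussTopo(lay, c(0.7, -0.6, 0.4), 0.5),
                  eq, name = "n1"))
  simulationConfig(cond, nSubjects = 8, trialsPerCondition = 8,
                   layout = lay, sfreq = 512, tStart = 0, tEnd = 125,
                   components = comps,
                   noise = noiseSpec(pinkSD = 2, whiteSD = 1,
                                     spatialSmoothing = 0.5),
                   seed = seed)
}

# A fast pipeline configuration for orchestration tests.
miniRunConfig <- function(seed = 7, effect = "strong") {
  runConfig(
    simulation = presetDesk(effect, nSubjects = 4, trialsPerCondition = 8,
                            nChannels = 16, seed = seed),
    model = deskModelSpec(convFilters = c(4L, 8L), denseUnits = c(16L, 8L)),
    training = trainingConfig(maxEpochs = 2L, earlyStopPatience = 2L,
                              nFolds = 2L, holdoutSubjects = 1L,
                              seed = seed),
    perm = permConfig(nPermutations = 60L),
    backgroundSize = 30L, nPathSamples = 16L, seed = seed)
}

# Independent brute-force local-maximum reference for the peak finder.
bruteForcePeaks <- function(v, order) {
  n <- length(v)
  idx <- integer(0)
  for (i in 2:(n - 1)) {
    ok <- TRUE
    for (j in max(1, i - order):min(n, i + order)) {
      if (j != i && !(v[i] > v[j])) { ok <- FALSE; break }
    }
    if (ok) idx <- c(idx, i)
  }
  idx
}
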