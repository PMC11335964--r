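## Synthetic epoched-ERP generator.  Each ERP component is a Gaussian time
## course times a fixed scalp topography, scaled per condition; trials add
## amplitude/latency jitter plus pink (1/f) and white noise.  The generator
## reproduces the statistical structure the downstream analyses assume
## (within-subject design, balanced conditions, exchangeable labels under
## equal gains) without any biophysical forward modelling.

#' Specify one ERP component
#'
#' @param latency peak latency in ms.
#' @param width Gaussian SD of the time course in ms (> 0).
#' @param amplitude signed peak amplitude in microvolts (at the topography
#'   maximum, before condition gain and jitter).
#' @param topography per-channel weight in `[-1, 1]`; either a named
#'   vector (matched to channel names) or an unnamed vector in channel
#'   order.
#' @param conditionGains named numeric, one multiplier per condition.
#' @param latencyJitterSD per-trial latency jitter SD in ms.
#' @param amplitudeJitterSD per-trial multiplicative amplitude jitter SD
#'   (fraction).
#' @param name optional component name.
#' @return a `ComponentSpec` list.
#' @export
componentSpec <- function(latency, width, amplitude, topography,
                          conditionGains, latencyJitterSD = 0,
                          amplitudeJitterSD = 0, name = "component") {
  .assertScalarNumber(width, "width", positive = TRUE)
  .assertScalarNumber(latency, "latency")
  .assertScalarNumber(amplitude, "amplitude")
  structure(list(latency = latency, width = width, amplitude = amplitude,
                 topography = topography, conditionGains = conditionGains,
                 latencyJitterSD = latencyJitterSD,
                 amplitudeJitterSD = amplitudeJitterSD, name = name),
            class = "ComponentSpec")
}

#' Specify the additive noise model
#'
#' @param pinkSD per-channel SD in microvolts of the 1/f ("pink")
#'   component, synthesized in the frequency domain with power spectral
#'   density proportional to `1/f^exponent` and random phases.
#' @param whiteSD per-sample white noise SD in microvolts.
#' @param spatialSmoothing neighbour-mixing coefficient in `[0, 1)`; the
#'   noise of each channel is mixed with the mean of its adjacent
#'   channels (requires a layout in the simulation config).
#' @param exponent spectral exponent of the coloured component (1 = pink).
#' @return a `NoiseSpec` list.
#' @export
noiseSpec <- function(pinkSD = 0, whiteSD = 0, spatialSmoothing = 0,
                      exponent = 1) {
  stopifnot(pinkSD >= 0, whiteSD >= 0,
            spatialSmoothing >= 0, spatialSmoothing < 1)
  structure(list(pinkSD = pinkSD, whiteSD = whiteSD,
                 spatialSmoothing = spatialSmoothing, exponent = exponent),
            class = "NoiseSpec")
}

#' Assemble a full simulation configuration
#'
#' @param conditions ordered condition names.
#' @param nSubjects number of subjects.
#' @param trialsPerCondition trials per condition per subject (balanced).
#' @param layout channel layout `data.frame` (see [sphericalLayout()]).
#' @param sfreq sampling rate in Hz.
#' @param tStart,tEnd epoch span in ms, half-open `[tStart, tEnd)`.
#' @param components list of [componentSpec()] objects.
#' @param noise a [noiseSpec()] object.
#' @param seed default seed used by [simulateEpochs()].
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(conditions, nSubjects, trialsPerCondition,
                             layout, sfreq, tStart = 0, tEnd,
                             components, noise = noiseSpec(), seed = 1L) {
  stopifnot(length(conditions) >= 1, nSubjects >= 1,
            trialsPerCondition >= 1, tStart < tEnd)
  for (comp in components) {
    stopifnot(inherits(comp, "ComponentSpec"))
    miss <- setdiff(conditions, names(comp$conditionGains))
    if (length(miss))
      stop(sprintf("component '%s' lacks gains for condition(s): %s",
                   comp$name, paste(miss, collapse = ", ")))
  }
  structure(list(conditions = as.character(conditions),
                 nSubjects = as.integer(nSubjects),
                 trialsPerCondition = as.integer(trialsPerCondition),
                 layout = layout, sfreq = sfreq, tStart = tStart,
                 tEnd = tEnd, components = components, noise = noise,
                 seed = seed),
            class = "SimulationConfig")
}

#' Gaussian time course of an ERP component
#'
#' `exp(-(t - latency)^2 / (2 width^2))`: unit peak at the component
#' latency, before amplitude scaling.
#'
#' @param spec a [componentSpec()] (or anything with `latency`/`width`).
#' @param times latency grid in ms.
#' @param latencyShift additive latency offset in ms (trial jitter).
#' @return numeric vector of per-sample weights in `(0, 1]`.
#' @export
componentTimecourse <- function(spec, times, latencyShift = 0) {
  if (!length(times)) stop("'times' must be nonempty")
  if (spec$width <= 0) stop("'width' must be > 0")
  exp(-(times - spec$latency - latencyShift)^2 / (2 * spec$width^2))
}

## Coloured noise, one column per channel: hermitian spectrum with
## amplitude f^(-exponent/2) and uniform random phases, scaled so each
## channel has exactly unit theoretical SD.
.colouredNoise <- function(nTimes, nChannels, exponent = 1) {
  nFreq <- nTimes %/% 2L
  if (nFreq < 1L) return(matrix(rnorm(nTimes * nChannels), nTimes))
  k <- seq_len(nFreq)
  amp <- k^(-exponent / 2)
  out <- matrix(0, nTimes, nChannels)
  phases <- matrix(runif(nFreq * nChannels, 0, 2 * pi), nFreq)
  for (ch in seq_len(nChannels)) {
    spec <- complex(modulus = amp, argument = phases[, ch])
    full <- complex(length.out = nTimes)
    full[1L + k] <- spec
    # hermitian mirror (excluding DC; Nyquist, if present, overlaps k = n/2)
    idx <- nTimes + 1L - k
    keep <- idx > nFreq + 1L
    full[idx[keep]] <- Conj(spec[keep])
    x <- Re(fft(full, inverse = TRUE)) / nTimes
    out[, ch] <- x / sqrt(sum(Mod(full)^2) / nTimes^2)
  }
  out
}

.resolveTopography <- function(topo, channels, compName) {
  if (!is.null(names(topo))) {
    w <- rep(0, length(channels))
    names(w) <- channels
    known <- intersect(names(topo), channels)
    w[known] <- topo[known]
    w
  } else {
    if (length(topo) != length(channels))
      stop(sprintf("component '%s': unnamed topography length %d != %d channels",
                   compName, length(topo), length(channels)))
    stats::setNames(as.numeric(topo), channels)
  }
}

#' Simulate epoched EEG from a configuration
#'
#' Every trial is the sum over components of
#' `gain * (1 + amplitude jitter) * amplitude * topography (x) timecourse`
#' (with per-trial latency jitter) plus pink and white noise.
#' Deterministic given the seed; trials are balanced across conditions
#' within every subject.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return an [EpochedData-class] object.
#' @export
simulateEpochs <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  k <- length(config$conditions)
  nTr <- config$nSubjects * config$trialsPerCondition * k
  if (nTr == 0L) stop("configuration yields zero trials")
  nT <- round((config$tEnd - config$tStart) * config$sfreq / 1000)
  if (nT < 1L) stop("epoch span shorter than one sample period")
  times <- config$tStart + (seq_len(nT) - 1) * 1000 / config$sfreq
  channels <- config$layout$name
  nCh <- length(channels)

  topos <- lapply(config$components, function(comp)
    .resolveTopography(comp$topography, channels, comp$name))

  smoothM <- NULL
  if (config$noise$spatialSmoothing > 0) {
    adj <- buildAdjacency(config$layout)
    A <- matrix(0, nCh, nCh, dimnames = list(channels, channels))
    for (ch in channels) {
      nb <- adj[[ch]]
      if (length(nb)) A[ch, nb] <- 1 / length(nb)
    }
    s <- config$noise$spatialSmoothing
    smoothM <- (1 - s) * diag(nCh) + s * A
  }

  set.seed(seed)
  labels <- character(nTr)
  subjects <- character(nTr)
  data <- array(0, c(nTr, nCh, nT))
  tr <- 0L
  for (s in seq_len(config$nSubjects)) {
    sid <- sprintf("S%02d", s)
    for (cond in config$conditions) {
      for (r in seq_len(config$trialsPerCondition)) {
        tr <- tr + 1L
        labels[tr] <- cond
        subjects[tr] <- sid
        sig <- matrix(0, nCh, nT)
        for (ci in seq_along(config$components)) {
          comp <- config$components[[ci]]
          latJ <- if (comp$latencyJitterSD > 0)
            rnorm(1, 0, comp$latencyJitterSD) else 0
          ampJ <- if (comp$amplitudeJitterSD > 0)
            rnorm(1, 0, comp$amplitudeJitterSD) else 0
          gain <- comp$conditionGains[[cond]]
          if (gain == 0 && comp$latencyJitterSD <= 0) next
          tc <- componentTimecourse(comp, times, latencyShift = latJ)
          sig <- sig + (gain * comp$amplitude * (1 + ampJ)) *
            tcrossprod(topos[[ci]], tc)
        }
        noise <- matrix(0, nCh, nT)
        if (config$noise$pinkSD > 0)
          noise <- noise + config$noise$pinkSD *
            t(.colouredNoise(nT, nCh, config$noise$exponent))
        if (config$noise$whiteSD > 0)
          noise <- noise + matrix(rnorm(nCh * nT, 0, config$noise$whiteSD),
                                  nCh, nT)
        if (!is.null(smoothM)) noise <- smoothM %*% noise
        data[tr, , ] <- sig + noise
      }
    }
  }
  EpochedData(data, labels = labels, sfreq = config$sfreq,
              t0 = config$tStart, channels = channels,
              subjectIds = subjects, conditions = config$conditions)
}

#' Simulate a null dataset (exchangeable labels)
#'
#' Replaces every component's condition gains by their mean, so the
#' condition labels carry no signal and are exchangeable -- the substrate
#' for type-I-error checks of the permutation test.
#'
#' @inheritParams simulateEpochs
#' @return an [EpochedData-class] object.
#' @export
nullDataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  config$components <- lapply(config$components, function(comp) {
    g <- mean(unlist(comp$conditionGains[config$conditions]))
    comp$conditionGains <- stats::setNames(
      rep(g, length(config$conditions)), config$conditions)
    comp
  })
  simulateEpochs(config, seed = seed)
}

## Gaussian scalp weight map centred on a 3-D direction.
.gaussTopo <- function(layout, center, sigma) {
  center <- center / sqrt(sum(center^2))
  P <- as.matrix(layout[, c("x", "y", "z")])
  d2 <- rowSums(sweep(P, 2, center)^2)
  stats::setNames(exp(-d2 / (2 * sigma^2)), layout$name)
}

.presetComponents <- function(layout, gainsN170, gainsLate, sigmaScale = 1) {
  conditions <- c("face", "blurred", "scrambled")
  topoP100 <- .gaussTopo(layout, c(0, -0.8, 0.6), 0.6 * sigmaScale)
  topoN170 <- pmax(.gaussTopo(layout, c(0.75, -0.55, 0.5), 0.4 * sigmaScale),
                   .gaussTopo(layout, c(-0.75, -0.55, 0.5), 0.4 * sigmaScale))
  topoLate <- .gaussTopo(layout, c(0, -0.35, 0.94), 0.6 * sigmaScale)
  list(
    componentSpec(100, 12, 4, topoP100,
                  stats::setNames(c(1, 1, 1), conditions),
                  latencyJitterSD = 5, amplitudeJitterSD = 0.1,
                  name = "P100"),
    componentSpec(170, 15, -6, topoN170, gainsN170,
                  latencyJitterSD = 5, amplitudeJitterSD = 0.1,
                  name = "N170"),
    componentSpec(300, 25, 4, topoLate, gainsLate,
                  latencyJitterSD = 8, amplitudeJitterSD = 0.1,
                  name = "late300"))
}

.effectGains <- function(effect) {
  conditions <- c("face", "blurred", "scrambled")
  n170 <- switch(effect,
    strong   = c(1.0, 0.2, 0.6),
    moderate = c(1.0, 0.5, 0.9),
    typical  = c(1.0, 0.5, 0.9),
    null     = c(1.0, 1.0, 1.0))
  late <- switch(effect,
    strong   = c(1.0, 0.1, 0.1),
    moderate = c(1.0, 0.5, 0.5),
    typical  = c(1.0, 0.5, 0.5),
    null     = c(0.4, 0.4, 0.4))
  list(n170 = stats::setNames(n170, conditions),
       late = stats::setNames(late, conditions))
}

#' Reduced "desk" preset: fast, fully testable geometry
#'
#' Three conditions x 8 subjects x 30 trials on 32 synthetic electrodes,
#' 0--500 ms at 512 Hz (256 samples).  Components: an equal-gain positive
#' posterior deflection at 100 ms, a condition-dependent negative
#' occipito-temporal deflection at 170 ms, and a late (300 ms)
#' face-selective positive component.
#'
#' @param effect `"strong"` (well-separated classes), `"moderate"`
#'   (ordering face > scrambled > blurred on the 170 ms component, weakest
#'   for blurred) or `"null"` (equal gains, exchangeable labels).
#' @param nSubjects,trialsPerCondition,nChannels,sfreq geometry overrides.
#' @param seed default simulation seed.
#' @return a [simulationConfig()].
#' @export
presetDesk <- function(effect = c("strong", "moderate", "null"),
                       nSubjects = 8, trialsPerCondition = 30,
                       nChannels = 32, sfreq = 512, seed = 1L) {
  effect <- match.arg(effect)
  layout <- sphericalLayout(nChannels)
  g <- .effectGains(effect)
  simulationConfig(conditions = c("face", "blurred", "scrambled"),
                   nSubjects = nSubjects,
                   trialsPerCondition = trialsPerCondition,
                   layout = layout, sfreq = sfreq, tStart = 0, tEnd = 500,
                   components = .presetComponents(layout, g$n170, g$late),
                   noise = noiseSpec(pinkSD = 2, whiteSD = 1),
                   seed = seed)
}

#' Study-scale preset: 26 subjects, 128 channels, 0--1500 ms
#'
#' Emulates the face/blurred/scrambled design at full scale on the
#' packaged BioSemi 128-channel layout: equal-gain P100-like component,
#' an N170-like lateral-posterior component whose gain is weakest for
#' blurred faces, and a late (300 ms) face-selective component.  The
#' gains are fixture parameters of the generator, not measured facts.
#'
#' @param effect `"typical"` (face 1.0 / blurred 0.5 / scrambled 0.9 on
#'   the 170 ms component, blurred weakest), `"strong"` or `"null"`.
#' @param nSubjects,trialsPerCondition,sfreq geometry overrides (reduce
#'   them for quick runs; the defaults mirror the study design).
#' @param seed default simulation seed.
#' @return a [simulationConfig()].
#' @export
presetN170 <- function(effect = c("typical", "strong", "null"),
                       nSubjects = 26, trialsPerCondition = 60,
                       sfreq = 512, seed = 1L) {
  effect <- match.arg(effect)
  layout <- biosemiLayout()
  g <- .effectGains(effect)
  simulationConfig(conditions = c("face", "blurred", "scrambled"),
                   nSubjects = nSubjects,
                   trialsPerCondition = trialsPerCondition,
                   layout = layout, sfreq = sfreq, tStart = 0, tEnd = 1500,
                   components = .presetComponents(layout, g$n170, g$late),
                   noise = noiseSpec(pinkSD = 2, whiteSD = 1,
                                     spatialSmoothing = 0.3),
                   seed = seed)
}
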