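#' @import methods
NULL

## Central data containers.  All heavy numeric blocks are plain arrays in
## slots; geometry (channel names, time axis) travels with the values so
## every downstream stage can validate against it.

#' EpochedData: trials x channels x times voltage block with metadata
#'
#' The common currency of the pipeline: a 3-D numeric array of epoched,
#' preprocessed EEG amplitudes (microvolts) together with per-trial
#' condition labels, per-trial subject identifiers, the time axis in ms and
#' the ordered channel names.  The channel order fixes the channel axis
#' everywhere downstream.
#'
#' @slot data numeric array `[n_trials, n_channels, n_times]`, microvolts.
#' @slot labels character, one condition name per trial.
#' @slot conditions character, the declared (ordered) condition names.
#' @slot times numeric, sample latencies in ms, uniformly spaced at
#'   `1000 / sfreq`.
#' @slot sfreq numeric scalar, sampling rate in Hz.
#' @slot channels character, unique ordered channel names.
#' @slot subjectIds character, one subject identifier per trial.
#' @export
setClass("EpochedData",
  representation(data = "array", labels = "character",
                 conditions = "character", times = "numeric",
                 sfreq = "numeric", channels = "character",
                 subjectIds = "character"))

setValidity("EpochedData", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("'data' must be a 3-D array [trials x channels x times]")
  if (length(object@labels) != d[1L])
    return(sprintf("'labels' has length %d but data has %d trials",
                   length(object@labels), d[1L]))
  if (length(object@subjectIds) != d[1L])
    return(sprintf("'subjectIds' has length %d but data has %d trials",
                   length(object@subjectIds), d[1L]))
  if (length(object@channels) != d[2L])
    return(sprintf("'channels' has length %d but data has %d channels",
                   length(object@channels), d[2L]))
  if (anyDuplicated(object@channels))
    return("'channels' must be unique")
  if (length(object@times) != d[3L])
    return(sprintf("'times' has length %d but data has %d samples",
                   length(object@times), d[3L]))
  if (length(object@sfreq) != 1L || !is.finite(object@sfreq) ||
      object@sfreq <= 0)
    return("'sfreq' must be a positive scalar (Hz)")
  if (d[3L] >= 2L) {
    dt <- diff(object@times)
    if (any(dt <= 0))
      return("'times' must be strictly increasing")
    if (max(abs(dt - 1000 / object@sfreq)) > 1e-9)
      return("'times' spacing must equal 1000/sfreq within 1e-9 ms")
  }
  bad <- setdiff(unique(object@labels), object@conditions)
  if (length(bad))
    return(sprintf("labels contain undeclared conditions: %s",
                   paste(bad, collapse = ", ")))
  TRUE
})

#' AttributionTensor: per-trial, per-class feature attributions
#'
#' Signed expected-gradients SHAP values with the same channel/time
#' geometry as the epochs they explain, in units of the model output
#' (class probability).
#'
#' @slot values numeric array `[n_trials, n_classes, n_channels, n_times]`.
#' @slot classes character, class (condition) names, second axis.
#' @slot channels character, channel names, third axis.
#' @slot times numeric, latencies in ms, fourth axis.
#' @slot trialLabels character, condition label of each explained trial
#'   (may be `NA` when unknown).
#' @slot provenance list: model hash, background size, `nPathSamples`, seed.
#' @export
setClass("AttributionTensor",
  representation(values = "array", classes = "character",
                 channels = "character", times = "numeric",
                 trialLabels = "character", provenance = "list"))

setValidity("AttributionTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L)
    return("'values' must be 4-D [trials x classes x channels x times]")
  if (length(object@classes) != d[2L]) return("class axis mismatch")
  if (length(object@channels) != d[3L]) return("channel axis mismatch")
  if (length(object@times) != d[4L]) return("time axis mismatch")
  if (length(object@trialLabels) != d[1L]) return("trialLabels length mismatch")
  if (!all(is.finite(object@values))) return("'values' must be finite")
  TRUE
})

#' ImportanceMatrix: channels x times aggregated absolute attributions
#'
#' Mean over trials of the class-summed absolute SHAP values; the object
#' behind the contour plot of importance over the scalp and time.
#'
#' @slot values nonnegative numeric matrix `[n_channels, n_times]`.
#' @slot channels character, row names.
#' @slot times numeric, column latencies in ms.
#' @slot aggregation character, a human-readable descriptor.
#' @export
setClass("ImportanceMatrix",
  representation(values = "matrix", channels = "character",
                 times = "numeric", aggregation = "character"))

setValidity("ImportanceMatrix", function(object) {
  if (nrow(object@values) != length(object@channels))
    return("row/channel mismatch")
  if (ncol(object@values) != length(object@times))
    return("column/time mismatch")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("'values' must be finite and >= 0")
  TRUE
})

#' ImportanceCurve: per-class importance over time
#'
#' For one target class, the electrode-summed absolute attribution at each
#' time point, averaged over the scoped trials.
#'
#' @slot className character scalar, the target class.
#' @slot values nonnegative numeric, one entry per time sample.
#' @slot times numeric, latencies in ms.
#' @slot scope character, `"all_trials"` or `"class_trials"`.
#' @export
setClass("ImportanceCurve",
  representation(className = "character", values = "numeric",
                 times = "numeric", scope = "character"))

setValidity("ImportanceCurve", function(object) {
  if (length(object@values) != length(object@times))
    return("values/times length mismatch")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("'values' must be finite and >= 0")
  if (!object@scope %in% c("all_trials", "class_trials"))
    return("scope must be 'all_trials' or 'class_trials'")
  TRUE
})

#' ClusterResult: spatio-temporal clusters and their permutation p-values
#'
#' @slot clusters list; each element has `members` (two-column integer
#'   matrix of channel/time indices), `channels`, `timeRange` (ms) and
#'   `mass` (sum of F over members).
#' @slot nullDistribution numeric, per-permutation maximum cluster mass.
#' @slot pValues numeric, one Monte-Carlo p per cluster.
#' @slot threshold numeric scalar, the sample-level F threshold.
#' @slot dfNum,dfDen numeric, the F map degrees of freedom.
#' @slot nPermutations integer.
#' @slot seed integer seed used for the permutation stream.
#' @export
setClass("ClusterResult",
  representation(clusters = "list", nullDistribution = "numeric",
                 pValues = "numeric", threshold = "numeric",
                 dfNum = "numeric", dfDen = "numeric",
                 nPermutations = "integer", seed = "integer"))

setValidity("ClusterResult", function(object) {
  if (length(object@pValues) != length(object@clusters))
    return("one p-value per cluster required")
  if (length(object@pValues)) {
    lo <- 1 / (object@nPermutations + 1)
    if (any(object@pValues < lo - 1e-12 | object@pValues > 1 + 1e-12))
      return("p-values must lie in [1/(n_permutations+1), 1]")
  }
  TRUE
})

setMethod("show", "EpochedData", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochedData: %d trials x %d channels x %d samples\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  time: %.2f..%.2f ms @ %g Hz\n",
              object@times[1L], object@times[length(object@times)],
              object@sfreq))
  tab <- table(object@labels)
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  cat(sprintf("  subjects: %d\n", length(unique(object@subjectIds))))
})

setMethod("show", "AttributionTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "AttributionTensor: %d trials x %d classes x %d channels x %d samples\n",
    d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  classes: %s\n", paste(object@classes, collapse = ", ")))
})

setMethod("show", "ImportanceMatrix", function(object) {
  cat(sprintf("ImportanceMatrix: %d channels x %d samples (%s)\n",
              nrow(object@values), ncol(object@values), object@aggregation))
})

setMethod("show", "ImportanceCurve", function(object) {
  cat(sprintf("ImportanceCurve[%s, %s]: %d samples, peak %.4g at %.2f ms\n",
              object@className, object@scope, length(object@values),
              max(object@values),
              object@times[which.max(object@values)]))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf(
    "ClusterResult: %d cluster(s), threshold F(%g,%g) > %.4f, %d permutations\n",
    length(object@clusters), object@dfNum, object@dfDen, object@threshold,
    object@nPermutations))
  if (length(object@clusters)) {
    for (i in seq_along(object@clusters)) {
      cl <- object@clusters[[i]]
      cat(sprintf("  #%d: %d samples, %d channels, %.2f..%.2f ms, mass %.2f, p = %.4g\n",
                  i, nrow(cl$members), length(cl$channels),
                  cl$timeRange[1L], cl$timeRange[2L], cl$mass,
                  object@pValues[i]))
    }
  }
})
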