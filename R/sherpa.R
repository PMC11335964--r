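#' Configure the SHERPA distillation stage
#'
#' @param extremumOrder neighbourhood half-width, in samples, of the
#'   local-extremum comparison (a sample is a peak iff it strictly
#'   exceeds every neighbour within this many samples).  Default 10
#'   samples (about 19.5 ms at 512 Hz).
#' @param windowLength length in ms of the window cut around each peak
#'   (the peak is the exact center); default 40 ms.
#' @param quantileThresholds empirical quantiles defining the important
#'   electrode sets; default `c(0.75, 0.9)`.
#' @param topKPeaks maximum number of peaks retained per class.
#' @return a `SherpaConfig` list.
#' @export
sherpaConfig <- function(extremumOrder = 10L, windowLength = 40,
                         quantileThresholds = c(0.75, 0.9),
                         topKPeaks = 5L) {
  stopifnot(extremumOrder >= 1, windowLength > 0,
            all(quantileThresholds > 0 & quantileThresholds < 1),
            topKPeaks >= 1)
  structure(list(extremumOrder = as.integer(extremumOrder),
                 windowLength = windowLength,
                 quantileThresholds = sort(quantileThresholds),
                 topKPeaks = as.integer(topKPeaks)),
            class = "SherpaConfig")
}

#' Find local maxima of an importance curve
#'
#' Sample `i` is a peak iff `curve[i] > curve[j]` for every other `j`
#' within `extremumOrder` samples (strict inequality: flat plateaus yield
#' no peak; curve endpoints are never peaks).  Peaks are returned sorted
#' by descending importance and truncated to `topKPeaks`.
#'
#' @param curve an [ImportanceCurve-class] (or plain numeric vector).
#' @param cfg a [sherpaConfig()].
#' @param times time axis in ms when `curve` is a plain vector.
#' @return a `data.frame` with columns `sample` (0-based offset),
#'   `latency` (ms) and `value`; zero rows when there is no peak.
#' @export
findImportancePeaks <- function(curve, cfg = sherpaConfig(),
                                times = NULL) {
  if (is(curve, "ImportanceCurve")) {
    times <- curve@times
    v <- curve@values
  } else {
    v <- as.numeric(curve)
    if (is.null(times)) times <- seq_along(v) - 1
  }
  n <- length(v)
  ord <- cfg$extremumOrder
  if (n <= 2L * ord)
    stop(sprintf("curve length (%d) must exceed 2*extremumOrder (%d)",
                 n, 2L * ord))
  isPeak <- logical(n)
  for (i in 2L:(n - 1L)) {
    lo <- max(1L, i - ord); hi <- min(n, i + ord)
    nb <- v[lo:hi][-(i - lo + 1L)]
    isPeak[i] <- all(v[i] > nb)
  }
  idx <- which(isPeak)
  out <- data.frame(sample = idx - 1L, latency = times[idx],
                    value = v[idx])
  out <- out[order(-out$value, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  head(out, cfg$topKPeaks)
}

#' Cut a time window centered on a peak
#'
#' `tLo = peak - windowLength/2`, `tHi = peak + windowLength/2`, clipped
#' to the time grid (with a flag when clipping occurred); the sample
#' range is the nearest-sample index span of `[tLo, tHi]`, inclusive.
#'
#' @param peakLatency peak latency in ms (on the grid).
#' @param windowLength window length in ms (> 0).
#' @param times the time grid in ms.
#' @return a `Window` list: `tLo`, `tHi` (ms), `idxLo`, `idxHi` (1-based
#'   sample indices into `times`), `clipped`.
#' @export
extractWindow <- function(peakLatency, windowLength, times) {
  .assertScalarNumber(peakLatency, "peakLatency")
  if (windowLength <= 0) stop("'windowLength' must be > 0")
  stopifnot(length(times) >= 2L)
  tLo <- peakLatency - windowLength / 2
  tHi <- peakLatency + windowLength / 2
  clipped <- FALSE
  if (tLo < times[1L]) { tLo <- times[1L]; clipped <- TRUE }
  if (tHi > times[length(times)]) {
    tHi <- times[length(times)]; clipped <- TRUE
  }
  sfreq <- 1000 / (times[2L] - times[1L])
  idxLo <- timeToIndex(tLo, sfreq, t0 = times[1L]) + 1L
  idxHi <- timeToIndex(tHi, sfreq, t0 = times[1L]) + 1L
  idxLo <- max(1L, min(idxLo, length(times)))
  idxHi <- max(1L, min(idxHi, length(times)))
  structure(list(tLo = tLo, tHi = tHi, idxLo = idxLo, idxHi = idxHi,
                 clipped = clipped),
            class = "Window")
}

#' @export
print.Window <- function(x, ...) {
  cat(sprintf("Window: %.2f..%.2f ms (samples %d..%d%s)\n", x$tLo, x$tHi,
              x$idxLo, x$idxHi, if (x$clipped) ", clipped" else ""))
  invisible(x)
}

#' Rank electrodes inside a time window
#'
#' Each electrode's score is the mean importance over the window samples
#' (mean, not sum, so reports are comparable across window lengths); the
#' quantile sets collect the electrodes whose score reaches each
#' configured empirical quantile of the score distribution.  The sets
#' are nested by construction.
#'
#' @param matrix an [ImportanceMatrix-class].
#' @param window a `Window` from [extractWindow()].
#' @param cfg a [sherpaConfig()].
#' @return a `WindowReport` list: `window`, `scores` (named, descending),
#'   `quantileSets` (named list of channel vectors), `condition`, `peak`.
#' @export
rankElectrodes <- function(matrix, window, cfg = sherpaConfig()) {
  stopifnot(is(matrix, "ImportanceMatrix"), inherits(window, "Window"))
  if (window$idxLo > ncol(matrix@values) || window$idxHi < 1L ||
      window$idxHi < window$idxLo)
    stop("window lies outside the matrix time range")
  cols <- window$idxLo:window$idxHi
  scores <- rowMeans(matrix@values[, cols, drop = FALSE])
  names(scores) <- matrix@channels
  qsets <- lapply(cfg$quantileThresholds, function(q) {
    thr <- quantile(scores, q, names = FALSE)
    names(scores)[scores >= thr]
  })
  names(qsets) <- sprintf("q%g", cfg$quantileThresholds)
  structure(list(window = window,
                 scores = sort(scores, decreasing = TRUE),
                 quantileSets = qsets, condition = NA_character_,
                 peak = NULL),
            class = "WindowReport")
}

#' @export
print.WindowReport <- function(x, ...) {
  cat(sprintf("WindowReport%s: %.2f..%.2f ms\n",
              if (!is.na(x$condition)) paste0(" [", x$condition, "]") else "",
              x$window$tLo, x$window$tHi))
  top <- head(x$scores, 5L)
  cat("  top electrodes:",
      paste(sprintf("%s=%.4g", names(top), top), collapse = ", "), "\n")
  for (nm in names(x$quantileSets))
    cat(sprintf("  %s set (%d): %s\n", nm, length(x$quantileSets[[nm]]),
                paste(x$quantileSets[[nm]], collapse = " ")))
  invisible(x)
}

#' Distill an attribution tensor into per-condition window reports
#'
#' For every class: build its importance curve, find the local maxima,
#' cut a window around each retained peak, and rank electrodes in that
#' window against the trial-and-class aggregated importance matrix.
#'
#' @param attr an [AttributionTensor-class].
#' @param cfg a [sherpaConfig()].
#' @param trialScope scope of the per-class curves (see
#'   [classImportanceCurve()]).
#' @return a `SherpaReport`: named list (one entry per class) of lists of
#'   `WindowReport`s, with the peak table attached; empty per-class lists
#'   when no peak exists.
#' @export
sherpaReport <- function(attr, cfg = sherpaConfig(),
                         trialScope = "all_trials") {
  stopifnot(is(attr, "AttributionTensor"))
  mat <- aggregateImportance(attr)
  out <- list()
  for (cls in attr@classes) {
    curve <- classImportanceCurve(attr, cls, trialScope = trialScope)
    peaks <- findImportancePeaks(curve, cfg)
    reports <- list()
    if (nrow(peaks)) {
      for (pi in seq_len(nrow(peaks))) {
        win <- extractWindow(peaks$latency[pi], cfg$windowLength,
                             attr@times)
        rep_ <- rankElectrodes(mat, win, cfg)
        rep_$condition <- cls
        rep_$peak <- as.list(peaks[pi, ])
        reports[[pi]] <- rep_
      }
    }
    out[[cls]] <- list(peaks = peaks, windows = reports)
  }
  structure(out, class = "SherpaReport", config = cfg)
}

#' @export
print.SherpaReport <- function(x, ...) {
  cat("SherpaReport\n")
  for (cls in names(x)) {
    p <- x[[cls]]$peaks
    if (!nrow(p)) {
      cat(sprintf("  %s: no peaks\n", cls))
      next
    }
    cat(sprintf("  %s: peaks at %s ms (summed importance %s)\n", cls,
                paste(sprintf("%.2f", p$latency), collapse = ", "),
                paste(signif(p$value, 3), collapse = ", ")))
  }
  invisible(x)
}

## Plain-list view used for JSON export.
.sherpaReportAsList <- function(report) {
  lapply(report, function(cls) {
    list(peaks = cls$peaks,
         windows = lapply(cls$windows, function(w) list(
           condition = w$condition,
           peak = w$peak,
           tLo = w$window$tLo, tHi = w$window$tHi,
           clipped = w$window$clipped,
           scores = as.list(w$scores),
           quantileSets = w$quantileSets)))
  })
}

#' Write a SherpaReport as JSON
#'
#' @param report a `SherpaReport`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSherpaReport <- function(report, path) {
  stopifnot(inherits(report, "SherpaReport"))
  .writeJSON(.sherpaReportAsList(report), path)
}
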