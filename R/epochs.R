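#' Construct an EpochedData object
#'
#' @param data numeric array `[n_trials, n_channels, n_times]` (microvolts).
#' @param labels character (or factor), one condition per trial.
#' @param sfreq sampling rate in Hz.
#' @param t0 latency of the first sample in ms (ignored when `times` given).
#' @param times optional explicit time axis in ms; defaults to a uniform
#'   grid `t0 + (0:(n_times-1)) * 1000/sfreq`.
#' @param channels optional channel names; default `ch001`, `ch002`, ...
#' @param subjectIds character, one subject identifier per trial.
#' @param conditions declared condition order; defaults to the sorted
#'   unique labels.
#' @return a validated [EpochedData-class] object.
#' @examples
#' x <- EpochedData(array(0, c(2, 3, 4)), labels = c("a", "b"),
#'                  sfreq = 1000, subjectIds = c("s1", "s1"))
#' nTimes(x)
#' @export
EpochedData <- function(data, labels, sfreq, t0 = 0, times = NULL,
                        channels = NULL, subjectIds,
                        conditions = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array [trials x channels x times]")
  labels <- as.character(labels)
  subjectIds <- as.character(subjectIds)
  if (is.null(times))
    times <- t0 + (seq_len(dim(data)[3L]) - 1) * 1000 / sfreq
  if (is.null(channels))
    channels <- sprintf("ch%03d", seq_len(dim(data)[2L]))
  if (is.null(conditions)) conditions <- sort(unique(labels))
  new("EpochedData", data = data, labels = labels,
      conditions = as.character(conditions), times = as.numeric(times),
      sfreq = as.numeric(sfreq), channels = as.character(channels),
      subjectIds = subjectIds)
}

#' @describeIn EpochedData number of trials
#' @param x an `EpochedData` object.
#' @export
nTrials <- function(x) dim(x@data)[1L]

#' @describeIn EpochedData number of channels
#' @export
nChannels <- function(x) dim(x@data)[2L]

#' @describeIn EpochedData number of time samples
#' @export
nTimes <- function(x) dim(x@data)[3L]

#' @describeIn EpochedData the trials x channels x times array
#' @export
epochData <- function(x) x@data

#' @describeIn EpochedData per-trial condition labels
#' @export
epochLabels <- function(x) x@labels

#' @describeIn EpochedData the declared condition names
#' @export
conditionNames <- function(x) x@conditions

#' @describeIn EpochedData the time axis in ms
#' @export
epochTimes <- function(x) x@times

#' @describeIn EpochedData sampling rate in Hz
#' @export
samplingRate <- function(x) x@sfreq

#' @describeIn EpochedData ordered channel names
#' @export
channelNames <- function(x) x@channels

#' @describeIn EpochedData per-trial subject identifiers
#' @export
subjectIds <- function(x) x@subjectIds

#' Crop epochs to a half-open latency interval
#'
#' Keeps samples with `tStart <= t < tEnd`.  The half-open convention is
#' what makes a 0--1500 ms crop at 512 Hz yield exactly 768 samples.
#'
#' @param x an [EpochedData-class] object.
#' @param tStart,tEnd interval bounds in ms, `tStart < tEnd`.
#' @return a new `EpochedData` restricted to the interval.
#' @export
cropEpochs <- function(x, tStart, tEnd) {
  stopifnot(is(x, "EpochedData"))
  .assertScalarNumber(tStart, "tStart")
  .assertScalarNumber(tEnd, "tEnd")
  if (tStart >= tEnd)
    stop("'tStart' must be strictly less than 'tEnd'")
  keep <- which(x@times >= tStart & x@times < tEnd)
  if (!length(keep))
    stop(sprintf("crop [%g, %g) contains no samples (axis spans %g..%g ms)",
                 tStart, tEnd, x@times[1L], x@times[length(x@times)]))
  new("EpochedData", data = x@data[, , keep, drop = FALSE],
      labels = x@labels, conditions = x@conditions,
      times = x@times[keep], sfreq = x@sfreq, channels = x@channels,
      subjectIds = x@subjectIds)
}

#' Convert between sample offsets and latencies
#'
#' `indexToTime` maps a 0-based sample offset on a uniform grid to its
#' latency `t0 + i * 1000/sfreq`; `timeToIndex` maps a latency to the
#' nearest 0-based sample offset.  Offsets are 0-based so that offset `i`
#' is exactly `i` sample periods after the grid origin (e.g. offset 80 at
#' 512 Hz is 156.25 ms).
#'
#' @param i integer sample offset(s), 0-based.
#' @param sfreq sampling rate in Hz.
#' @param t0 latency of offset 0 in ms.
#' @param nTimes optional grid length; when given, offsets (latencies)
#'   outside `[0, nTimes)` (the grid span) are an error.
#' @return latencies in ms (`indexToTime`) or integer 0-based offsets
#'   (`timeToIndex`).
#' @examples
#' indexToTime(80, 512)          # 156.25
#' timeToIndex(156.25, 512)      # 80
#' @export
indexToTime <- function(i, sfreq, t0 = 0, nTimes = NULL) {
  .assertScalarNumber(sfreq, "sfreq", positive = TRUE)
  if (any(i < 0) || any(i != floor(i)))
    stop("sample offsets must be nonnegative integers")
  if (!is.null(nTimes) && any(i >= nTimes))
    stop(sprintf("sample offset out of range [0, %d)", nTimes))
  t0 + i * 1000 / sfreq
}

#' @rdname indexToTime
#' @param t latency (or latencies) in ms.
#' @export
timeToIndex <- function(t, sfreq, t0 = 0, nTimes = NULL) {
  .assertScalarNumber(sfreq, "sfreq", positive = TRUE)
  i <- round((t - t0) * sfreq / 1000)
  if (!is.null(nTimes) && (any(i < 0) || any(i >= nTimes)))
    stop(sprintf("latency maps outside the grid [0, %d)", nTimes))
  as.integer(i)
}

## ---------------------------------------------------------------------
## Epochs container I/O: a directory holding a raw little-endian float32
## array (time fastest, then channel, then trial) plus a JSON sidecar with
## all metadata.  Language-neutral and diff-able; note float64 inputs are
## stored at float32 precision.

#' Write / read the epochs container
#'
#' The container is a directory with `data.bin` (raw little-endian 32-bit
#' floats, C order for shape `[trials, channels, times]`) and `meta.json`
#' (shape, sampling rate, time origin, labels, conditions, subjects,
#' channels).
#'
#' @param x an [EpochedData-class] object.
#' @param path directory to create (write) or read.
#' @return `writeEpochs` returns `path` invisibly; `readEpochs` returns a
#'   validated [EpochedData-class] object.
#' @export
writeEpochs <- function(x, path) {
  stopifnot(is(x, "EpochedData"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    shape = dim(x@data), sfreq = x@sfreq, t0 = x@times[1L],
    labels = x@labels, conditions = x@conditions,
    subjects = x@subjectIds, channels = x@channels,
    dtype = "float32-le", order = "trial-major (time fastest)")
  .writeJSON(meta, file.path(path, "meta.json"))
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(x@data, c(3L, 2L, 1L))), con,
           size = 4L, endian = "little")
  invisible(path)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
  metaPath <- file.path(path, "meta.json")
  binPath <- file.path(path, "data.bin")
  if (!file.exists(metaPath) || !file.exists(binPath))
    stop(sprintf("'%s' is not an epochs container (missing meta.json or data.bin)",
                 path))
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  for (field in c("shape", "sfreq", "t0", "labels", "subjects", "channels"))
    if (is.null(meta[[field]]))
      stop(sprintf("epochs container metadata is missing field '%s'", field))
  shape <- as.integer(meta$shape)
  if (length(shape) != 3L)
    stop("epochs container field 'shape' must have 3 entries")
  n <- prod(shape)
  con <- file(binPath, "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "numeric", n = n + 1L, size = 4L,
                 endian = "little")
  if (length(raw) != n)
    stop(sprintf("epochs container field 'shape' (%s) disagrees with data.bin (%d values)",
                 paste(shape, collapse = "x"), length(raw)))
  data <- aperm(array(raw, rev(shape)), c(3L, 2L, 1L))
  EpochedData(data, labels = as.character(meta$labels),
              sfreq = meta$sfreq, t0 = meta$t0,
              channels = as.character(meta$channels),
              subjectIds = as.character(meta$subjects),
              conditions = if (!is.null(meta$conditions))
                as.character(meta$conditions) else NULL)
}
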