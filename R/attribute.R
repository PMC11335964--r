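## Expected-gradients SHAP attribution.
##
## For trial x and class c the attribution is the average over draws
## (b ~ background, alpha ~ U(0,1)) of  grad f_c(b + alpha (x - b)) * (x - b),
## a Monte-Carlo estimator of integrated gradients with a background
## distribution; it satisfies the SHAP completeness (additivity) property
## sum_i phi_i ~= f_c(x) - E_b f_c(b) as the number of path samples grows.

#' Low-level model interface used by the attribution engine
#'
#' `modelForward` runs the model on a `[channels, times, batch]` array and
#' returns the per-class outputs plus whatever cache the gradient needs;
#' `modelInputGradient` returns the gradient of one class output with
#' respect to the inputs.  Methods exist for `cnnModel` and for the
#' [linearModel()] reference; any differentiable model can plug in by
#' providing both methods.
#'
#' @param model the model object.
#' @param X numeric array `[n_channels, n_times, batch]`.
#' @param fw the value returned by `modelForward`.
#' @param classIndex integer class index.
#' @return `modelForward`: list with `out` (`[n_classes, batch]`) and any
#'   cache; `modelInputGradient`: array `[n_channels, n_times, batch]`.
#' @export
modelForward <- function(model, X) UseMethod("modelForward")

#' @rdname modelForward
#' @export
modelInputGradient <- function(model, fw, X, classIndex)
  UseMethod("modelInputGradient")

#' @rdname modelForward
#' @export
modelForward.cnnModel <- function(model, X) {
  .nnForward(model$layers, X, training = FALSE, keepCache = TRUE)
}

#' @rdname modelForward
#' @export
modelInputGradient.cnnModel <- function(model, fw, X, classIndex) {
  P <- fw$out
  dTop <- matrix(0, nrow(P), ncol(P))
  dTop[classIndex, ] <- 1
  bw <- .nnBackward(model$layers, fw$caches, dTop, training = FALSE,
                    paramGrads = FALSE, inputGrad = TRUE)
  bw$dInput
}

#' A linear reference model for attribution validation
#'
#' Scores are `f_c(x) = w_c . x + b_c` (no softmax), for which expected
#' gradients has the closed form `w_i (x_i - mean_b b_i)` -- the primary
#' correctness oracle for the attribution engine.
#'
#' @param W numeric matrix `[n_classes, n_channels * n_times]` (row-major
#'   over channels within each time sample, i.e. channel index fastest).
#' @param b per-class intercepts.
#' @param classes optional class names.
#' @return an object of class `linearModel`.
#' @export
linearModel <- function(W, b = rep(0, nrow(W)), classes = NULL) {
  stopifnot(is.matrix(W), length(b) == nrow(W))
  structure(list(W = W, b = b,
                 classes = classes %||% sprintf("class%d", seq_len(nrow(W))),
                 spec = list(nClasses = nrow(W), kernelSize = 1L)),
            class = "linearModel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname modelForward
#' @export
modelForward.linearModel <- function(model, X) {
  d <- dim(X)
  list(out = model$W %*% matrix(X, d[1L] * d[2L], d[3L]) + model$b)
}

#' @rdname modelForward
#' @export
modelInputGradient.linearModel <- function(model, fw, X, classIndex) {
  d <- dim(X)
  array(rep(model$W[classIndex, ], d[3L]), d)
}

#' Draw a background set from training epochs
#'
#' The background distribution the expected-gradients integral averages
#' over; by default 100 trials sampled uniformly from the training set.
#'
#' @param epochs an [EpochedData-class] object or `[n, channels, times]`
#'   array.
#' @param size number of background samples.
#' @param seed sampling seed (recorded in provenance).
#' @return an object of class `BackgroundSet`.
#' @export
backgroundSet <- function(epochs, size = 100L, seed = 1L) {
  arr <- if (is(epochs, "EpochedData")) epochData(epochs) else epochs
  stopifnot(is.array(arr), length(dim(arr)) == 3L, size >= 1)
  set.seed(deriveSeed(seed, "background"))
  idx <- sample.int(dim(arr)[1L], min(size, dim(arr)[1L]))
  structure(list(samples = arr[idx, , , drop = FALSE], seed = seed),
            class = "BackgroundSet")
}

#' Expected-gradients SHAP attributions
#'
#' @param model a `cnnModel`, [linearModel()], or any object with
#'   [modelForward()]/[modelInputGradient()] methods.
#' @param inputs trials to explain: [EpochedData-class] or array
#'   `[n, channels, times]`.
#' @param background a [backgroundSet()].
#' @param nPathSamples Monte-Carlo path samples per trial (>= 1); 200 is
#'   a practical pipeline default, 2000 gives oracle-grade accuracy.
#' @param seed seed for the background/interpolation draws.
#' @param classes class names for the output axis (defaults to the
#'   model's classes).
#' @param channels,times geometry metadata for the result (filled from
#'   `inputs` when it is an `EpochedData`).
#' @return an [AttributionTensor-class].
#' @export
expectedGradients <- function(model, inputs, background,
                              nPathSamples = 200L, seed = 1L,
                              classes = NULL, channels = NULL,
                              times = NULL) {
  stopifnot(inherits(background, "BackgroundSet"))
  if (nPathSamples < 1) stop("'nPathSamples' must be >= 1")
  trialLabels <- NA_character_
  if (is(inputs, "EpochedData")) {
    channels <- channels %||% channelNames(inputs)
    times <- times %||% epochTimes(inputs)
    trialLabels <- epochLabels(inputs)
    inputs <- epochData(inputs)
  }
  stopifnot(is.array(inputs), length(dim(inputs)) == 3L)
  n <- dim(inputs)[1L]; C <- dim(inputs)[2L]; T <- dim(inputs)[3L]
  bg <- background$samples
  if (!all(dim(bg)[2:3] == c(C, T)))
    stop("background geometry does not match the inputs")
  nBg <- dim(bg)[1L]
  classes <- classes %||% model$classes %||%
    sprintf("class%d", seq_len(model$spec$nClasses))
  nCls <- length(classes)
  if (length(trialLabels) == 1L && is.na(trialLabels[1L]))
    trialLabels <- rep(NA_character_, n)

  set.seed(deriveSeed(seed, "expected-gradients"))
  # variance-reduced path sampling: every background sample is drawn a
  # near-equal number of times, and each background's interpolation
  # positions form a jittered stratification of (0,1) -- an unbiased
  # draw of the (b, alpha) integral with far smaller quadrature error
  # than independent uniforms.
  bgIdx <- matrix(0L, n, nPathSamples)
  alphas <- matrix(0, n, nPathSamples)
  for (i in seq_len(n)) {
    ord <- rep_len(seq_len(nBg), nPathSamples)
    al <- numeric(nPathSamples)
    for (b in seq_len(min(nBg, nPathSamples))) {
      j <- which(ord == b)
      al[j] <- (seq_along(j) - runif(length(j))) / length(j)
    }
    bgIdx[i, ] <- ord
    alphas[i, ] <- al
  }

  chunk <- .inferChunk(C, model$spec$kernelSize %||% 1L, T)
  values <- array(0, c(n, nCls, C, T))
  for (i in seq_len(n)) {
    xi <- array(inputs[i, , ], c(C, T))
    acc <- vector("list", nCls)
    for (ci in seq_len(nCls)) acc[[ci]] <- numeric(C * T)
    s <- 1L
    while (s <= nPathSamples) {
      e <- min(nPathSamples, s + chunk - 1L)
      draws <- s:e
      B <- length(draws)
      Bg <- aperm(bg[bgIdx[i, draws], , , drop = FALSE], c(2L, 3L, 1L))
      D <- array(xi, c(C, T, B)) - Bg
      Z <- Bg + sweep(D, 3L, alphas[i, draws], "*")
      fw <- modelForward(model, Z)
      for (ci in seq_len(nCls)) {
        G <- modelInputGradient(model, fw, Z, ci)
        acc[[ci]] <- acc[[ci]] + rowSums(matrix(G * D, C * T, B))
      }
      s <- e + 1L
    }
    for (ci in seq_len(nCls))
      values[i, ci, , ] <- matrix(acc[[ci]] / nPathSamples, C, T)
  }
  new("AttributionTensor", values = values, classes = classes,
      channels = channels %||% sprintf("ch%03d", seq_len(C)),
      times = times %||% as.numeric(seq_len(T) - 1L),
      trialLabels = trialLabels,
      provenance = list(nBackground = nBg, nPathSamples = nPathSamples,
                        seed = seed, backgroundSeed = background$seed))
}

#' Aggregate attributions into a channels x times importance matrix
#'
#' `values[ch, t]` is the mean over trials of the class-summed absolute
#' attribution -- the matrix behind the importance contour plot.  The
#' mean (rather than sum) over trials keeps scales comparable across
#' dataset sizes.
#'
#' @param attr an [AttributionTensor-class].
#' @return an [ImportanceMatrix-class].
#' @export
aggregateImportance <- function(attr) {
  stopifnot(is(attr, "AttributionTensor"))
  a <- abs(attr@values)
  if (!length(a)) stop("empty attribution tensor")
  perTrial <- colMeans(a, dims = 1L)        # [classes, channels, times]
  mat <- colSums(perTrial, dims = 1L)       # [channels, times]
  dimnames(mat) <- NULL
  new("ImportanceMatrix", values = mat, channels = attr@channels,
      times = attr@times,
      aggregation = "mean over trials of sum over classes of |attribution|")
}

#' Per-class importance over time
#'
#' For one class, sums the absolute attribution over all electrodes at
#' each time point and averages over the scoped trials (all trials, or
#' only the trials of that class).
#'
#' @param attr an [AttributionTensor-class].
#' @param class one of the tensor's class names.
#' @param trialScope `"all_trials"` (default) or `"class_trials"`.
#' @return an [ImportanceCurve-class].
#' @export
classImportanceCurve <- function(attr, class,
                                 trialScope = c("all_trials",
                                                "class_trials")) {
  stopifnot(is(attr, "AttributionTensor"))
  trialScope <- match.arg(trialScope)
  ci <- match(class, attr@classes)
  if (is.na(ci))
    stop(sprintf("unknown class '%s' (have: %s)", class,
                 paste(attr@classes, collapse = ", ")))
  idx <- seq_len(dim(attr@values)[1L])
  if (trialScope == "class_trials") {
    if (all(is.na(attr@trialLabels)))
      stop("trialScope='class_trials' requires trial labels")
    idx <- which(attr@trialLabels == class)
    if (!length(idx))
      stop(sprintf("no trials with label '%s'", class))
  }
  d <- dim(attr@values)
  a <- abs(array(attr@values[idx, ci, , ], c(length(idx), d[3L], d[4L])))
  curve <- colSums(colMeans(a, dims = 1L), dims = 1L)  # sum over channels
  new("ImportanceCurve", className = class, values = as.numeric(curve),
      times = attr@times, scope = trialScope)
}

#' Write / read an attribution tensor container
#'
#' Same on-disk scheme as the epochs container (raw little-endian
#' float32 block plus a JSON sidecar), with a classes axis: C order for
#' shape `[trials, classes, channels, times]` (time fastest).
#'
#' @param attr an [AttributionTensor-class].
#' @param path directory to create (write) or read.
#' @return `writeAttributionTensor` returns `path` invisibly;
#'   `readAttributionTensor` the tensor.
#' @export
writeAttributionTensor <- function(attr, path) {
  stopifnot(is(attr, "AttributionTensor"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(shape = dim(attr@values), classes = attr@classes,
               channels = attr@channels, times = attr@times,
               trialLabels = attr@trialLabels,
               provenance = attr@provenance,
               dtype = "float32-le", order = "trial-major (time fastest)")
  .writeJSON(meta, file.path(path, "meta.json"))
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(attr@values, 4:1)), con, size = 4L,
           endian = "little")
  invisible(path)
}

#' @rdname writeAttributionTensor
#' @export
readAttributionTensor <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "numeric", n = prod(shape) + 1L, size = 4L,
                 endian = "little")
  if (length(raw) != prod(shape))
    stop("attribution container shape disagrees with data.bin")
  new("AttributionTensor", values = aperm(array(raw, rev(shape)), 4:1),
      classes = as.character(meta$classes),
      channels = as.character(meta$channels),
      times = as.numeric(meta$times),
      trialLabels = as.character(meta$trialLabels),
      provenance = as.list(meta$provenance))
}
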