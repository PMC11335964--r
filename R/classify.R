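#' Specify the convolutional classifier architecture
#'
#' Defaults mirror the reference architecture: four 1-D convolutional
#' layers with ascending filter counts 16..128, kernel size 50 samples,
#' GELU activation and L2 weight regularization, each followed by max
#' pooling; batch normalization at the start and end of the feature
#' extractor; three hidden dense layers (descending 128..32, ReLU) and a
#' softmax output.  The first convolutional layer uses a Glorot-normal
#' initializer, all other layers Glorot-uniform.  Pool size, L2 strength,
#' learning rate and batch-norm momentum are not fixed by the reference
#' description and are exposed here as explicit fields.
#'
#' @param convFilters integer vector of ascending conv filter counts.
#' @param kernelSize conv kernel length in samples.
#' @param poolSize max-pool width per conv block.
#' @param denseUnits descending hidden dense widths.
#' @param nClasses number of output classes.
#' @param l2 L2 coefficient applied to conv kernels.
#' @param learningRate Adam learning rate.
#' @param bnMomentum running-moment momentum of the batch-norm layers.
#' @param bnEps batch-norm variance floor.
#' @return a `ModelSpec` list.
#' @export
modelSpec <- function(convFilters = c(16L, 32L, 64L, 128L),
                      kernelSize = 50L, poolSize = 2L,
                      denseUnits = c(128L, 64L, 32L), nClasses = 3L,
                      l2 = 1e-4, learningRate = 1e-3,
                      bnMomentum = 0.9, bnEps = 1e-3) {
  stopifnot(length(convFilters) >= 1, all(diff(convFilters) >= 0),
            kernelSize >= 1, poolSize >= 1, nClasses >= 2,
            all(diff(denseUnits) <= 0), l2 >= 0, learningRate > 0)
  structure(list(convFilters = as.integer(convFilters),
                 kernelSize = as.integer(kernelSize),
                 poolSize = as.integer(poolSize),
                 denseUnits = as.integer(denseUnits),
                 nClasses = as.integer(nClasses), l2 = l2,
                 learningRate = learningRate, bnMomentum = bnMomentum,
                 bnEps = bnEps),
            class = "ModelSpec")
}

#' A reduced architecture matched to the desk-scale preset
#'
#' Filter counts and kernel scale down proportionally (kernel
#' `50 * 256/768 = 17` samples on 256-sample epochs) so the full protocol
#' runs on one CPU in minutes.
#'
#' @param ... overrides passed to [modelSpec()].
#' @return a `ModelSpec`.
#' @export
deskModelSpec <- function(...) {
  args <- list(convFilters = c(8L, 16L, 32L, 64L), kernelSize = 17L,
               denseUnits = c(64L, 32L, 16L))
  args[names(list(...))] <- list(...)
  do.call(modelSpec, args)
}

#' Specify the training and validation protocol
#'
#' Defaults mirror the reference protocol: batch size 64, at most 200
#' epochs with early stopping after 50 epochs without improvement in
#' validation loss, five-fold cross-validation, and a hold-out test set
#' mixing trials of entirely held-out subjects with a stratified sample
#' of the remaining subjects' trials.
#'
#' @param batchSize minibatch size.
#' @param maxEpochs maximum training epochs per fold.
#' @param earlyStopPatience epochs without validation-loss improvement
#'   before stopping.
#' @param nFolds number of cross-validation folds (>= 2).
#' @param testFraction fraction of all trials forming the test set.
#' @param holdoutSubjects number of subjects placed entirely in the test
#'   set.
#' @param seed default seed for splitting/fold assignment/training.
#' @return a `TrainingConfig` list.
#' @export
trainingConfig <- function(batchSize = 64L, maxEpochs = 200L,
                           earlyStopPatience = 50L, nFolds = 5L,
                           testFraction = 0.2, holdoutSubjects = 2L,
                           seed = 1L) {
  stopifnot(nFolds >= 2, testFraction > 0, testFraction < 1,
            batchSize >= 1, maxEpochs >= 1, earlyStopPatience >= 1,
            holdoutSubjects >= 0)
  structure(list(batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 earlyStopPatience = as.integer(earlyStopPatience),
                 nFolds = as.integer(nFolds), testFraction = testFraction,
                 holdoutSubjects = as.integer(holdoutSubjects),
                 seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Build an untrained classifier
#'
#' @param spec a [modelSpec()].
#' @param nChannels,nTimes input geometry.
#' @param seed seed for the weight initialization.
#' @return an object of class `cnnModel`.
#' @export
buildModel <- function(spec, nChannels, nTimes, seed = 1L) {
  stopifnot(inherits(spec, "ModelSpec"))
  if (nTimes <= spec$kernelSize)
    stop(sprintf("nTimes (%d) must exceed the kernel size (%d)",
                 nTimes, spec$kernelSize))
  set.seed(seed)
  layers <- list()
  addBN <- function(C) {
    layers[[length(layers) + 1L]] <<- list(
      type = "bn", gamma = rep(1, C), beta = rep(0, C),
      runMean = rep(0, C), runVar = rep(1, C),
      momentum = spec$bnMomentum, eps = spec$bnEps)
  }
  addBN(nChannels)
  C <- nChannels; T <- nTimes; K <- spec$kernelSize
  padL <- (K - 1L) %/% 2L; padR <- K - 1L - padL
  for (li in seq_along(spec$convFilters)) {
    F <- spec$convFilters[li]
    fanIn <- C * K; fanOut <- F * K
    W <- if (li == 1L) .glorotNormal(F, C * K, fanIn, fanOut)
         else .glorotUniform(F, C * K, fanIn, fanOut)
    layers[[length(layers) + 1L]] <- list(type = "conv", W = W,
                                          b = rep(0, F), K = K,
                                          padL = padL, padR = padR)
    layers[[length(layers) + 1L]] <- list(type = "gelu")
    layers[[length(layers) + 1L]] <- list(type = "pool",
                                          size = spec$poolSize)
    C <- F
    T <- T %/% spec$poolSize
    if (T < 1L) stop("pooling collapsed the time axis; reduce poolSize")
  }
  addBN(C)
  layers[[length(layers) + 1L]] <- list(type = "flatten")
  nIn <- C * T
  for (U in spec$denseUnits) {
    layers[[length(layers) + 1L]] <- list(
      type = "dense", W = .glorotUniform(U, nIn, nIn, U),
      b = rep(0, U), activation = "relu")
    nIn <- U
  }
  layers[[length(layers) + 1L]] <- list(
    type = "dense",
    W = .glorotUniform(spec$nClasses, nIn, nIn, spec$nClasses),
    b = rep(0, spec$nClasses), activation = "softmax")
  structure(list(spec = spec, nChannels = nChannels, nTimes = nTimes,
                 layers = layers, classes = NULL),
            class = "cnnModel")
}

#' @export
print.cnnModel <- function(x, ...) {
  nPar <- sum(vapply(x$layers, function(l)
    sum(vapply(.layerParamNames(l), function(p) length(l[[p]]), 0)), 0))
  cat(sprintf("cnnModel: %d channels x %d samples -> %d classes, %d parameters\n",
              x$nChannels, x$nTimes, x$spec$nClasses, nPar))
  invisible(x)
}

## EpochedData or [n, C, T] array -> [C, T, n] array.
.asBatchArray <- function(x) {
  if (is(x, "EpochedData")) x <- epochData(x)
  stopifnot(is.array(x), length(dim(x)) == 3L)
  aperm(x, c(2L, 3L, 1L))
}

#' Predict class probabilities
#'
#' @param model a trained (or untrained) model.
#' @param newdata an [EpochedData-class] object or a numeric array
#'   `[n_trials, n_channels, n_times]`.
#' @param ... unused.
#' @return numeric matrix `[n_trials, n_classes]`; rows sum to 1.
#' @export
predictProba <- function(model, newdata, ...) UseMethod("predictProba")

#' @rdname predictProba
#' @export
predictProba.cnnModel <- function(model, newdata, ...) {
  X <- .asBatchArray(newdata)
  P <- t(.nnPredict(model, X))
  if (!is.null(model$classes)) colnames(P) <- model$classes
  P
}

.subsetEpochs <- function(x, idx) {
  new("EpochedData", data = x@data[idx, , , drop = FALSE],
      labels = x@labels[idx], conditions = x@conditions,
      times = x@times, sfreq = x@sfreq, channels = x@channels,
      subjectIds = x@subjectIds[idx])
}

#' Split epochs into a training set and a mixed hold-out test set
#'
#' The test set is the union of (i) every trial of `holdoutSubjects`
#' randomly chosen subjects (participants never encountered during
#' training) and (ii) a class-stratified random sample of the remaining
#' subjects' trials, topping the test set up to `testFraction` of all
#' trials.  Deterministic given the seed.
#'
#' @param epochs an [EpochedData-class] object.
#' @param cfg a [trainingConfig()].
#' @param seed seed (defaults to `cfg$seed`).
#' @return list with elements `train`, `test` (both `EpochedData`),
#'   `testIdx` and `heldOutSubjects`.
#' @export
splitData <- function(epochs, cfg, seed = cfg$seed) {
  stopifnot(is(epochs, "EpochedData"), inherits(cfg, "TrainingConfig"))
  subjects <- unique(subjectIds(epochs))
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  if (cfg$holdoutSubjects >= length(subjects))
    stop(sprintf("holdoutSubjects (%d) must be < number of subjects (%d)",
                 cfg$holdoutSubjects, length(subjects)))
  set.seed(deriveSeed(seed, "split"))
  held <- if (cfg$holdoutSubjects > 0)
    sample(subjects, cfg$holdoutSubjects) else character(0)
  holdIdx <- which(subjectIds(epochs) %in% held)
  target <- round(cfg$testFraction * nTrials(epochs))
  extra <- max(0L, target - length(holdIdx))
  testIdx <- holdIdx
  if (extra > 0L) {
    remaining <- setdiff(seq_len(nTrials(epochs)), holdIdx)
    byClass <- split(remaining, epochLabels(epochs)[remaining])
    k <- length(byClass)
    want <- rep(extra %/% k, k) +
      (seq_len(k) <= extra %% k)  # distribute the remainder
    picked <- unlist(lapply(seq_len(k), function(i)
      sample(byClass[[i]], min(want[i], length(byClass[[i]])))),
      use.names = FALSE)
    testIdx <- sort(c(holdIdx, picked))
  }
  trainIdx <- setdiff(seq_len(nTrials(epochs)), testIdx)
  list(train = .subsetEpochs(epochs, trainIdx),
       test = .subsetEpochs(epochs, testIdx),
       testIdx = testIdx, heldOutSubjects = held)
}

#' Train with stratified k-fold cross-validation
#'
#' Shuffles trials into `nFolds` class-stratified folds; each fold trains
#' a fresh model on the remaining folds and keeps the weights of the
#' epoch with the best validation accuracy, while early stopping monitors
#' the validation loss.
#'
#' @param spec a [modelSpec()].
#' @param epochs the training [EpochedData-class].
#' @param cfg a [trainingConfig()].
#' @param seed seed (defaults to `cfg$seed`).
#' @return an object of class `sherpaCVFit`: list with `models` (fold-best
#'   model states), `histories`, `classes`, `foldValAccuracy`.
#' @export
trainCrossval <- function(spec, epochs, cfg, seed = cfg$seed) {
  stopifnot(is(epochs, "EpochedData"))
  if (nTrials(epochs) == 0L) stop("empty training set")
  classes <- conditionNames(epochs)
  y <- as.integer(factor(epochLabels(epochs), levels = classes))
  X <- .asBatchArray(epochs)
  set.seed(deriveSeed(seed, "cv"))
  fold <- integer(length(y))
  for (cls in seq_along(classes)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(cfg$nFolds), length(idx))
  }
  models <- vector("list", cfg$nFolds)
  histories <- vector("list", cfg$nFolds)
  for (f in seq_len(cfg$nFolds)) {
    trIdx <- which(fold != f); vaIdx <- which(fold == f)
    model <- buildModel(spec, dim(X)[1L], dim(X)[2L],
                        seed = deriveSeed(seed, paste0("init", f)))
    set.seed(deriveSeed(seed, paste0("fit", f)))
    fit <- .fitModel(model, X[, , trIdx, drop = FALSE], y[trIdx],
                     X[, , vaIdx, drop = FALSE], y[vaIdx], cfg)
    fit$model$classes <- classes
    models[[f]] <- fit$model
    histories[[f]] <- fit$history
  }
  structure(list(models = models, histories = histories,
                 classes = classes,
                 foldValAccuracy = vapply(histories,
                                          function(h) max(h$valAcc), 0)),
            class = "sherpaCVFit")
}

#' @export
print.sherpaCVFit <- function(x, ...) {
  cat(sprintf("sherpaCVFit: %d folds, val accuracy %s (mean %.3f)\n",
              length(x$models),
              paste(sprintf("%.3f", x$foldValAccuracy), collapse = "/"),
              mean(x$foldValAccuracy)))
  invisible(x)
}

#' Evaluate fold models on a hold-out test set
#'
#' Computes each model state's test accuracy, reports their mean and SD,
#' and a row-normalized confusion matrix from the designated state (the
#' last fold, by convention).
#'
#' @param fit a `sherpaCVFit` or a list of model states (anything with a
#'   [predictProba()] method).
#' @param test the test [EpochedData-class].
#' @return an `EvaluationReport` list: `perFoldValAccuracy`,
#'   `testAccuracies`, `testAccuracyMean`, `testAccuracySD`, `confusion`.
#' @export
evaluateModels <- function(fit, test) {
  stopifnot(is(test, "EpochedData"))
  if (inherits(fit, "sherpaCVFit")) {
    states <- fit$models
    perFoldVal <- fit$foldValAccuracy
    classes <- fit$classes
  } else {
    states <- fit
    perFoldVal <- NULL
    classes <- states[[1L]]$classes
  }
  if (length(states) < 1L) stop("need at least one model state")
  if (is.null(classes)) classes <- conditionNames(test)
  if (!setequal(classes, conditionNames(test)))
    stop(sprintf("label set mismatch: model classes {%s} vs test conditions {%s}",
                 paste(classes, collapse = ","),
                 paste(conditionNames(test), collapse = ",")))
  yTrue <- factor(epochLabels(test), levels = classes)
  acc <- vapply(states, function(st) {
    P <- predictProba(st, test)
    mean(classes[max.col(P, ties.method = "first")] == as.character(yTrue))
  }, 0)
  Plast <- predictProba(states[[length(states)]], test)
  yPred <- factor(classes[max.col(Plast, ties.method = "first")],
                  levels = classes)
  confusion <- table(actual = yTrue, predicted = yPred)
  confusion <- sweep(unclass(confusion), 1L,
                     pmax(rowSums(confusion), 1L), "/")
  structure(list(perFoldValAccuracy = perFoldVal,
                 testAccuracies = acc,
                 testAccuracyMean = mean(acc),
                 testAccuracySD = if (length(acc) > 1L) sd(acc) else 0,
                 confusion = confusion),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: test accuracy %.3f (SD %.3f) over %d states\n",
              x$testAccuracyMean, x$testAccuracySD, length(x$testAccuracies)))
  print(round(x$confusion, 3))
  invisible(x)
}

#' Save / load a trained model state
#'
#' The state is written in R's native serialization format with a JSON
#' sidecar (`<path>.json`) describing the architecture.
#'
#' @param model a `cnnModel`.
#' @param path file path for the state.
#' @return `writeModelState` returns `path` invisibly; `readModelState`
#'   the model.
#' @export
writeModelState <- function(model, path) {
  stopifnot(inherits(model, "cnnModel"))
  saveRDS(model, path)
  .writeJSON(model$spec[names(model$spec)], paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeModelState
#' @export
readModelState <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cnnModel"))
  model
}
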