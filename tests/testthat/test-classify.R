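test_that("an untrained model emits valid softmax rows, deterministically", {
  spec <- modelSpec(convFilters = c(4L, 8L), kernelSize = 7L,
                    denseUnits = c(16L, 8L), nClasses = 3L)
  m <- buildModel(spec, 6, 32, seed = 3)
  set.seed(1)
  X <- array(rnorm(5 * 6 * 32), c(5, 6, 32))
  P <- predictProba(m, X)
  expect_equal(dim(P), c(5L, 3L))
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
  m2 <- buildModel(spec, 6, 32, seed = 3)
  expect_identical(predictProba(m2, X), P)
  m3 <- buildModel(spec, 6, 32, seed = 4)
  expect_false(identical(predictProba(m3, X), P))
  expect_error(buildModel(spec, 6, 5), "kernel")
})

test_that("the test split mixes held-out subjects with stratified trials", {
  cond <- c("a", "b", "c")
  lay <- sphericalLayout(3)
  cfg <- simulationConfig(cond, nSubjects = 10, trialsPerCondition = 20,
                          layout = lay, sfreq = 256, tStart = 0,
                          tEnd = 62.5,
                          components = list(componentSpec(
                            30, 10, 1, stats::setNames(c(1, 0, 0), lay$name),
                            stats::setNames(c(1, 1, 1), cond))),
                          noise = noiseSpec(whiteSD = 1), seed = 2)
  ep <- simulateEpochs(cfg)  # 600 trials
  tc <- trainingConfig(testFraction = 0.3, holdoutSubjects = 2L, seed = 9)
  sp <- splitData(ep, tc)
  expect_length(sp$heldOutSubjects, 2L)
  # every trial of the held-out subjects is in the test set
  expect_true(all(subjectIds(sp$train) %in%
                    setdiff(unique(subjectIds(ep)), sp$heldOutSubjects)))
  expect_true(all(which(subjectIds(ep) %in% sp$heldOutSubjects) %in%
                    sp$testIdx))
  # partition: no overlap, sizes add up
  expect_equal(nTrials(sp$train) + nTrials(sp$test), nTrials(ep))
  expect_equal(nTrials(sp$test), round(0.3 * nTrials(ep)))
  # class balance within 2 percentage points of 1/3
  prop <- table(epochLabels(sp$test)) / nTrials(sp$test)
  expect_true(all(abs(prop - 1 / 3) < 0.02))
  # determinism
  sp2 <- splitData(ep, tc)
  expect_identical(sp2$testIdx, sp$testIdx)
  expect_error(splitData(ep, trainingConfig(holdoutSubjects = 10L)),
               "holdoutSubjects")
})

test_that("cross-validation learns separable classes and respects the protocol", {
  ep <- simulateEpochs(smallSepConfig(), seed = 2)
  spec <- modelSpec(convFilters = c(4L, 8L), kernelSize = 7L,
                    denseUnits = c(16L, 8L), nClasses = 3L)
  tc <- trainingConfig(maxEpochs = 6L, earlyStopPatience = 3L,
                       nFolds = 3L, holdoutSubjects = 1L, seed = 2)
  sp <- splitData(ep, tc)
  fit <- trainCrossval(spec, sp$train, tc)
  expect_length(fit$models, 3L)
  expect_gt(mean(fit$foldValAccuracy), 0.5)  # separable >> chance of 1/3
  for (h in fit$histories) {
    expect_lte(nrow(h), tc$maxEpochs)
    # early stopping: the run never continues more than `patience`
    # epochs past the best validation-loss epoch
    expect_lte(nrow(h) - which.min(h$valLoss), tc$earlyStopPatience)
  }
  ev <- evaluateModels(fit, sp$test)
  expect_gt(ev$testAccuracyMean, 0.5)
  expect_equal(rowSums(ev$confusion), rep(1, 3), ignore_attr = TRUE)
})

test_that("uniformly shuffled labels bring accuracy back to chance", {
  ep <- simulateEpochs(smallSepConfig(), seed = 6)
  set.seed(11)
  shuffled <- EpochedData(epochData(ep),
                          labels = sample(epochLabels(ep)),
                          sfreq = samplingRate(ep),
                          t0 = epochTimes(ep)[1],
                          channels = channelNames(ep),
                          subjectIds = subjectIds(ep),
                          conditions = conditionNames(ep))
  spec <- modelSpec(convFilters = c(4L, 8L), kernelSize = 7L,
                    denseUnits = c(16L, 8L), nClasses = 3L)
  tc <- trainingConfig(maxEpochs = 3L, earlyStopPatience = 3L,
                       nFolds = 2L, holdoutSubjects = 1L, seed = 3)
  sp <- splitData(shuffled, tc)
  fit <- trainCrossval(spec, sp$train, tc)
  ev <- evaluateModels(fit, sp$test)
  expect_gte(ev$testAccuracyMean, 0.25)
  expect_lte(ev$testAccuracyMean, 0.42)
})

test_that("evaluation handles oracle and degenerate predictors", {
  test <- tinyEpochs(nTrials = 9)
  classes <- conditionNames(test)
  oracle <- structure(list(classes = classes, truth = epochLabels(test)),
                      class = "oraclePredictor")
  .S3method("predictProba", "oraclePredictor",
            function(model, newdata, ...) {
              P <- matrix(0, length(model$truth), length(model$classes),
                          dimnames = list(NULL, model$classes))
              P[cbind(seq_along(model$truth),
                      match(model$truth, model$classes))] <- 1
              P
            })
  ev <- evaluateModels(list(oracle), test)
  expect_equal(ev$testAccuracyMean, 1.0)
  expect_equal(unclass(ev$confusion), diag(3), ignore_attr = TRUE)

  constant <- structure(list(classes = classes), class = "constPredictor")
  .S3method("predictProba", "constPredictor",
            function(model, newdata, ...) {
              n <- if (is(newdata, "EpochedData")) nTrials(newdata)
                   else dim(newdata)[1]
              P <- matrix(0, n, 3, dimnames = list(NULL, model$classes))
              P[, 1] <- 1
              P
            })
  ev2 <- evaluateModels(list(constant), test)
  expect_equal(ev2$testAccuracyMean, 1 / 3)
  expect_equal(unname(ev2$confusion[, 1]), rep(1, 3))
  expect_equal(rowSums(ev2$confusion), rep(1, 3), ignore_attr = TRUE)

  other <- tinyEpochs()
  other@labels <- rep("odd", nTrials(other))
  other@conditions <- "odd"
  expect_error(evaluateModels(list(oracle), other), "label set mismatch")
})

test_that("model states roundtrip through serialization bitwise", {
  spec <- modelSpec(convFilters = c(4L, 8L), kernelSize = 7L,
                    denseUnits = c(8L, 4L), nClasses = 3L)
  m <- buildModel(spec, 4, 16, seed = 5)
  m$classes <- c("face", "blurred", "scrambled")
  set.seed(8)
  X <- array(rnorm(3 * 4 * 16), c(3, 4, 16))
  path <- withr::local_tempfile(fileext = ".rds")
  writeModelState(m, path)
  m2 <- readModelState(path)
  expect_identical(predictProba(m2, X), predictProba(m, X))
  expect_true(file.exists(paste0(path, ".json")))
})
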