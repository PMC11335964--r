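test_that("expected gradients matches the linear-model closed form", {
  set.seed(1)
  C <- 3; T <- 10; n <- 4; nbg <- 30
  W <- matrix(rnorm(2 * C * T, 0, 0.05), 2)
  bg <- backgroundSet(array(rnorm(nbg * C * T), c(nbg, C, T)),
                      size = nbg, seed = 3)
  X <- array(rnorm(n * C * T), c(n, C, T))
  at <- expectedGradients(linearModel(W), X, bg, nPathSamples = 2000,
                          seed = 5)
  bmean <- apply(bg$samples, c(2, 3), mean)
  for (i in seq_len(n)) for (cl in 1:2) {
    oracle <- matrix(W[cl, ], C, T) * (array(X[i, , ], c(C, T)) - bmean)
    expect_lt(max(abs(at@values[i, cl, , ] - oracle)), 1e-3)
  }
})

test_that("a constant model attributes nothing", {
  bg <- backgroundSet(array(rnorm(5 * 2 * 6), c(5, 2, 6)), size = 5,
                      seed = 1)
  X <- array(rnorm(3 * 2 * 6), c(3, 2, 6))
  at <- expectedGradients(linearModel(matrix(0, 2, 12), b = c(1, 2)),
                          X, bg, nPathSamples = 50, seed = 2)
  expect_true(all(at@values == 0))
})

test_that("attributions are seed-deterministic and duplication-invariant", {
  ep <- simulateEpochs(smallSepConfig(nSubjects = 2,
                                      trialsPerCondition = 6), seed = 4)
  spec <- modelSpec(convFilters = c(4L, 8L), kernelSize = 7L,
                    denseUnits = c(8L, 4L), nClasses = 3L)
  m <- buildModel(spec, nChannels(ep), nTimes(ep), seed = 2)
  m$classes <- conditionNames(ep)
  bgArr <- epochData(ep)[1:10, , , drop = FALSE]
  bg <- backgroundSet(bgArr, size = 10, seed = 1)
  X <- epochData(ep)[11:13, , , drop = FALSE]
  a1 <- expectedGradients(m, X, bg, nPathSamples = 40, seed = 7)
  a2 <- expectedGradients(m, X, bg, nPathSamples = 40, seed = 7)
  expect_identical(a1@values, a2@values)

  # duplicating every background sample leaves the estimate unchanged in
  # expectation; with balanced draws it is near-identical at tolerance
  bgDup <- backgroundSet(bgArr[rep(1:10, 2), , , drop = FALSE],
                         size = 20, seed = 1)
  a3 <- expectedGradients(m, X, bgDup, nPathSamples = 400, seed = 8)
  a4 <- expectedGradients(m, X, bg, nPathSamples = 400, seed = 9)
  scale <- max(abs(a4@values))
  expect_lt(max(abs(a3@values - a4@values)), 0.25 * scale)

  expect_error(expectedGradients(m, X, bg, nPathSamples = 0), "nPathSamples")
})

test_that("importance aggregation follows the absolute-mean contract", {
  n <- 5; k <- 2; C <- 4; T <- 6
  zero <- new("AttributionTensor", values = array(0, c(n, k, C, T)),
              classes = c("x", "y"), channels = sprintf("c%d", 1:C),
              times = as.numeric(1:T), trialLabels = rep(NA_character_, n),
              provenance = list())
  expect_true(all(aggregateImportance(zero)@values == 0))
  expect_true(all(classImportanceCurve(zero, "x")@values == 0))

  one <- zero
  v <- array(0, c(n, k, C, T)); v[1, 1, 3, 5] <- -2.5
  one@values <- v
  mat <- aggregateImportance(one)@values
  expect_equal(mat[3, 5], 2.5 / n)
  expect_equal(sum(mat), 2.5 / n)

  # triangle inequality: absolute aggregation dominates signed aggregation
  set.seed(3)
  rnd <- zero
  rnd@values <- array(rnorm(n * k * C * T), c(n, k, C, T))
  agAbs <- aggregateImportance(rnd)@values
  signed <- abs(colSums(colMeans(rnd@values, dims = 1), dims = 1))
  expect_true(all(agAbs - signed >= -1e-12))
})

test_that("per-class curves decompose the channel/time sums", {
  set.seed(4)
  n <- 6; k <- 3; C <- 4; T <- 8
  at <- new("AttributionTensor",
            values = array(rnorm(n * k * C * T), c(n, k, C, T)),
            classes = c("a", "b", "c"), channels = sprintf("c%d", 1:C),
            times = as.numeric(1:T),
            trialLabels = rep(c("a", "b", "c"), 2),
            provenance = list())
  cu <- classImportanceCurve(at, "b")
  expect_equal(sum(cu@values),
               mean(apply(abs(at@values[, 2, , ]), 1, sum)))
  # class-trial scoping restricts the mean to that class's trials
  cuScoped <- classImportanceCurve(at, "b", trialScope = "class_trials")
  idx <- which(at@trialLabels == "b")
  expect_equal(sum(cuScoped@values),
               mean(apply(abs(at@values[idx, 2, , ]), 1, sum)))
  expect_error(classImportanceCurve(at, "zz"), "unknown class")
})

test_that("attribution tensors roundtrip through the container format", {
  set.seed(13)
  vals <- array(round(rnorm(3 * 2 * 4 * 6) * 1024) / 1024, c(3, 2, 4, 6))
  at <- new("AttributionTensor", values = vals, classes = c("x", "y"),
            channels = sprintf("c%d", 1:4), times = as.numeric(0:5),
            trialLabels = c("x", "y", "x"),
            provenance = list(nPathSamples = 8))
  d <- withr::local_tempdir()
  writeAttributionTensor(at, file.path(d, "attr"))
  back <- readAttributionTensor(file.path(d, "attr"))
  expect_identical(back@values, at@values)
  expect_identical(back@classes, at@classes)
  expect_identical(back@trialLabels, at@trialLabels)
})
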