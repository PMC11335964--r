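test_that("subject-condition averaging is exact and order-invariant", {
  # hand-computed 2-trial mean on a 2-subject x 2-condition fixture
  d <- array(0, c(8, 1, 3))
  d[1, 1, ] <- c(1, 2, 3); d[2, 1, ] <- c(3, 2, 1)   # S1/a
  d[3, 1, ] <- c(0, 0, 4); d[4, 1, ] <- c(2, 0, 0)   # S1/b
  d[5:8, 1, ] <- 1
  ep <- EpochedData(d, labels = rep(c("a", "a", "b", "b"), 2),
                    sfreq = 1000,
                    subjectIds = rep(c("S1", "S2"), each = 4))
  erp <- subjectConditionAverages(ep)
  expect_equal(erp$means[1, 1, 1, ], c(2, 2, 2))
  expect_equal(erp$means[1, 2, 1, ], c(1, 0, 2))
  expect_equal(erp$means[2, 1, 1, ], c(1, 1, 1))

  # permuting trial order leaves the averages unchanged
  set.seed(3)
  perm <- sample(8)
  ep2 <- EpochedData(d[perm, , , drop = FALSE],
                     labels = epochLabels(ep)[perm], sfreq = 1000,
                     subjectIds = subjectIds(ep)[perm])
  erp2 <- subjectConditionAverages(ep2)
  # subjects are ordered by first occurrence; align before comparing
  expect_equal(erp2$means[match(erp$subjects, erp2$subjects), , , ,
                          drop = FALSE],
               erp$means)

  # a subject with identical trials averages to the trial itself
  expect_equal(erp$means[2, 1, 1, ], d[5, 1, ])

  bad <- EpochedData(d[1:6, , , drop = FALSE],
                     labels = c("a", "a", "b", "b", "a", "a"),
                     sfreq = 1000,
                     subjectIds = c(rep("S1", 4), "S2", "S2"))
  expect_error(subjectConditionAverages(bad), "missing cells.*S2/b")
})

test_that("the dependent F map agrees with the textbook rmANOVA", {
  n <- 8; k <- 3
  set.seed(21)
  for (r in 1:5) {
    A <- matrix(rnorm(n * k), n, k)
    erp <- structure(list(means = array(A, c(n, k, 1, 1)),
                          subjects = sprintf("s%d", 1:n),
                          conditions = letters[1:k],
                          channels = "c1", times = 0),
                     class = "SubjectConditionERP")
    fm <- dependentFMap(erp)
    expect_equal(fm$dfNum, 2); expect_equal(fm$dfDen, 14)
    df <- data.frame(y = as.vector(A), subj = factor(rep(1:n, k)),
                     cond = factor(rep(1:k, each = n)))
    av <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df))
    Faov <- av[["Error: subj:cond"]][[1]]["cond", "F value"]
    expect_equal(fm$F[1, 1], Faov, tolerance = 1e-10)
    # subject-specific constants cancel in the dependent design
    erp2 <- erp
    erp2$means <- erp$means + array(rep(rnorm(n, 0, 5), k), c(n, k, 1, 1))
    expect_equal(dependentFMap(erp2)$F[1, 1], fm$F[1, 1],
                 tolerance = 1e-8)
  }
  # identical conditions: F == 0 everywhere
  m2 <- array(0, c(n, k, 2, 2))
  vals <- matrix(rnorm(n * 4), n, 4)
  for (j in 1:k) m2[, j, , ] <- array(vals, c(n, 2, 2))
  erpSame <- structure(list(means = m2, subjects = sprintf("s%d", 1:n),
                            conditions = letters[1:k],
                            channels = c("c1", "c2"), times = 0:1),
                       class = "SubjectConditionERP")
  expect_true(all(dependentFMap(erpSame)$F == 0))
})

test_that("cluster threshold matches the F quantile", {
  expect_equal(fClusterThreshold(2, 50, 0.05), 3.1826, tolerance = 1e-3)
})

test_that("cluster formation obeys adjacency and the spatial rule", {
  # toy 3-channel chain a-b-c
  chain <- list(a = "b", b = c("a", "c"), c = "b")
  class(chain) <- "AdjacencyGraph"
  Fm <- matrix(0, 3, 10)
  Fm[1, 5:7] <- 10; Fm[2, 5:7] <- 11        # supra block on a,b at t=5..7
  fmap <- structure(list(F = Fm, dfNum = 2, dfDen = 14,
                         channels = c("a", "b", "c"),
                         times = as.numeric(0:9)),
                    class = "FMap")
  cl <- formClusters(fmap, permConfig(), chain)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$members), 6L)
  expect_equal(cl[[1]]$mass, sum(Fm))
  expect_setequal(cl[[1]]$channels, c("a", "b"))

  # an isolated single-channel supra-threshold sample is discarded
  Fi <- matrix(0, 3, 10); Fi[1, 4] <- 50
  fi <- fmap; fi$F <- Fi
  expect_length(formClusters(fi, permConfig(), chain), 0L)
  # ... but kept when the neighbour rule is relaxed
  expect_length(formClusters(fi, permConfig(minChannelNeighbors = 1L),
                             chain), 1L)
  # channels a and c are not adjacent: no qualifying cluster
  Fc <- matrix(0, 3, 10); Fc[1, 4] <- 50; Fc[3, 4] <- 50
  fc <- fmap; fc$F <- Fc
  expect_length(formClusters(fc, permConfig(), chain), 0L)

  badAdj <- list(x = "y", y = "x"); class(badAdj) <- "AdjacencyGraph"
  expect_error(formClusters(fmap, permConfig(), badAdj), "match")
})

test_that("raw connected components match an igraph flood fill", {
  skip_if_not_installed("igraph")
  set.seed(31)
  lay <- sphericalLayout(12)
  adj <- buildAdjacency(lay)
  nCh <- 12; nT <- 20
  cfg <- permConfig(minChannelNeighbors = 1L)  # raw components
  for (r in 1:25) {
    Fm <- matrix(stats::rexp(nCh * nT), nCh, nT)
    thr <- fClusterThreshold(2, 14, 0.05)
    Fm <- Fm * thr   # some supra, some not
    fmap <- structure(list(F = Fm, dfNum = 2, dfDen = 14,
                           channels = lay$name,
                           times = as.numeric(seq_len(nT) - 1)),
                      class = "FMap")
    got <- formClusters(fmap, cfg, adj)
    # independent flood fill on the same grid graph
    mask <- Fm > thr
    nodes <- which(mask)
    adjPairs <- sherpa:::.adjacencyPairs(adj, lay$name)
    grid <- sherpa:::.gridEdges(nCh, nT, adjPairs)
    keep <- mask[grid$edges[, 1]] & mask[grid$edges[, 2]]
    g <- igraph::graph_from_edgelist(
      matrix(as.character(grid$edges[keep, , drop = FALSE]),
             ncol = 2), directed = FALSE)
    g <- g + igraph::vertices(setdiff(as.character(nodes),
                                      igraph::V(g)$name))
    comp <- igraph::components(g)
    wantMasses <- sort(vapply(seq_len(comp$no), function(ci) {
      ids <- as.integer(igraph::V(g)$name[comp$membership == ci])
      sum(Fm[ids])
    }, 0))
    gotMasses <- sort(vapply(got, `[[`, 0, "mass"))
    expect_equal(gotMasses, wantMasses, tolerance = 1e-12)
  }
})

test_that("permutation p-values are valid, deterministic and label-consistent", {
  ep <- nullDataset(nullSmallConfig(seed = 2), seed = 2)
  erp <- subjectConditionAverages(ep)
  adj <- buildAdjacency(sphericalLayout(16))
  cfg <- permConfig(nPermutations = 80L)
  r1 <- clusterPermutationTest(erp, cfg, adj, seed = 5)
  r2 <- clusterPermutationTest(erp, cfg, adj, seed = 5)
  expect_identical(r1@pValues, r2@pValues)
  expect_identical(r1@nullDistribution, r2@nullDistribution)
  if (length(r1@pValues)) {
    expect_true(all(r1@pValues >= 1 / 81 - 1e-12))
    expect_true(all(r1@pValues <= 1))
  }

  # consistent channel relabeling of data and adjacency leaves the
  # cluster masses and p-values unchanged
  set.seed(6)
  perm <- sample(16)
  lay <- sphericalLayout(16)
  layP <- lay[perm, ]
  erpP <- erp
  erpP$means <- erp$means[, , perm, , drop = FALSE]
  erpP$channels <- erp$channels[perm]
  rP <- clusterPermutationTest(erpP, cfg, buildAdjacency(layP), seed = 5)
  expect_equal(sort(vapply(rP@clusters, `[[`, 0, "mass")),
               sort(vapply(r1@clusters, `[[`, 0, "mass")))
  expect_equal(sort(rP@pValues), sort(r1@pValues))
})

test_that("a strong implanted effect is detected where it was implanted", {
  cfgSim <- presetDesk("strong", seed = 3)
  ep <- simulateEpochs(cfgSim)
  erp <- subjectConditionAverages(ep)
  adj <- buildAdjacency(cfgSim$layout)
  res <- clusterPermutationTest(erp, permConfig(nPermutations = 100L),
                                adj, seed = 4)
  expect_gte(length(res@clusters), 1L)
  expect_lte(min(res@pValues), 0.05)
  sig <- which(res@pValues <= 0.05)
  covers <- function(lat) any(vapply(sig, function(i)
    res@clusters[[i]]$timeRange[1] <= lat &&
      res@clusters[[i]]$timeRange[2] >= lat, TRUE))
  expect_true(covers(170) || covers(300))
})

test_that("the conventional rmANOVA reproduces textbook arithmetic", {
  # 26 subjects x 3 conditions: degrees of freedom as published designs
  cond <- c("face", "blurred", "scrambled")
  lay <- sphericalLayout(4)
  cfg <- simulationConfig(cond, nSubjects = 26, trialsPerCondition = 4,
                          layout = lay, sfreq = 512, tStart = 100,
                          tEnd = 250,
                          components = list(componentSpec(
                            180, 15, -5,
                            stats::setNames(c(1, .6, 0, 0), lay$name),
                            stats::setNames(c(1, .5, .9), cond))),
                          noise = noiseSpec(whiteSD = 1.5), seed = 12)
  ep <- simulateEpochs(cfg)
  an <- conventionalAnalysis(ep, electrodes = c("E01", "E02"),
                             window = c(165, 205))
  expect_equal(an$dfNum, 2)
  expect_equal(an$dfDen, 50)
  expect_equal(unique(an$pairwise$df), 25)
  expect_equal(nrow(an$pairwise), 3L)
  expect_true(an$etaSq >= 0 && an$etaSq <= 1)

  # longhand sum-of-squares oracle on the extracted amplitude table
  A <- an$amplitudes
  g <- mean(A); cj <- colMeans(A); mi <- rowMeans(A)
  ssc <- nrow(A) * sum((cj - g)^2)
  sse <- sum((A - outer(mi, rep(1, 3)) - outer(rep(1, 26), cj) + g)^2)
  expect_equal(an$F, (ssc / 2) / (sse / 50), tolerance = 1e-10)
  expect_equal(an$etaSq, ssc / (ssc + sse), tolerance = 1e-10)

  # identical condition data: F and all pairwise t collapse to zero
  d <- epochData(ep)
  dSame <- d
  labs <- epochLabels(ep)
  for (s in unique(subjectIds(ep))) {
    idx <- which(subjectIds(ep) == s)
    dSame[idx, , ] <- rep(colMeans(d[idx[labs[idx] == "face"], , ,
                                     drop = FALSE], dims = 1),
                          each = length(idx))
  }
  epSame <- EpochedData(dSame, labels = labs, sfreq = 512, t0 = 100,
                        channels = channelNames(ep),
                        subjectIds = subjectIds(ep))
  anSame <- conventionalAnalysis(epSame, electrodes = c("E01", "E02"),
                                 window = c(165, 205))
  expect_equal(anSame$F, 0)
  expect_true(all(abs(anSame$pairwise$t) < 1e-8))

  expect_error(conventionalAnalysis(ep, electrodes = "Nonsense"),
               "unknown electrode")
})

test_that("10-20 aliases resolve onto the packaged 128-channel layout", {
  al <- electrodeAliases()
  expect_true(all(c("P7", "P8", "PO7", "PO8", "P9", "P10") %in% al$alias))
  expect_true(all(al$channel %in% biosemiLayout()$name))
  expect_false(anyDuplicated(al$channel) > 0)
})
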