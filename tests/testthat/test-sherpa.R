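test_that("peak finding matches hand-worked and degenerate cases", {
  cfg <- sherpaConfig(extremumOrder = 1L)
  p <- findImportancePeaks(c(0, 1, 0, 2, 0), cfg)
  expect_equal(p$sample, c(3L, 1L))       # descending importance
  expect_equal(p$value, c(2, 1))

  # strictly increasing curve: endpoints are never peaks
  expect_equal(nrow(findImportancePeaks(seq(0, 1, length.out = 20), cfg)),
               0L)
  # constant curve has no strict local maximum
  expect_equal(nrow(findImportancePeaks(rep(1, 20), cfg)), 0L)
  # flat plateau yields no peak under the strict-inequality policy
  expect_equal(nrow(findImportancePeaks(c(0, 1, 1, 0, 0), cfg)), 0L)
  expect_error(findImportancePeaks(c(1, 2, 1),
                                   sherpaConfig(extremumOrder = 5L)),
               "exceed")
})

test_that("peak finder equals the brute-force reference on random curves", {
  set.seed(7)
  for (r in 1:200) {
    n <- sample(25:80, 1)
    ord <- sample(1:8, 1)
    v <- abs(rnorm(n)) + ifelse(runif(1) < 0.3,
                                rep(0.5, n),  # induce potential ties
                                cumsum(rnorm(n, 0, 0.1)))
    v <- abs(v)
    if (runif(1) < 0.2) v[sample(n, 3)] <- v[1]  # exact ties
    cfg <- sherpaConfig(extremumOrder = ord, topKPeaks = n)
    got <- sort(findImportancePeaks(v, cfg)$sample + 1L)
    expect_identical(got, sort(bruteForcePeaks(v, ord)))
  }
})

test_that("window extraction centers the peak and clips at the grid", {
  times <- indexToTime(0:767, 512)
  w <- extractWindow(156.25, 40, times)
  expect_equal(w$tLo, 136.25)
  expect_equal(w$tHi, 176.25)
  expect_false(w$clipped)
  # center equals the peak whenever no clipping occurs
  set.seed(2)
  for (pk in sample(times[30:700], 10)) {
    wi <- extractWindow(pk, 40, times)
    expect_equal((wi$tLo + wi$tHi) / 2, pk)
    expect_equal(wi$tHi - wi$tLo, 40)
  }
  wc <- extractWindow(times[2], 40, times)
  expect_true(wc$clipped)
  expect_equal(wc$tLo, times[1])
  expect_error(extractWindow(100, 0, times), "> 0")
})

test_that("electrode ranking produces nested quantile sets", {
  chs <- sprintf("c%02d", 1:10)
  times <- as.numeric(0:19)
  base <- matrix(0, 10, 20)
  base[4, 6:9] <- 3      # only channel c04 carries importance
  m <- new("ImportanceMatrix", values = base, channels = chs,
           times = times, aggregation = "test")
  w <- extractWindow(7, 4, times)
  rep_ <- rankElectrodes(m, w, sherpaConfig())
  expect_equal(names(rep_$scores)[1], "c04")
  for (qs in rep_$quantileSets) expect_true("c04" %in% qs)

  # uniform matrix: every channel reaches every quantile
  mu <- new("ImportanceMatrix", values = matrix(1, 10, 20),
            channels = chs, times = times, aggregation = "test")
  repU <- rankElectrodes(mu, w, sherpaConfig())
  for (qs in repU$quantileSets) expect_setequal(qs, chs)

  # nesting on random matrices
  set.seed(9)
  for (r in 1:100) {
    mr <- new("ImportanceMatrix",
              values = matrix(abs(rnorm(200)), 10, 20),
              channels = chs, times = times, aggregation = "test")
    rr <- rankElectrodes(mr, w, sherpaConfig())
    expect_true(all(rr$quantileSets[["q0.9"]] %in%
                      rr$quantileSets[["q0.75"]]))
  }
  badW <- extractWindow(7, 4, times); badW$idxLo <- 50L; badW$idxHi <- 60L
  expect_error(rankElectrodes(m, badW, sherpaConfig()), "outside")
})

test_that("full reports are deterministic, scale-equivariant, and empty on zero input", {
  set.seed(12)
  n <- 4; k <- 3; C <- 6; T <- 64
  vals <- array(rnorm(n * k * C * T, 0, 0.01), c(n, k, C, T))
  # implant a smooth bump so peaks exist
  bump <- exp(-(seq_len(T) - 30)^2 / 18)
  for (i in 1:n) vals[i, 1, 2, ] <- vals[i, 1, 2, ] + 0.2 * bump
  at <- new("AttributionTensor", values = vals,
            classes = c("a", "b", "c"), channels = sprintf("c%d", 1:C),
            times = indexToTime(0:(T - 1), 512),
            trialLabels = rep(NA_character_, n), provenance = list())
  cfg <- sherpaConfig(extremumOrder = 5L)
  r1 <- sherpaReport(at, cfg)
  r2 <- sherpaReport(at, cfg)
  expect_identical(r1, r2)
  expect_true(nrow(r1$a$peaks) >= 1)

  lam <- 3.7
  atS <- at; atS@values <- at@values * lam
  rS <- sherpaReport(atS, cfg)
  for (cls in names(r1)) {
    expect_equal(rS[[cls]]$peaks$latency, r1[[cls]]$peaks$latency)
    expect_equal(rS[[cls]]$peaks$value, lam * r1[[cls]]$peaks$value)
    for (j in seq_along(r1[[cls]]$windows)) {
      expect_equal(rS[[cls]]$windows[[j]]$window,
                   r1[[cls]]$windows[[j]]$window)
      expect_equal(rS[[cls]]$windows[[j]]$quantileSets,
                   r1[[cls]]$windows[[j]]$quantileSets)
      expect_equal(rS[[cls]]$windows[[j]]$scores,
                   lam * r1[[cls]]$windows[[j]]$scores)
    }
  }

  zero <- at; zero@values <- array(0, dim(at@values))
  rz <- sherpaReport(zero, cfg)
  for (cls in names(rz)) {
    expect_equal(nrow(rz[[cls]]$peaks), 0L)
    expect_length(rz[[cls]]$windows, 0L)
  }
})
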