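## The two validation analyses: a spatio-temporal cluster-based
## permutation test on the dependent (repeated-measures) F statistic, and
## the conventional researcher-driven rmANOVA on mean amplitudes in a
## literature window.

#' Configure the cluster-based permutation test
#'
#' @param clusterAlpha sample-level threshold: samples with
#'   `F > qF(1 - clusterAlpha)` enter clusters.
#' @param testAlpha cluster-level significance level.
#' @param nPermutations Monte-Carlo draws from the permutation
#'   distribution.
#' @param minChannelNeighbors a cluster must, at some time point, span at
#'   least this many mutually adjacent channels; clusters that never do
#'   are discarded.
#' @param seed seed of the permutation stream.
#' @return a `PermConfig` list.
#' @export
permConfig <- function(clusterAlpha = 0.05, testAlpha = 0.05,
                       nPermutations = 500L, minChannelNeighbors = 2L,
                       seed = 1L) {
  stopifnot(clusterAlpha > 0, clusterAlpha < 1, testAlpha > 0,
            testAlpha < 1, nPermutations >= 1, minChannelNeighbors >= 1)
  structure(list(clusterAlpha = clusterAlpha, testAlpha = testAlpha,
                 nPermutations = as.integer(nPermutations),
                 minChannelNeighbors = as.integer(minChannelNeighbors),
                 seed = as.integer(seed)),
            class = "PermConfig")
}

#' Per-subject condition-average ERPs
#'
#' Averages every subject's trials within each condition -- the complete
#' within-subject design required by the dependent statistics.
#'
#' @param epochs an [EpochedData-class] object.
#' @return a `SubjectConditionERP` list: `means` array
#'   `[n_subjects, n_conditions, n_channels, n_times]`, plus axis
#'   metadata.
#' @export
subjectConditionAverages <- function(epochs) {
  stopifnot(is(epochs, "EpochedData"))
  subjects <- unique(subjectIds(epochs))
  conditions <- conditionNames(epochs)
  d <- dim(epochData(epochs))
  means <- array(0, c(length(subjects), length(conditions), d[2L], d[3L]))
  missing <- character(0)
  for (si in seq_along(subjects)) {
    for (ci in seq_along(conditions)) {
      idx <- which(subjectIds(epochs) == subjects[si] &
                     epochLabels(epochs) == conditions[ci])
      if (!length(idx)) {
        missing <- c(missing,
                     sprintf("%s/%s", subjects[si], conditions[ci]))
        next
      }
      means[si, ci, , ] <- colMeans(
        epochData(epochs)[idx, , , drop = FALSE], dims = 1L)
    }
  }
  if (length(missing))
    stop("incomplete within-subject design; missing cells: ",
         paste(missing, collapse = ", "))
  structure(list(means = means, subjects = subjects,
                 conditions = conditions,
                 channels = channelNames(epochs),
                 times = epochTimes(epochs)),
            class = "SubjectConditionERP")
}

## One-way repeated-measures decomposition on an n x k table:
## SS_cond = n sum_j (c_j - g)^2, SS_err = sum_ij (y - m_i - c_j + g)^2,
## F = MS_cond / MS_(cond x subj), df (k-1, (k-1)(n-1)).
.rmAnovaTable <- function(A) {
  n <- nrow(A); k <- ncol(A)
  stopifnot(n >= 2, k >= 2)
  g <- mean(A)
  cj <- colMeans(A); mi <- rowMeans(A)
  ssCond <- n * sum((cj - g)^2)
  resid <- A - outer(mi, rep(1, k)) - outer(rep(1, n), cj) + g
  ssErr <- sum(resid^2)
  dfN <- k - 1; dfD <- (k - 1) * (n - 1)
  scale <- max(mean(A^2), .Machine$double.eps)
  Fv <- if (ssErr <= 1e-18 * scale)
    (if (ssCond <= 1e-18 * scale) 0 else Inf)
  else (ssCond / dfN) / (ssErr / dfD)
  list(F = Fv, dfNum = dfN, dfDen = dfD,
       p = pf(Fv, dfN, dfD, lower.tail = FALSE),
       ssCond = ssCond, ssErr = ssErr,
       etaSq = if (ssCond + ssErr > 0) ssCond / (ssCond + ssErr) else 0)
}

#' Map of the dependent F statistic over channels and times
#'
#' At each (channel, time) sample, the one-way repeated-measures F
#' `MS_condition / MS_(condition x subject)` with degrees of freedom
#' `(k - 1, (k - 1)(n - 1))`.  Samples with zero effect and zero error
#' variance are defined as `F = 0`.
#'
#' @param erp a [subjectConditionAverages()] result.
#' @return an `FMap` list: `F` matrix `[n_channels, n_times]`, `dfNum`,
#'   `dfDen`, `channels`, `times`.
#' @export
dependentFMap <- function(erp) {
  stopifnot(inherits(erp, "SubjectConditionERP"))
  d <- dim(erp$means)
  n <- d[1L]; k <- d[2L]; S <- d[3L] * d[4L]
  if (n < 2L || k < 2L)
    stop("need >= 2 subjects and >= 2 conditions")
  Y <- matrix(erp$means, n * k, S)
  subjIdx <- rep(seq_len(n), k)
  condIdx <- rep(seq_len(k), each = n)
  g <- colMeans(Y)
  Cm <- rowsum(Y, condIdx) / n
  Sm <- rowsum(Y, subjIdx) / k
  ssCond <- n * colSums(sweep(Cm, 2L, g)^2)
  resid <- Y - Sm[subjIdx, , drop = FALSE] - Cm[condIdx, , drop = FALSE]
  resid <- sweep(resid, 2L, g, "+")
  ssErr <- colSums(resid^2)
  dfN <- k - 1; dfD <- (k - 1) * (n - 1)
  scale <- pmax(colMeans(Y^2), .Machine$double.eps)
  Fv <- ifelse(ssErr <= 1e-18 * scale,
               ifelse(ssCond <= 1e-18 * scale, 0, Inf),
               (ssCond / dfN) / (ssErr / dfD))
  structure(list(F = matrix(Fv, d[3L], d[4L]), dfNum = dfN, dfDen = dfD,
                 channels = erp$channels, times = erp$times),
            class = "FMap")
}

#' Sample-level cluster-forming threshold
#'
#' Upper-tail critical value of the F distribution:
#' `qf(1 - alpha, dfNum, dfDen)`.
#'
#' @param dfNum,dfDen degrees of freedom.
#' @param alpha sample-level alpha.
#' @return the critical F value.
#' @export
fClusterThreshold <- function(dfNum, dfDen, alpha = 0.05) {
  qf(1 - alpha, dfNum, dfDen)
}

## Iterative union-find with path halving.
.unionFind <- function(nNodes, edges) {
  parent <- seq_len(nNodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(nNodes), find, 0L)
}

## Precompute the spatio-temporal grid edges for a C x T map:
## (ch,t)~(ch,t+1) and (ch,t)~(ch',t) for adjacent channel pairs.
## Node id = ch + C*(t-1) (column-major).
.gridEdges <- function(nCh, nT, adjPairs) {
  tEdges <- if (nT > 1L) {
    t0 <- rep(seq_len(nT - 1L), each = nCh)
    ch <- rep(seq_len(nCh), nT - 1L)
    cbind(ch + nCh * (t0 - 1L), ch + nCh * t0)
  } else matrix(0L, 0L, 2L)
  sEdges <- if (nrow(adjPairs)) {
    tt <- rep(seq_len(nT), each = nrow(adjPairs))
    a <- rep(adjPairs[, 1L], nT)
    b <- rep(adjPairs[, 2L], nT)
    cbind(a + nCh * (tt - 1L), b + nCh * (tt - 1L))
  } else matrix(0L, 0L, 2L)
  list(edges = rbind(tEdges, sEdges),
       spatial = c(rep(FALSE, nrow(tEdges)), rep(TRUE, nrow(sEdges))))
}

.adjacencyPairs <- function(adjacency, channels) {
  if (!setequal(names(adjacency), channels))
    stop("adjacency channels do not match the map channels")
  ed <- adjacencyEdges(adjacency)
  cbind(match(ed$from, channels), match(ed$to, channels))
}

## Largest mutually-adjacent channel group inside a channel subset.
.largestAdjacentGroup <- function(chIdx, adjPairs) {
  if (length(chIdx) <= 1L) return(length(chIdx))
  sel <- adjPairs[, 1L] %in% chIdx & adjPairs[, 2L] %in% chIdx
  if (!any(sel)) return(1L)
  sub <- adjPairs[sel, , drop = FALSE]
  rank <- match(seq_len(max(chIdx)), chIdx)
  comp <- .unionFind(length(chIdx),
                     cbind(rank[sub[, 1L]], rank[sub[, 2L]]))
  max(tabulate(comp))
}

## Core clustering on a supra-threshold mask; returns member node ids,
## masses, and applies the min-neighbour spatial rule.
.clusterMask <- function(Fv, mask, nCh, nT, grid, adjPairs, minNb) {
  nodes <- which(mask)
  if (!length(nodes)) return(list())
  eSel <- mask[grid$edges[, 1L]] & mask[grid$edges[, 2L]]
  edges <- grid$edges[eSel, , drop = FALSE]
  rank <- integer(nCh * nT)
  rank[nodes] <- seq_along(nodes)
  comp <- .unionFind(length(nodes),
                     cbind(rank[edges[, 1L]], rank[edges[, 2L]]))
  out <- list()
  for (cid in unique(comp)) {
    mem <- nodes[comp == cid]
    ch <- ((mem - 1L) %% nCh) + 1L
    tt <- ((mem - 1L) %/% nCh) + 1L
    if (minNb > 1L) {
      ok <- FALSE
      for (t in unique(tt)) {
        grp <- .largestAdjacentGroup(unique(ch[tt == t]), adjPairs)
        if (grp >= minNb) { ok <- TRUE; break }
      }
      if (!ok) next
    }
    out[[length(out) + 1L]] <- list(members = cbind(channel = ch,
                                                    time = tt),
                                    mass = sum(Fv[mem]))
  }
  out
}

#' Form spatio-temporal clusters from an F map
#'
#' Supra-threshold samples (`F` above the critical value at
#' `clusterAlpha` for the map's degrees of freedom) are grouped by
#' temporal adjacency on the same channel and spatial adjacency at the
#' same time point; clusters that never span `minChannelNeighbors`
#' mutually adjacent channels at any time point are discarded.  Cluster
#' mass is the sum of F over members.
#'
#' @param fmap a [dependentFMap()] result.
#' @param cfg a [permConfig()].
#' @param adjacency an `AdjacencyGraph` over the map's channels.
#' @return list of clusters sorted by descending mass; each has
#'   `members` (channel/time index matrix), `channels`, `timeRange` (ms)
#'   and `mass`.
#' @export
formClusters <- function(fmap, cfg, adjacency) {
  stopifnot(inherits(fmap, "FMap"), inherits(cfg, "PermConfig"))
  nCh <- nrow(fmap$F); nT <- ncol(fmap$F)
  adjPairs <- .adjacencyPairs(adjacency, fmap$channels)
  grid <- .gridEdges(nCh, nT, adjPairs)
  thr <- fClusterThreshold(fmap$dfNum, fmap$dfDen, cfg$clusterAlpha)
  cl <- .clusterMask(fmap$F, fmap$F > thr, nCh, nT, grid, adjPairs,
                     cfg$minChannelNeighbors)
  cl <- cl[order(-vapply(cl, `[[`, 0, "mass"))]
  lapply(cl, function(x) {
    list(members = x$members,
         channels = fmap$channels[sort(unique(x$members[, "channel"]))],
         timeRange = range(fmap$times[x$members[, "time"]]),
         mass = x$mass)
  })
}

#' Cluster-based permutation test on the dependent F statistic
#'
#' The null distribution relabels the conditions independently within
#' every subject (the exchangeability-preserving scheme for a dependent
#' design), recomputes the F map, reclusters, and records the maximum
#' cluster mass (0 when no cluster forms).  Each observed cluster's
#' Monte-Carlo p-value is `(1 + #(null >= mass)) / (nPermutations + 1)`,
#' which includes the observed statistic in the null for validity.
#'
#' @param erp a [subjectConditionAverages()] result.
#' @param cfg a [permConfig()].
#' @param adjacency an `AdjacencyGraph` over the data channels.
#' @param seed permutation seed (defaults to `cfg$seed`).
#' @return a [ClusterResult-class].
#' @export
clusterPermutationTest <- function(erp, cfg, adjacency, seed = cfg$seed) {
  stopifnot(inherits(erp, "SubjectConditionERP"),
            inherits(cfg, "PermConfig"))
  fmap <- dependentFMap(erp)
  nCh <- nrow(fmap$F); nT <- ncol(fmap$F)
  adjPairs <- .adjacencyPairs(adjacency, fmap$channels)
  grid <- .gridEdges(nCh, nT, adjPairs)
  thr <- fClusterThreshold(fmap$dfNum, fmap$dfDen, cfg$clusterAlpha)
  observed <- formClusters(fmap, cfg, adjacency)

  d <- dim(erp$means)
  n <- d[1L]; k <- d[2L]; S <- d[3L] * d[4L]
  Y <- matrix(erp$means, n * k, S)
  g <- colMeans(Y)
  Sm <- rowsum(Y, rep(seq_len(n), k)) / k
  # within-subject total SS: invariant under per-subject relabeling and
  # equal to SS_cond + SS_err at every sample
  W <- colSums(Y^2) - k * colSums(Sm^2)
  dfN <- k - 1; dfD <- (k - 1) * (n - 1)
  scale <- pmax(colMeans(Y^2), .Machine$double.eps)

  set.seed(deriveSeed(seed, "permutation"))
  nullMax <- numeric(cfg$nPermutations)
  for (b in seq_len(cfg$nPermutations)) {
    Csum <- matrix(0, k, S)
    for (i in seq_len(n)) {
      pi_ <- sample.int(k)
      Csum <- Csum + Y[i + n * (pi_ - 1L), , drop = FALSE]
    }
    ssCond <- n * colSums(sweep(Csum / n, 2L, g)^2)
    ssErr <- pmax(W - ssCond, 0)
    Fv <- ifelse(ssErr <= 1e-18 * scale,
                 ifelse(ssCond <= 1e-18 * scale, 0, Inf),
                 (ssCond / dfN) / (ssErr / dfD))
    Fm <- matrix(Fv, nCh, nT)
    cl <- .clusterMask(Fm, Fm > thr, nCh, nT, grid, adjPairs,
                       cfg$minChannelNeighbors)
    nullMax[b] <- if (length(cl))
      max(vapply(cl, `[[`, 0, "mass")) else 0
  }
  pv <- vapply(observed, function(x)
    (1 + sum(nullMax >= x$mass)) / (cfg$nPermutations + 1), 0)
  new("ClusterResult", clusters = observed, nullDistribution = nullMax,
      pValues = pv, threshold = thr, dfNum = dfN, dfDen = dfD,
      nPermutations = cfg$nPermutations, seed = as.integer(seed))
}

.resolveElectrodes <- function(electrodes, channels) {
  al <- electrodeAliases()
  out <- character(length(electrodes))
  for (i in seq_along(electrodes)) {
    e <- electrodes[i]
    if (e %in% channels) out[i] <- e
    else if (e %in% al$alias) {
      ch <- al$channel[al$alias == e]
      if (!ch %in% channels)
        stop(sprintf("alias '%s' maps to '%s', absent from the data", e, ch))
      out[i] <- ch
    } else {
      stop(sprintf("unknown electrode '%s'; channels or aliases allowed (aliases: %s)",
                   e, paste(al$alias, collapse = ", ")))
    }
  }
  unique(out)
}

#' Conventional researcher-driven rmANOVA on mean amplitudes
#'
#' Extracts each subject's per-condition mean amplitude over a set of
#' literature electrodes and a fixed latency window (inclusive bounds),
#' then runs a one-way repeated-measures ANOVA with factor condition
#' (uncorrected degrees of freedom, partial eta squared) and all
#' pairwise paired t-tests.
#'
#' @param epochs an [EpochedData-class] object.
#' @param electrodes channel names or 10-20 aliases (see
#'   [electrodeAliases()]); defaults to the classic N170 set.
#' @param window inclusive latency window in ms, default `c(165, 205)`.
#' @return an `AnovaResult` list: `F`, `dfNum`, `dfDen`, `p`, `etaSq`
#'   (partial), `pairwise` data.frame, `amplitudes` (subject x condition
#'   table), `electrodes`, `window`.
#' @export
conventionalAnalysis <- function(epochs,
                                 electrodes = c("P7", "P8", "PO7", "PO8",
                                                "P9", "P10"),
                                 window = c(165, 205)) {
  stopifnot(is(epochs, "EpochedData"), length(window) == 2L,
            window[1L] < window[2L])
  chs <- .resolveElectrodes(electrodes, channelNames(epochs))
  tIdx <- which(epochTimes(epochs) >= window[1L] &
                  epochTimes(epochs) <= window[2L])
  if (!length(tIdx))
    stop("the latency window contains no samples")
  erp <- subjectConditionAverages(epochs)
  chIdx <- match(chs, erp$channels)
  A <- apply(erp$means[, , chIdx, tIdx, drop = FALSE], c(1L, 2L), mean)
  colnames(A) <- erp$conditions
  rownames(A) <- erp$subjects
  res <- .rmAnovaTable(A)
  pairs <- utils::combn(erp$conditions, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    dif <- A[, a] - A[, b]
    if (sd(dif) <= 1e-14 * max(abs(A), 1)) {
      # identical conditions: the paired t degenerates to 0
      tt <- list(statistic = 0, parameter = nrow(A) - 1L, p.value = 1)
    } else {
      tt <- t.test(A[, a], A[, b], paired = TRUE)
    }
    data.frame(pair = paste(a, b, sep = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  structure(list(F = res$F, dfNum = res$dfNum, dfDen = res$dfDen,
                 p = res$p, etaSq = res$etaSq, pairwise = pw,
                 amplitudes = A, electrodes = chs, window = window),
            class = "AnovaResult")
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat(sprintf("rmANOVA: F(%d,%d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$dfNum, x$dfDen, x$F, x$p, x$etaSq))
  cat(sprintf("  electrodes: %s; window %g..%g ms\n",
              paste(x$electrodes, collapse = ", "),
              x$window[1L], x$window[2L]))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
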