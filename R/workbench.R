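## End-to-end orchestration: simulate (or load) -> split -> train ->
## evaluate -> attribute -> distill -> comparator analyses -> comparison
## table, with every artifact written to a run directory as plain text
## (JSON/CSV) plus serialized model states, and a provenance record.

#' Assemble a full pipeline configuration
#'
#' @param simulation a [simulationConfig()], or `NULL` with `epochsPath`
#'   pointing at an existing epochs container.
#' @param epochsPath optional path to an epochs container (used when
#'   `simulation` is `NULL`).
#' @param model a [modelSpec()].
#' @param training a [trainingConfig()].
#' @param sherpa a [sherpaConfig()].
#' @param perm a [permConfig()].
#' @param backgroundSize background samples for attribution.
#' @param nPathSamples expected-gradients path samples.
#' @param anovaElectrodes,anovaWindow conventional-analysis settings
#'   (`NULL` electrodes picks the channels with the highest grand-average
#'   negativity in the window -- the packaged aliases assume the
#'   128-channel layout).
#' @param seed global seed; every stochastic stage derives its own
#'   sub-stream from it.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(simulation = presetDesk(), epochsPath = NULL,
                      model = deskModelSpec(), training = trainingConfig(),
                      sherpa = sherpaConfig(), perm = permConfig(),
                      backgroundSize = 100L, nPathSamples = 200L,
                      anovaElectrodes = NULL, anovaWindow = c(165, 205),
                      seed = 1L) {
  if (is.null(simulation) && is.null(epochsPath))
    stop("either 'simulation' or 'epochsPath' must be given")
  structure(list(simulation = simulation, epochsPath = epochsPath,
                 model = model, training = training, sherpa = sherpa,
                 perm = perm, backgroundSize = as.integer(backgroundSize),
                 nPathSamples = as.integer(nPathSamples),
                 anovaElectrodes = anovaElectrodes,
                 anovaWindow = anovaWindow, seed = as.integer(seed)),
            class = "RunConfig")
}

.logLine <- function(con, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  if (!is.null(con)) writeLines(line, con)
  message(line)
}

## Fallback electrode pick for layouts without packaged aliases: the
## channels with the most negative grand average in the window.
.defaultAnovaElectrodes <- function(epochs, window, nPick = 6L) {
  tIdx <- which(epochTimes(epochs) >= window[1L] &
                  epochTimes(epochs) <= window[2L])
  ga <- colMeans(epochData(epochs)[, , tIdx, drop = FALSE], dims = 1L)
  score <- rowMeans(ga)
  channelNames(epochs)[order(score)][seq_len(min(nPick, length(score)))]
}

#' Run the full pipeline into a run directory
#'
#' Executes every stage with seeds derived from the global seed and
#' persists: the epochs container (when simulated), fold model states and
#' the evaluation report, the importance matrix and per-class curves, the
#' SHERPA report, the cluster-permutation and rmANOVA results, a
#' cross-method comparison table, a structured log and a provenance
#' record.  A stage failure aborts with the stage name; artifacts of
#' completed stages remain on disk.
#'
#' @param cfg a [runConfig()].
#' @param outputDir run directory (created if needed).
#' @return the output directory, invisibly; artifacts on disk.
#' @export
runPipeline <- function(cfg, outputDir) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file(file.path(outputDir, "log.txt"), "w")
  on.exit(close(logCon))
  seed <- cfg$seed
  stage <- "init"
  artifacts <- list()
  tryCatch({
    stage <- "simulate"
    epochs <- if (!is.null(cfg$simulation)) {
      .logLine(logCon, "simulate: generating epochs")
      e <- simulateEpochs(cfg$simulation, seed = deriveSeed(seed, "simulate"))
      writeEpochs(e, file.path(outputDir, "epochs"))
      artifacts$epochs <- "epochs/"
      e
    } else {
      .logLine(logCon, paste("load:", cfg$epochsPath))
      readEpochs(cfg$epochsPath)
    }

    stage <- "split"
    sp <- splitData(epochs, cfg$training, seed = seed)
    .logLine(logCon, sprintf("split: %d train / %d test trials",
                             nTrials(sp$train), nTrials(sp$test)))

    stage <- "train"
    fit <- trainCrossval(cfg$model, sp$train, cfg$training, seed = seed)
    .logLine(logCon, sprintf("train: fold val acc %s",
                             paste(sprintf("%.3f", fit$foldValAccuracy),
                                   collapse = "/")))
    dir.create(file.path(outputDir, "models"), showWarnings = FALSE)
    for (f in seq_along(fit$models))
      writeModelState(fit$models[[f]],
                      file.path(outputDir, "models",
                                sprintf("fold%d.rds", f)))
    artifacts$models <- "models/"

    stage <- "evaluate"
    ev <- evaluateModels(fit, sp$test)
    .logLine(logCon, sprintf("evaluate: test acc %.3f (SD %.3f)",
                             ev$testAccuracyMean, ev$testAccuracySD))
    .writeJSON(list(perFoldValAccuracy = ev$perFoldValAccuracy,
                    testAccuracies = ev$testAccuracies,
                    testAccuracyMean = ev$testAccuracyMean,
                    testAccuracySD = ev$testAccuracySD),
               file.path(outputDir, "evaluation.json"))
    cm <- as.data.frame(ev$confusion)
    write.csv(cm, file.path(outputDir, "confusion.csv"),
              row.names = TRUE)
    artifacts$evaluation <- "evaluation.json"

    stage <- "attribute"
    bg <- backgroundSet(sp$train, size = cfg$backgroundSize,
                        seed = deriveSeed(seed, "bg"))
    attr <- expectedGradients(fit$models[[length(fit$models)]], sp$test,
                              bg, nPathSamples = cfg$nPathSamples,
                              seed = deriveSeed(seed, "attr"))
    .logLine(logCon, "attribute: expected gradients done")
    mat <- aggregateImportance(attr)
    mv <- mat@values
    rownames(mv) <- mat@channels
    colnames(mv) <- sprintf("%.4f", mat@times)
    write.csv(mv, file.path(outputDir, "importance_matrix.csv"))
    curves <- do.call(rbind, lapply(attr@classes, function(cls) {
      cu <- classImportanceCurve(attr, cls)
      data.frame(class = cls, time = cu@times, value = cu@values)
    }))
    write.csv(curves, file.path(outputDir, "importance_curves.csv"),
              row.names = FALSE)
    artifacts$importance <- "importance_matrix.csv"

    stage <- "sherpa"
    rep_ <- sherpaReport(attr, cfg$sherpa)
    writeSherpaReport(rep_, file.path(outputDir, "sherpa_report.json"))
    .logLine(logCon, "sherpa: report written")
    artifacts$sherpa <- "sherpa_report.json"

    stage <- "permtest"
    erp <- subjectConditionAverages(epochs)
    adjacency <- buildAdjacency(
      if (!is.null(cfg$simulation)) cfg$simulation$layout
      else sphericalLayout(nChannels(epochs)))
    clus <- clusterPermutationTest(erp, cfg$perm, adjacency,
                                   seed = deriveSeed(seed, "perm"))
    .writeJSON(list(
      threshold = clus@threshold, dfNum = clus@dfNum, dfDen = clus@dfDen,
      nPermutations = clus@nPermutations, pValues = clus@pValues,
      clusters = lapply(clus@clusters, function(cl) list(
        channels = cl$channels, timeRange = cl$timeRange,
        mass = cl$mass, nSamples = nrow(cl$members)))),
      file.path(outputDir, "cluster_result.json"))
    if (length(clus@clusters)) {
      mask <- do.call(rbind, lapply(seq_along(clus@clusters), function(i)
        data.frame(cluster = i,
                   channel = erp$channels[clus@clusters[[i]]$members[, "channel"]],
                   time = erp$times[clus@clusters[[i]]$members[, "time"]])))
      write.csv(mask, file.path(outputDir, "cluster_mask.csv"),
                row.names = FALSE)
    }
    .logLine(logCon, sprintf("permtest: %d cluster(s), min p %s",
                             length(clus@clusters),
                             if (length(clus@pValues))
                               format(min(clus@pValues)) else "-"))
    artifacts$permtest <- "cluster_result.json"

    stage <- "anova"
    electrodes <- cfg$anovaElectrodes
    if (is.null(electrodes))
      electrodes <- .defaultAnovaElectrodes(epochs, cfg$anovaWindow)
    an <- conventionalAnalysis(epochs, electrodes, cfg$anovaWindow)
    .writeJSON(list(F = an$F, dfNum = an$dfNum, dfDen = an$dfDen,
                    p = an$p, etaSq = an$etaSq,
                    electrodes = an$electrodes, window = an$window,
                    pairwise = an$pairwise),
               file.path(outputDir, "anova.json"))
    .logLine(logCon, sprintf("anova: F(%d,%d)=%.2f p=%.4g",
                             an$dfNum, an$dfDen, an$F, an$p))
    artifacts$anova <- "anova.json"

    stage <- "compare"
    sherpaSets <- lapply(rep_, function(cls) {
      if (length(cls$windows))
        cls$windows[[1L]]$quantileSets[[1L]] else character(0)
    })
    sigIdx <- which(clus@pValues <= cfg$perm$testAlpha)
    clusterChannels <- unique(unlist(lapply(clus@clusters[sigIdx],
                                            `[[`, "channels")))
    comparison <- list(
      sherpaTopWindowElectrodes = sherpaSets,
      significantClusterChannels = clusterChannels,
      nSignificantClusters = length(sigIdx),
      conventionalElectrodes = an$electrodes,
      overlapSherpaCluster = lapply(sherpaSets, function(s)
        intersect(s, clusterChannels)))
    .writeJSON(comparison, file.path(outputDir, "comparison.json"))
    artifacts$comparison <- "comparison.json"

    stage <- "provenance"
    cfgJson <- jsonlite::serializeJSON(cfg[setdiff(names(cfg), "layout")])
    .writeJSON(list(seed = seed, configHash = .cheapHash(cfgJson),
                    artifacts = artifacts,
                    package = as.character(utils::packageVersion("sherpa"))),
               file.path(outputDir, "provenance.json"))
    .logLine(logCon, "done")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(outputDir)
}

#' Export figure-ready data from a completed run directory
#'
#' Emits, under `<runDir>/figure_data/`: the importance contour matrix,
#' the per-class importance curves, a topography value table per SHERPA
#' window, and the grand-average ERP traces of each quantile electrode
#' set.  Deterministic: repeated calls produce byte-identical files.
#'
#' @param runDir a directory produced by [runPipeline()].
#' @return the figure-data directory, invisibly.
#' @export
exportFigureData <- function(runDir) {
  need <- c("epochs", "importance_matrix.csv", "importance_curves.csv",
            "sherpa_report.json")
  for (f in need)
    if (!file.exists(file.path(runDir, f)))
      stop(sprintf("missing upstream artifact '%s' in %s", f, runDir))
  figDir <- file.path(runDir, "figure_data")
  dir.create(figDir, showWarnings = FALSE)
  file.copy(file.path(runDir, "importance_matrix.csv"),
            file.path(figDir, "contour_matrix.csv"), overwrite = TRUE)
  file.copy(file.path(runDir, "importance_curves.csv"),
            file.path(figDir, "class_curves.csv"), overwrite = TRUE)
  rep_ <- jsonlite::read_json(file.path(runDir, "sherpa_report.json"),
                              simplifyVector = TRUE)
  epochs <- readEpochs(file.path(runDir, "epochs"))
  ga <- vapply(conditionNames(epochs), function(cond) {
    idx <- which(epochLabels(epochs) == cond)
    colMeans(epochData(epochs)[idx, , , drop = FALSE], dims = 1L)
  }, matrix(0, nChannels(epochs), nTimes(epochs)))
  for (cls in names(rep_)) {
    wins <- rep_[[cls]]$windows
    if (!length(wins)) next
    w <- if (is.data.frame(wins)) as.list(wins[1L, ]) else wins[[1L]]
    topo <- data.frame(channel = names(unlist(w$scores)),
                       score = unname(unlist(w$scores)))
    write.csv(topo, file.path(figDir, sprintf("topography_%s.csv", cls)),
              row.names = FALSE)
    for (qn in names(w$quantileSets)) {
      chs <- unlist(w$quantileSets[[qn]])
      chIdx <- match(chs, channelNames(epochs))
      tr <- do.call(rbind, lapply(conditionNames(epochs), function(cond)
        data.frame(condition = cond, time = epochTimes(epochs),
                   amplitude = colMeans(matrix(ga[chIdx, , cond],
                                               length(chIdx))))))
      write.csv(tr, file.path(figDir,
                              sprintf("erp_%s_%s.csv", cls, qn)),
                row.names = FALSE)
    }
  }
  invisible(figDir)
}
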