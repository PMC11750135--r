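#' Pipeline configuration
#'
#' Bundles the tunable settings of the end-to-end analysis with the
#' conventional defaults: 10 EM restarts, a state-number grid of 2..10,
#' 1000 transition-surrogate permutations, 5000 modulation permutations,
#' and a Louvain resolution sweep from 1.2 to 2.5 in steps of 0.01.
#' Desk-scale analyses override these downward. Every stage derives its
#' random stream from the master seed.
#'
#' @param manifest optional path to a cohort manifest (see
#'   [loadCohort()]); `NULL` to pass a cohort in memory.
#' @param kGrid candidate numbers of states.
#' @param nRestarts EM restarts.
#' @param nPermTransition transition-surrogate permutations.
#' @param nPermModulation modulation permutations.
#' @param gammaGrid Louvain resolution sweep.
#' @param louvainRuns Louvain runs per resolution.
#' @param kNeighbors KNN neighbourhood for narrative decoding.
#' @param fineK number of states of the finer model used for metastate
#'   reconstruction; `NULL` skips the stage.
#' @param tr repetition time, seconds.
#' @param hubState,peripheralStates state roles for the hub summary.
#' @param seed master seed.
#' @return a list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(manifest = NULL, kGrid = 2:10, nRestarts = 10L,
                           nPermTransition = 1000L, nPermModulation = 5000L,
                           gammaGrid = seq(1.2, 2.5, by = 0.01),
                           louvainRuns = 1000L, kNeighbors = 5L,
                           fineK = 10L, tr = 2,
                           hubState = 2L, peripheralStates = c(1L, 3L),
                           seed = 1L) {
  structure(list(manifest = manifest, kGrid = as.integer(kGrid),
                 nRestarts = as.integer(nRestarts),
                 nPermTransition = as.integer(nPermTransition),
                 nPermModulation = as.integer(nPermModulation),
                 gammaGrid = gammaGrid, louvainRuns = as.integer(louvainRuns),
                 kNeighbors = as.integer(kNeighbors),
                 fineK = if (is.null(fineK)) NULL else as.integer(fineK),
                 tr = tr,
                 hubState = as.integer(hubState),
                 peripheralStates = as.integer(peripheralStates),
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipelineConfig()].
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  do.call(pipelineConfig, y[intersect(names(y), known)])
}

#' Run the full latent-state analysis pipeline
#'
#' Composes the stages in order: state-number selection (skipped for a
#' single-valued grid), full-cohort HMM fit, per-subject decoding, state
#' dynamics with the transition-hub surrogate null, per-state network
#' topology, stimulus modulation (when regressors are available) and
#' behaviour (when scores are available). Returns a nested list that
#' serializes directly to a JSON report.
#'
#' @param config a `pipelineConfig` from [pipelineConfig()].
#' @param cohort optional [SimulatedCohort-class] or the list returned by
#'   [loadCohort()]; loaded from `config$manifest` when omitted.
#' @param out optional path; when given, the report is written there as
#'   JSON.
#' @return the report list, invisibly when `out` is given.
#' @export
runPipeline <- function(config, cohort = NULL, out = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.null(cohort)) {
    if (is.null(config$manifest)) stop("no cohort and no manifest path")
    cohort <- loadCohort(config$manifest)
  }
  if (is(cohort, "SimulatedCohort")) {
    seriesList <- cohort@series
    conditions <- vapply(cohort@series, function(s) s@condition, "")
    narratives <- cohort@narrativeLabels
    scores <- cohort@scores
    fdTraces <- cohort@fdTraces
    regressors <- if (length(cohort@regressors)) cohort@regressors[[1]]
                  else NULL
  } else {
    seriesList <- cohort$series
    conditions <- if (!is.null(cohort$conditions)) cohort$conditions
                  else vapply(cohort$series, function(s) s@condition, "")
    narratives <- cohort$narrativeLabels
    scores <- cohort$scores
    fdTraces <- cohort$fdTraces
    regressors <- if (length(cohort$regressors)) cohort$regressors[[1]]
                  else NULL
  }
  seed <- config$seed
  report <- list(schema = "brainstates-report/1",
                 nSubjects = length(seriesList),
                 nTimepoints = nrow(seriesList[[1]]@data),
                 nNetworks = ncol(seriesList[[1]]@data),
                 seed = seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  if (length(config$kGrid) > 1L) {
    sel <- stage("select-k",
      selectNumStates(seriesList, narratives, kGrid = config$kGrid,
                      nRestarts = config$nRestarts,
                      kNeighbors = config$kNeighbors,
                      seed = childSeed(seed, "select")))
    kStar <- sel@kStar
    report$selection <- list(kGrid = sel@kGrid, chScores = sel@chScores,
                             decodeAccuracy = sel@decodeAccuracy,
                             zSum = sel@zSum, kStar = kStar)
  } else {
    kStar <- config$kGrid[1]
    report$selection <- list(kGrid = kStar, kStar = kStar, skipped = TRUE)
  }

  model <- stage("fit",
    fitHMM(seriesList, kStar, nRestarts = config$nRestarts,
           seed = childSeed(seed, "fit")))
  posteriors <- stage("decode",
    lapply(seriesList, posteriorProbs, model = model))
  report$model <- list(k = kStar, means = model@means,
                       transition = model@transition,
                       initial = model@initial,
                       evidence = model@evidence,
                       converged = model@converged)

  hub <- min(config$hubState, kStar)
  per <- config$peripheralStates[config$peripheralStates <= kStar]
  dyn <- stage("dynamics", {
    ds <- dynamicsSummary(posteriors, model, tr = config$tr,
                          hub = hub,
                          peripheral = if (length(per) == 2L) per
                                       else head(setdiff(seq_len(kStar), hub), 2L))
    sn <- transitionSurrogateNull(seriesList, kStar,
                                  nPerm = config$nPermTransition,
                                  nRestarts = config$nRestarts,
                                  seed = childSeed(seed, "surrogate"),
                                  observedModel = model, tr = config$tr)
    list(summary = ds, surrogate = sn)
  })
  meanFO <- colMeans(dyn$summary$fo)
  meanDwell <- colMeans(dyn$summary$meanDwell, na.rm = TRUE)
  report$dynamics <- list(
    meanFO = meanFO,
    meanDwellS = meanDwell,
    hubAsym = as.list(dyn$summary$hubAsym),
    surrogate = list(observed = dyn$surrogate@observed,
                     empiricalP = dyn$surrogate@empiricalP,
                     rawProportion = dyn$surrogate@rawProportion,
                     nPerm = dyn$surrogate@nPerm,
                     hubFOPercentile = occupancySurrogatePercentile(
                       meanFO[hub], dyn$surrogate@foValues),
                     hubDwellPercentile = occupancySurrogatePercentile(
                       meanDwell[hub], dyn$surrogate@dwellValues)))

  topo <- stage("graph",
    tryCatch(stateTopologyContrast(seriesList, posteriors, model,
                                   seed = childSeed(seed, "topo")),
             error = function(e) NULL))
  if (!is.null(topo))
    report$topology <- list(
      meanGeff = colMeans(topo$geff, na.rm = TRUE),
      meanQ = colMeans(topo$q, na.rm = TRUE),
      tests = topo$tests, modelDerived = topo$modelDerived,
      nExcluded = length(topo$excluded))

  if (!is.null(config$fineK) && config$fineK > kStar) {
    meta <- stage("metastates", {
      fine <- fitHMM(seriesList, config$fineK, nRestarts = config$nRestarts,
                     seed = childSeed(seed, "fine"))
      cl <- clusterTransitions(transitionMatrix(fine), kStar)
      finePaths <- lapply(seriesList, function(s)
        statePath(posteriorProbs(s, fine)))
      mg <- mergeClusterStates(fine, cl, finePaths)
      mm <- spatialMatch(mg$means, model@means)
      mapped <- lapply(mg$paths, function(p) mm@mapping[p])
      mainPaths <- lapply(posteriors, statePath)
      ov <- temporalJaccard(unlist(mapped), unlist(mainPaths), k = kStar)
      list(clusters = cl, mapping = mm@mapping, primed = mm@primed,
           spatialR = mm@similarity, jaccardPerState = ov$perState,
           overlap = ov$overall)
    })
    report$metastates <- meta
  }

  if (length(unique(conditions)) > 1L) {
    match <- stage("match", {
      ref <- if ("task" %in% conditions) "task" else conditions[1]
      out <- list()
      for (cond in setdiff(unique(conditions), ref)) {
        idx <- which(conditions == cond)
        mc <- fitHMM(seriesList[idx], kStar, nRestarts = config$nRestarts,
                     seed = childSeed(seed, "cond", cond))
        mm <- spatialMatch(mc@means, model@means)
        out[[cond]] <- list(mapping = mm@mapping, primed = mm@primed,
                            similarity = mm@similarity,
                            hubStat = hubStatistic(mc@transition))
      }
      out
    })
    report$conditionMatch <- match
  }

  if (!is.null(regressors)) {
    allRegs <- if (is(cohort, "SimulatedCohort")) cohort@regressors
               else cohort$regressors
    features <- names(allRegs[[1]])
    # one regressor per subject: each subject's own narrative's feature
    perSubject <- lapply(features, function(f)
      lapply(narratives, function(m) allRegs[[m]][[f]]))
    names(perSubject) <- features
    mods <- stage("modulate",
      modulationScan(perSubject, lapply(posteriors, slot, "gamma"),
                     nPerm = config$nPermModulation,
                     seed = childSeed(seed, "mod")))
    report$modulation <- mods
  }

  if (length(scores) && !all(is.na(scores))) {
    beh <- stage("behavior", {
      gam <- lapply(posteriors, slot, "gamma")
      perState <- lapply(seq_len(kStar), function(s) {
        ab <- alignmentToBest(gam, scores, narratives, s)
        bc <- behaviorCorrelation(ab$alignment, scores[!ab$isBest])
        grp <- alignmentToGroup(gam, s, narratives)
        gc <- behaviorCorrelation(grp, scores)
        res <- list(bestR = bc$r, bestP = bc$p, groupR = gc$r, groupP = gc$p)
        if (length(fdTraces)) {
          fdAb <- fdAlignmentToBest(fdTraces, scores, narratives)
          pc <- behaviorCorrelation(ab$alignment, scores[!ab$isBest],
                                    covariate = fdAb$alignment)
          res$partialR <- pc$partialR
          res$partialP <- pc$partialP
        }
        res
      })
      names(perState) <- sprintf("state%d", seq_len(kStar))
      perState
    })
    report$behavior <- beh
  }

  if (!is.null(out)) {
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}
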