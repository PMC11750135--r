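#' @include AllClasses.R
NULL

#' Accessors for brainstates objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a brainstates S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("stateMeans", function(object) standardGeneric("stateMeans"))
#' @rdname accessors
#' @export
setGeneric("stateCovs", function(object) standardGeneric("stateCovs"))
#' @rdname accessors
#' @export
setGeneric("transitionMatrix",
           function(object) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("initialDistribution",
           function(object) standardGeneric("initialDistribution"))
#' @rdname accessors
#' @export
setGeneric("modelEvidence", function(object) standardGeneric("modelEvidence"))
#' @rdname accessors
#' @export
setGeneric("expressionProbs",
           function(object) standardGeneric("expressionProbs"))
#' @rdname accessors
#' @export
setGeneric("statePath", function(object) standardGeneric("statePath"))
#' @rdname accessors
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("cohortSeries", function(object) standardGeneric("cohortSeries"))
#' @rdname accessors
#' @export
setGeneric("truePaths", function(object) standardGeneric("truePaths"))
#' @rdname accessors
#' @export
setGeneric("narrativeLabels",
           function(object) standardGeneric("narrativeLabels"))
#' @rdname accessors
#' @export
setGeneric("comprehensionScores",
           function(object) standardGeneric("comprehensionScores"))
#' @rdname accessors
#' @export
setGeneric("regressorValues",
           function(object) standardGeneric("regressorValues"))

setMethod("nStates", "GaussianHMM", function(object) object@k)
setMethod("stateMeans", "GaussianHMM", function(object) object@means)
setMethod("stateCovs", "GaussianHMM", function(object) object@covs)
setMethod("transitionMatrix", "GaussianHMM",
          function(object) object@transition)
setMethod("initialDistribution", "GaussianHMM",
          function(object) object@initial)
setMethod("modelEvidence", "GaussianHMM", function(object) object@evidence)
setMethod("stateMeans", "GroundTruthConfig", function(object) object@stateMeans)
setMethod("stateCovs", "GroundTruthConfig", function(object) object@stateCovs)
setMethod("transitionMatrix", "GroundTruthConfig",
          function(object) object@baseTransition)
setMethod("nStates", "GroundTruthConfig", function(object) object@kTrue)
setMethod("expressionProbs", "StatePosterior", function(object) object@gamma)
setMethod("statePath", "StatePosterior", function(object) object@path)
setMethod("seriesData", "NetworkTimeSeries", function(object) object@data)
setMethod("subjectId", "NetworkTimeSeries", function(object) object@subjectId)
setMethod("trSeconds", "NetworkTimeSeries", function(object) object@tr)
setMethod("cohortSeries", "SimulatedCohort", function(object) object@series)
setMethod("truePaths", "SimulatedCohort", function(object) object@truePaths)
setMethod("narrativeLabels", "SimulatedCohort",
          function(object) object@narrativeLabels)
setMethod("comprehensionScores", "SimulatedCohort",
          function(object) object@scores)
setMethod("regressorValues", "StimulusRegressor",
          function(object) object@values)

setMethod("show", "NetworkTimeSeries", function(object) {
  cat(sprintf("NetworkTimeSeries '%s': %d time points x %d networks (TR %g s)\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@tr))
  cat(sprintf("  narrative: %s | condition: %s\n", object@narrative,
              object@condition))
})

setMethod("show", "GaussianHMM", function(object) {
  cat(sprintf("GaussianHMM with %d states over %d networks\n", object@k,
              ncol(object@means)))
  cat(sprintf("  evidence (log-likelihood): %.2f | restarts: %d | converged: %s\n",
              object@evidence, object@nRestarts, object@converged))
  cat("  transition matrix:\n")
  print(round(object@transition, 3))
})

setMethod("show", "StatePosterior", function(object) {
  k <- ncol(object@gamma)
  fo <- tabulate(object@path, k) / length(object@path)
  cat(sprintf("StatePosterior: %d time points, %d states, loglik %.2f\n",
              nrow(object@gamma), k, object@loglik))
  cat("  Viterbi fractional occupancy:", paste(sprintf("%.3f", fo),
      collapse = " "), "\n")
})

setMethod("show", "SimulatedCohort", function(object) {
  n <- length(object@series)
  Tn <- if (n) nrow(object@series[[1]]@data) else 0L
  N <- if (n) ncol(object@series[[1]]@data) else 0L
  cat(sprintf("SimulatedCohort: %d subjects x %d time points x %d networks\n",
              n, Tn, N))
  cat(sprintf("  narratives: %s | behaviour simulated: %s\n",
              paste(unique(object@narrativeLabels), collapse = ", "),
              if (length(object@scores)) "yes" else "no"))
})

setMethod("show", "KSelectionResult", function(object) {
  cat("Dual-criterion selection of the number of states\n")
  print(data.frame(k = object@kGrid, CH = round(object@chScores, 2),
                   acc = round(object@decodeAccuracy, 3),
                   zSum = round(object@zSum, 3)))
  cat(sprintf("  selected k* = %d\n", object@kStar))
})

setMethod("show", "SurrogateNull", function(object) {
  cat(sprintf("SurrogateNull: observed %.4f vs %d permutations\n",
              object@observed, object@nPerm))
  cat(sprintf("  empirical p (add-one): %.4f | proportion >= observed: %.4f\n",
              object@empiricalP, object@rawProportion))
})

setMethod("show", "StateCorrespondence", function(object) {
  lab <- paste0("#", object@mapping, ifelse(object@primed, "'", ""))
  cat(sprintf("StateCorrespondence (%s basis)\n", object@basis))
  for (i in seq_along(object@mapping))
    cat(sprintf("  candidate %d -> state %s (r = %.3f)\n", i, lab[i],
                object@similarity[i]))
})
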