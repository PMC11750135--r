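#' @import methods
NULL

#' One subject's network-level BOLD time series
#'
#' Holds a T x N matrix of network time courses sampled every `tr` seconds,
#' together with the subject identifier and the narrative/condition labels
#' used downstream for decoding and cross-condition comparisons.
#'
#' @slot subjectId character scalar.
#' @slot data numeric T x N matrix (z-units after [standardizeSeries()]).
#' @slot tr sampling interval in seconds.
#' @slot narrative narrative label.
#' @slot condition one of `"task"`, `"rest"`, `"unintelligible"`.
#' @export
setClass("NetworkTimeSeries",
  representation(subjectId = "character", data = "matrix", tr = "numeric",
                 narrative = "character", condition = "character"),
  prototype(subjectId = "s1", tr = 2, narrative = "n1", condition = "task"))

setValidity("NetworkTimeSeries", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be a numeric matrix")
  if (nrow(d) < 2L) return("need at least 2 time points")
  if (anyNA(d) || any(!is.finite(d))) return("data contains missing/non-finite values")
  if (length(object@tr) != 1L || object@tr <= 0) return("tr must be a positive scalar")
  if (!object@condition %in% c("task", "rest", "unintelligible"))
    return("condition must be task, rest or unintelligible")
  TRUE
})

#' Multivariate-Gaussian-emission hidden Markov model
#'
#' @slot k number of latent states.
#' @slot means k x N matrix of per-state network activity loadings (z-units).
#' @slot covs N x N x k array of per-state covariance matrices.
#' @slot transition k x k row-stochastic between-state transition matrix.
#' @slot initial length-k initial state distribution.
#' @slot evidence training log-likelihood of the selected restart, used to
#'   pick the best of the random restarts.
#' @slot loglikTrace per-iteration log-likelihood of the winning restart.
#' @slot converged logical convergence flag.
#' @slot nRestarts number of random restarts performed.
#' @slot seed integer seed the fit was derived from.
#' @slot networks column (network) names.
#' @export
setClass("GaussianHMM",
  representation(k = "integer", means = "matrix", covs = "array",
                 transition = "matrix", initial = "numeric",
                 evidence = "numeric", loglikTrace = "numeric",
                 converged = "logical", nRestarts = "integer",
                 seed = "integer", networks = "character"))

setValidity("GaussianHMM", function(object) {
  k <- object@k
  if (nrow(object@means) != k) return("means must have k rows")
  if (!all(abs(rowSums(object@transition) - 1) < 1e-10))
    return("transition rows must sum to 1")
  if (abs(sum(object@initial) - 1) > 1e-10)
    return("initial distribution must sum to 1")
  if (any(object@transition < -1e-12) || any(object@initial < -1e-12))
    return("probabilities must be nonnegative")
  if (dim(object@covs)[3] != k) return("covs must stack k matrices")
  TRUE
})

#' Posterior state expression for one subject
#'
#' @slot gamma T x k matrix of state expression probabilities
#'   (forward-backward posteriors); rows sum to one.
#' @slot path length-T Viterbi state sequence (1-based labels).
#' @slot loglik data log-likelihood under the model.
#' @export
setClass("StatePosterior",
  representation(gamma = "matrix", path = "integer", loglik = "numeric"))

setValidity("StatePosterior", function(object) {
  if (!all(abs(rowSums(object@gamma) - 1) < 1e-10))
    return("gamma rows must sum to 1")
  k <- ncol(object@gamma)
  if (length(object@path) != nrow(object@gamma))
    return("path length must match gamma rows")
  if (any(object@path < 1L | object@path > k))
    return("path labels must lie in 1..k")
  TRUE
})

#' Ground-truth configuration for the synthetic cohort generator
#'
#' Describes the generative model: a k-state Gaussian HMM with a
#' hub-structured base transition matrix, narrative-specific smooth drive
#' signals that tilt the transition kernel (creating within-narrative
#' inter-subject correlation), stimulus regressors coupled to specific
#' states, and a behavioural model linking comprehension scores to each
#' subject's alignment with their narrative group.
#'
#' @slot nSubjects,nNetworks,nTimepoints cohort geometry.
#' @slot tr sampling interval, seconds.
#' @slot kTrue number of generating states.
#' @slot stateMeans kTrue x nNetworks matrix (z-units).
#' @slot stateCovs nNetworks x nNetworks x kTrue SPD array.
#' @slot baseTransition kTrue x kTrue row-stochastic matrix.
#' @slot nNarratives number of narrative groups.
#' @slot couplingStrength nFeatures x kTrue nonnegative matrix of log-odds
#'   tilts linking each stimulus feature to each state.
#' @slot narrativeDriveStrength nonnegative log-odds scale of the shared
#'   narrative drive.
#' @slot behaviorGain slope linking alignment to the comprehension score
#'   on the logit scale.
#' @slot behaviorNoiseSd noise sd of the score model (logit scale).
#' @slot fdBase,fdNoiseSd framewise-displacement level (mm) and noise sd.
#' @slot fdEngagementWeight mm decrease in FD per unit engagement.
#' @slot seed master seed.
#' @slot networks network names.
#' @slot features stimulus feature names.
#' @export
setClass("GroundTruthConfig",
  representation(nSubjects = "integer", nNetworks = "integer",
                 nTimepoints = "integer", tr = "numeric", kTrue = "integer",
                 stateMeans = "matrix", stateCovs = "array",
                 baseTransition = "matrix", nNarratives = "integer",
                 couplingStrength = "matrix",
                 narrativeDriveStrength = "numeric",
                 behaviorGain = "numeric", behaviorNoiseSd = "numeric",
                 fdBase = "numeric", fdNoiseSd = "numeric",
                 fdEngagementWeight = "numeric", seed = "integer",
                 networks = "character", features = "character"))

setValidity("GroundTruthConfig", function(object) {
  if (!all(abs(rowSums(object@baseTransition) - 1) < 1e-12))
    return("baseTransition rows must sum to 1")
  for (j in seq_len(object@kTrue)) {
    S <- object@stateCovs[, , j]
    if (max(abs(S - t(S))) > 1e-10) return("stateCovs must be symmetric")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      return("stateCovs must be positive definite")
  }
  if (any(object@couplingStrength < 0) || object@narrativeDriveStrength < 0)
    return("coupling and drive strengths must be nonnegative")
  if (nrow(object@stateMeans) != object@kTrue)
    return("stateMeans must have kTrue rows")
  TRUE
})

#' A simulated cohort with its generative ground truth
#'
#' @slot series list of [NetworkTimeSeries-class] objects.
#' @slot truePaths list of integer ground-truth state sequences.
#' @slot narrativeLabels per-subject narrative label.
#' @slot regressors per-narrative named list of
#'   [StimulusRegressor-class] objects.
#' @slot scores per-subject comprehension score (0-100); empty until
#'   [simulateBehavior()] is run.
#' @slot alignment per-subject ground-truth alignment of the hub-state
#'   indicator with the narrative-group mean.
#' @slot fdTraces list of per-subject framewise-displacement traces (mm).
#' @slot truth the generating [GroundTruthConfig-class].
#' @export
setClass("SimulatedCohort",
  representation(series = "list", truePaths = "list",
                 narrativeLabels = "character", regressors = "list",
                 scores = "numeric", alignment = "numeric",
                 fdTraces = "list", truth = "GroundTruthConfig"))

setValidity("SimulatedCohort", function(object) {
  Ts <- vapply(object@series, function(s) nrow(s@data), 1L)
  Ns <- vapply(object@series, function(s) ncol(s@data), 1L)
  if (length(unique(Ts)) > 1L || length(unique(Ns)) > 1L)
    return("all series must share T and N")
  if (length(object@truePaths) != length(object@series))
    return("one true path per subject required")
  TRUE
})

#' A stimulus feature time course on the TR grid
#'
#' @slot name feature name (`envelope`, `word_coherence`,
#'   `clause_coherence` or custom).
#' @slot values length-T numeric values on the TR grid.
#' @slot nativeRate sampling rate (Hz) of the source signal.
#' @slot tr TR of the target grid, seconds.
#' @slot hrfApplied whether the values are HRF-convolved.
#' @export
setClass("StimulusRegressor",
  representation(name = "character", values = "numeric",
                 nativeRate = "numeric", tr = "numeric",
                 hrfApplied = "logical"),
  prototype(name = "custom", nativeRate = 0.5, tr = 2, hrfApplied = FALSE))

setValidity("StimulusRegressor", function(object) {
  if (anyNA(object@values) || any(!is.finite(object@values)))
    return("regressor values must be finite")
  TRUE
})

#' Result of dual-criterion selection of the number of states
#'
#' @slot kGrid candidate numbers of states.
#' @slot chScores mean per-subject Calinski-Harabasz score per k.
#' @slot decodeAccuracy narrative classification accuracy per k.
#' @slot zCh,zAcc,zSum z-scored criteria across the grid and their sum.
#' @slot kStar selected number of states (argmax of zSum, ties toward the
#'   smallest k).
#' @export
setClass("KSelectionResult",
  representation(kGrid = "integer", chScores = "numeric",
                 decodeAccuracy = "numeric", zCh = "numeric",
                 zAcc = "numeric", zSum = "numeric", kStar = "integer"))

#' A surrogate null distribution with its empirical p-value
#'
#' @slot nPerm number of surrogate permutations.
#' @slot values null statistic per permutation.
#' @slot observed observed statistic.
#' @slot empiricalP add-one empirical p,
#'   `(1 + #(null >= observed)) / (1 + nPerm)`.
#' @slot rawProportion plain proportion of null values >= observed.
#' @slot foValues,dwellValues per-permutation maxima over states of the
#'   surrogate group-mean fractional occupancy and mean dwell time
#'   (seconds), for occupancy percentile comparisons.
#' @slot nRedrawn permutations re-drawn after a fit failure.
#' @slot seed integer seed.
#' @export
setClass("SurrogateNull",
  representation(nPerm = "integer", values = "numeric", observed = "numeric",
                 empiricalP = "numeric", rawProportion = "numeric",
                 foValues = "numeric", dwellValues = "numeric",
                 nRedrawn = "integer", seed = "integer"),
  prototype(foValues = numeric(0), dwellValues = numeric(0)))

setValidity("SurrogateNull", function(object) {
  if (object@empiricalP <= 0 || object@empiricalP > 1)
    return("empiricalP must lie in (0, 1]")
  TRUE
})

#' Correspondence between candidate and predefined states
#'
#' Records, for each candidate state, the predefined state it was assigned
#' to under the greedy confusion-resolving rule, the matched similarity,
#' and whether the assignment was "primed" (the candidate did not receive
#' its own top-correlated predefined state because a stronger candidate
#' claimed it).
#'
#' @slot mapping integer vector: `mapping[i]` is the predefined state
#'   assigned to candidate state `i`.
#' @slot similarity Pearson correlation of each matched pair.
#' @slot primed logical; `TRUE` where confusion occurred.
#' @slot basis `"spatial"` (activity patterns) or `"temporal"`
#'   (expression time courses).
#' @export
setClass("StateCorrespondence",
  representation(mapping = "integer", similarity = "numeric",
                 primed = "logical", basis = "character"))

setValidity("StateCorrespondence", function(object) {
  if (anyDuplicated(object@mapping)) return("mapping must be one-to-one")
  TRUE
})

#' A community partition from the resolution sweep
#'
#' @slot labels community id per node (contiguous from 1).
#' @slot gamma Louvain resolution parameter.
#' @slot q modularity of the representative partition.
#' @slot zrandMean mean pairwise z-Rand score across runs.
#' @slot weightedScore `q * zrandMean`, the modularity-weighted z-Rand.
#' @export
setClass("BrainPartition",
  representation(labels = "integer", gamma = "numeric", q = "numeric",
                 zrandMean = "numeric", weightedScore = "numeric"))
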