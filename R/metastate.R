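#' Cluster HMM states from their transition profiles
#'
#' Agglomerative hierarchical clustering (average linkage) of the states
#' of a finer HMM into metastates. The pairwise similarity combines two
#' signals, both computed on the transition matrix with self-transitions
#' excluded: (i) the correlation between the two states' transition
#' profiles (outgoing row plus incoming column), computed over the
#' positions that refer to neither state of the pair — deleting the pair's
#' own positions avoids the artefact that two states exchanging mass
#' anti-correlate because each peaks where the other is zeroed; and
#' (ii) their direct mutual transition mass, normalized by the largest
#' mutual mass in the matrix. On block-dominant transition matrices the
#' resulting clusters satisfy the metastate property: within-cluster
#' transition mass exceeds between-cluster mass.
#'
#' @param transition k x k row-stochastic transition matrix.
#' @param nClusters number of metastates (must be < k).
#' @return integer cluster label per state.
#' @export
clusterTransitions <- function(transition, nClusters = 3L) {
  k <- nrow(transition)
  if (nClusters >= k)
    stop("nClusters must be smaller than the number of states")
  A0 <- transition
  diag(A0) <- 0  # self-transitions carry no grouping information
  sym <- (A0 + t(A0)) / 2
  maxMass <- max(sym)
  S <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    keep <- setdiff(seq_len(k), c(i, j))
    x <- c(A0[i, keep], A0[keep, i])
    y <- c(A0[j, keep], A0[keep, j])
    pc <- if (sd(x) < 1e-12 || sd(y) < 1e-12) 0 else cor(x, y)
    mass <- if (maxMass > 0) sym[i, j] / maxMass else 0
    S[i, j] <- S[j, i] <- (pc + 1) / 4 + mass / 2
  }
  hc <- hclust(as.dist(1 - S), method = "average")
  cutree(hc, k = nClusters)
}

#' Merge clustered states into metastates
#'
#' Each metastate's activity pattern is the unweighted average of its
#' member states' mean vectors, and every decoded path label is replaced
#' by its cluster id.
#'
#' @param model a [GaussianHMM-class] or a k x N matrix of state means.
#' @param clusters integer cluster label per state (from
#'   [clusterTransitions()]).
#' @param paths list of integer state paths in the finer labels (optional).
#' @return list with `means` (nClusters x N) and `paths` (relabelled, or
#'   `NULL` when no paths given).
#' @export
mergeClusterStates <- function(model, clusters, paths = NULL) {
  means <- if (is(model, "GaussianHMM")) model@means else model
  clusters <- as.integer(clusters)
  ids <- sort(unique(clusters))
  if (!all(seq_len(max(clusters)) %in% ids))
    stop("empty cluster: labels must be contiguous")
  merged <- t(vapply(ids, function(cid)
    colMeans(means[clusters == cid, , drop = FALSE]), numeric(ncol(means))))
  rownames(merged) <- NULL
  newPaths <- if (is.null(paths)) NULL
    else lapply(paths, function(p) clusters[p])
  list(means = merged, paths = newPaths)
}

#' Match candidate states to predefined states
#'
#' Assigns each candidate state to the predefined state whose pattern it
#' most closely resembles (Pearson correlation), resolving confusions
#' greedily: when two candidates share a top match, the stronger keeps it
#' and the weaker takes its best still-unassigned predefined state and is
#' marked "primed". Assignment proceeds in descending order of match
#' strength over the remaining states.
#'
#' @param candidates k x D matrix of candidate state vectors (activity
#'   patterns for spatial matching, concatenated expression time courses
#'   for temporal matching).
#' @param predefined k x D matrix of predefined state vectors.
#' @param basis `"spatial"` or `"temporal"` (annotation only).
#' @return a [StateCorrespondence-class].
#' @export
spatialMatch <- function(candidates, predefined, basis = "spatial") {
  if (nrow(candidates) != nrow(predefined))
    stop("candidate and predefined state counts differ")
  if (ncol(candidates) != ncol(predefined))
    stop("candidate and predefined vector lengths differ")
  k <- nrow(candidates)
  S <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    S[i, j] <- if (sd(candidates[i, ]) < 1e-12 ||
                   sd(predefined[j, ]) < 1e-12) 0
               else cor(candidates[i, ], predefined[j, ])
  topChoice <- apply(S, 1L, which.max)
  mapping <- integer(k); similarity <- numeric(k)
  assignedCand <- logical(k); takenPre <- logical(k)
  while (!all(assignedCand)) {
    Savail <- S
    Savail[assignedCand, ] <- -Inf
    Savail[, takenPre] <- -Inf
    idx <- which(Savail == max(Savail), arr.ind = TRUE)[1L, ]
    i <- idx[1]; j <- idx[2]
    mapping[i] <- j
    similarity[i] <- S[i, j]
    assignedCand[i] <- TRUE
    takenPre[j] <- TRUE
  }
  new("StateCorrespondence", mapping = mapping, similarity = similarity,
      primed = mapping != topChoice, basis = basis)
}

#' Match states by expression time courses
#'
#' Temporal-basis variant of [spatialMatch()]: candidate and predefined
#' states are represented by their expression probability time courses
#' concatenated across subjects, useful when spatial patterns are not
#' comparable (e.g. across parcellation schemes).
#'
#' @param candidateGammas,predefinedGammas lists of T x k gamma matrices
#'   (one per subject, same subject order).
#' @return a [StateCorrespondence-class] with basis `"temporal"`.
#' @export
temporalMatch <- function(candidateGammas, predefinedGammas) {
  candMat <- t(do.call(rbind, candidateGammas))
  preMat <- t(do.call(rbind, predefinedGammas))
  spatialMatch(candMat, preMat, basis = "temporal")
}

#' Jaccard similarity between two state sequences
#'
#' Per-state Jaccard index (intersection over union of the time points
#' each sequence assigns to the state) and the overall fraction of time
#' points on which the two sequences agree.
#'
#' @param seqA,seqB integer state sequences of equal length.
#' @param k number of states (default: max label observed).
#' @return list with `perState` (length-k) and `overall`.
#' @export
#' @examples
#' temporalJaccard(c(1, 1, 2, 3), c(1, 2, 2, 3))
temporalJaccard <- function(seqA, seqB, k = max(c(seqA, seqB))) {
  if (length(seqA) != length(seqB)) stop("sequences must have equal length")
  per <- vapply(seq_len(k), function(s) {
    a <- seqA == s; b <- seqB == s
    u <- sum(a | b)
    if (u == 0) NA_real_ else sum(a & b) / u
  }, 0)
  list(perState = per, overall = mean(seqA == seqB))
}

#' Null distribution for state correspondence
#'
#' Refits the HMM on circular-shift surrogate cohorts and applies the same
#' greedy matching against the predefined states, collecting the matched
#' similarities as a null distribution for judging observed
#' correspondences.
#'
#' @param seriesList list of [NetworkTimeSeries-class] or a
#'   [SimulatedCohort-class].
#' @param predefined k x N matrix of predefined state means (or a
#'   [GaussianHMM-class]).
#' @param k number of states.
#' @param nPerm number of permutations (at least 1).
#' @param nRestarts EM restarts per surrogate fit.
#' @param seed integer seed.
#' @return list with `values` (all matched similarities, length k * nPerm),
#'   `percentile` (function mapping an observed similarity to its null
#'   percentile) and `nFailed` (failed fits, logged and skipped).
#' @export
correspondenceNull <- function(seriesList, predefined, k = 3L,
                               nPerm = 1000L, nRestarts = 3L, seed = 1L) {
  if (is(seriesList, "SimulatedCohort")) seriesList <- seriesList@series
  if (nPerm < 1L) stop("at least one permutation required")
  if (is(predefined, "GaussianHMM")) predefined <- predefined@means
  Tn <- nrow(seriesList[[1]]@data)
  values <- numeric(0)
  nFailed <- 0L
  for (p in seq_len(nPerm)) {
    shifted <- withSeed(childSeed(seed, "cperm", p), {
      lapply(seriesList, function(s) {
        s@data <- circularShift(s@data,
                                sample.int(Tn - 1L, ncol(s@data),
                                           replace = TRUE))
        s
      })
    })
    fit <- tryCatch(
      fitHMM(shifted, k, nRestarts = nRestarts,
             seed = childSeed(seed, "cfit", p)),
      error = function(e) NULL)
    if (is.null(fit)) { nFailed <- nFailed + 1L; next }
    m <- spatialMatch(fit@means, predefined)
    values <- c(values, m@similarity)
  }
  list(values = values,
       percentile = function(obs) mean(values < obs),
       nFailed = nFailed)
}
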