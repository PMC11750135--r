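#' Leave-one-subject-out decoding of state expression
#'
#' For each subject, an HMM is trained on the remaining subjects (best of
#' `nRestarts` restarts by model evidence) and used to decode the left-out
#' subject's state expression probabilities and Viterbi path. Each fold's
#' state labels are aligned to a full-cohort reference model so decoded
#' sequences are comparable across folds.
#'
#' @param seriesList list of [NetworkTimeSeries-class] (at least 3).
#' @param k number of states.
#' @param nRestarts EM restarts per fold.
#' @param seed integer seed.
#' @param refModel optional [GaussianHMM-class] used as the label
#'   reference; fitted on the full cohort when `NULL`.
#' @param maxIter EM iteration cap per fit (default 100).
#' @return list of [StatePosterior-class], one per subject, in reference
#'   labels.
#' @export
losoDecode <- function(seriesList, k, nRestarts = 10L, seed = 1L,
                       refModel = NULL, maxIter = 100L) {
  if (is(seriesList, "SimulatedCohort")) seriesList <- seriesList@series
  n <- length(seriesList)
  if (n < 3L) stop("leave-one-subject-out decoding needs at least 3 subjects")
  if (is.null(refModel))
    refModel <- fitHMM(seriesList, k, nRestarts = nRestarts,
                       seed = childSeed(seed, "ref"), maxIter = maxIter)
  lapply(seq_len(n), function(i) {
    fold <- tryCatch(
      fitHMM(seriesList[-i], k, nRestarts = nRestarts,
             seed = childSeed(seed, "fold"), maxIter = maxIter),
      error = function(e) stop("fold ", i, ": ", conditionMessage(e)))
    fold <- relabelModel(fold, alignStateLabels(fold, refModel))
    posteriorProbs(seriesList[[i]], fold)
  })
}

#' Calinski-Harabasz score of a decoded state labelling
#'
#' Ratio of between-cluster to within-cluster dispersion of the T time
#' points in network space, grouped by state label and normalized by
#' degrees of freedom:
#' `CH = (B / (k - 1)) / (W / (T - k))`. Degenerate, perfectly separated
#' labellings (zero within-cluster dispersion) are reported as the capped
#' sentinel `1e12`.
#'
#' @param x T x N data matrix or a [NetworkTimeSeries-class].
#' @param labels length-T state labels (at least 2 distinct).
#' @return the CH score.
#' @export
calinskiHarabasz <- function(x, labels) {
  if (is(x, "NetworkTimeSeries")) x <- x@data
  labels <- as.integer(labels)
  present <- sort(unique(labels))
  if (length(present) < 2L)
    stop("CH undefined for one cluster")
  Tn <- nrow(x)
  k <- length(present)
  gm <- colMeans(x)
  B <- 0; W <- 0
  for (g in present) {
    idx <- which(labels == g)
    cm <- colMeans(x[idx, , drop = FALSE])
    B <- B + length(idx) * sum((cm - gm)^2)
    W <- W + sum(sweep(x[idx, , drop = FALSE], 2L, cm, "-")^2)
  }
  if (W < 1e-300) return(1e12)
  min((B / (k - 1)) / (W / (Tn - k)), 1e12)
}

# leave-one-out k-nearest-neighbour vote on flattened gamma features;
# Euclidean distance, majority vote, ties resolved by the single nearest
# neighbour
knnLoso <- function(features, labels, kNeighbors) {
  n <- nrow(features)
  D <- as.matrix(dist(features))
  pred <- character(n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    others <- labels[-i]
    ord <- order(d)
    kk <- min(kNeighbors, length(ord))
    votes <- table(others[ord[seq_len(kk)]])
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1L) top else others[ord[1L]]
  }
  pred
}

#' Narrative decoding accuracy from decoded state sequences
#'
#' Leave-one-subject-out k-nearest-neighbour classification of which
#' narrative each subject heard, using the decoded state expression
#' matrices (flattened T x k gamma) as features.
#'
#' @param decoded list of [StatePosterior-class], all with equal T.
#' @param narratives per-subject narrative labels (at least 2 distinct).
#' @param kNeighbors neighbourhood size (default 5; majority vote, ties
#'   fall back to the single nearest neighbour).
#' @return mean classification accuracy in \[0, 1\].
#' @export
narrativeDecodingAccuracy <- function(decoded, narratives, kNeighbors = 5L) {
  Ts <- vapply(decoded, function(p) nrow(p@gamma), 1L)
  if (length(unique(Ts)) != 1L)
    stop("all decoded sequences must have the same length")
  if (length(unique(narratives)) < 2L)
    stop("at least two narratives required")
  features <- t(sapply(decoded, function(p) as.numeric(p@gamma)))
  pred <- knnLoso(features, as.character(narratives), kNeighbors)
  mean(pred == as.character(narratives))
}

#' Select the number of latent states by the dual criterion
#'
#' For every k on the grid, runs leave-one-subject-out decoding, computes
#' each subject's Calinski-Harabasz score from their decoded Viterbi
#' labelling (averaged across subjects) and the narrative decoding
#' accuracy, converts both criteria independently to z-scores across the
#' grid, and selects the k with the largest summed z-score (ties toward
#' the smallest k). Clustering quality typically favours few states while
#' decoding accuracy favours many; the summed z-score balances the two.
#'
#' @param seriesList list of [NetworkTimeSeries-class] or a
#'   [SimulatedCohort-class].
#' @param narratives per-subject narrative labels; taken from the cohort
#'   when omitted.
#' @param kGrid candidate numbers of states (default 2:10).
#' @param nRestarts EM restarts per fold (default 10).
#' @param kNeighbors KNN neighbourhood for narrative decoding (default 5).
#' @param seed integer seed.
#' @param maxIter EM iteration cap per fit (default 100).
#' @return a [KSelectionResult-class].
#' @export
selectNumStates <- function(seriesList, narratives = NULL, kGrid = 2:10,
                            nRestarts = 10L, kNeighbors = 5L, seed = 1L,
                            maxIter = 100L) {
  if (is(seriesList, "SimulatedCohort")) {
    if (is.null(narratives)) narratives <- seriesList@narrativeLabels
    seriesList <- seriesList@series
  }
  kGrid <- sort(unique(as.integer(kGrid)))
  if (length(kGrid) < 2L) stop("k grid must contain at least 2 values")
  ch <- acc <- numeric(length(kGrid))
  for (gi in seq_along(kGrid)) {
    k <- kGrid[gi]
    decoded <- losoDecode(seriesList, k, nRestarts = nRestarts,
                          seed = childSeed(seed, "k", k), maxIter = maxIter)
    chSub <- vapply(seq_along(decoded), function(i) {
      labs <- decoded[[i]]@path
      if (length(unique(labs)) < 2L) NA_real_
      else calinskiHarabasz(seriesList[[i]], labs)
    }, 0)
    ch[gi] <- mean(chSub, na.rm = TRUE)
    acc[gi] <- narrativeDecodingAccuracy(decoded, narratives, kNeighbors)
  }
  zCh <- as.numeric(scale(ch))
  zAcc <- as.numeric(scale(acc))
  if (anyNA(zCh)) zCh <- rep(0, length(ch))    # flat criterion
  if (anyNA(zAcc)) zAcc <- rep(0, length(acc))
  zSum <- zCh + zAcc
  new("KSelectionResult", kGrid = kGrid, chScores = ch,
      decodeAccuracy = acc, zCh = zCh, zAcc = zAcc, zSum = zSum,
      kStar = kGrid[which.max(zSum)])
}
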