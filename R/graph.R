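#' Group-averaged functional connectivity matrix
#'
#' Pearson correlation matrix per subject, averaged entrywise across
#' subjects, with a unit diagonal.
#'
#' @param seriesList list of [NetworkTimeSeries-class] or a
#'   [SimulatedCohort-class].
#' @return N x N symmetric matrix.
#' @export
groupFC <- function(seriesList) {
  if (is(seriesList, "SimulatedCohort")) seriesList <- seriesList@series
  if (!length(seriesList)) stop("at least one subject required")
  mats <- lapply(seriesList, function(s) {
    sdv <- apply(s@data, 2L, sd)
    if (any(sdv < 1e-12))
      stop("zero-variance network in subject ", s@subjectId)
    cor(s@data)
  })
  fc <- Reduce(`+`, mats) / length(mats)
  diag(fc) <- 1
  fc
}

#' z-Rand score between two partitions
#'
#' The z-scored Rand coefficient of Traud, Kelsic, Mucha and Porter: the
#' number of node pairs co-assigned in both partitions, standardized by
#' its permutation-null mean and variance. Zero in expectation for
#' independent partitions; maximal for identical partitions (up to label
#' permutation).
#'
#' @param a,b integer community labels of the same length.
#' @return the z-Rand score.
#' @export
zRandScore <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have the same length")
  n <- length(a)
  tab <- table(a, b)
  nai <- rowSums(tab); nbj <- colSums(tab)
  M <- n * (n - 1) / 2
  M1 <- sum(nai * (nai - 1) / 2); M2 <- sum(nbj * (nbj - 1) / 2)
  w <- sum(tab * (tab - 1) / 2)
  muw <- M1 * M2 / M
  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * sum(nai^3)
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * sum(nbj^3)
  a1 <- 4 * M1 - 2 * M; a2 <- 4 * M2 - 2 * M
  sigw2 <- M / 16 - a1^2 * a2^2 / (256 * M^2) +
    C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
    (a1^2 - 4 * C1 - 4 * M) * (a2^2 - 4 * C2 - 4 * M) /
      (64 * n * (n - 1) * (n - 2) * (n - 3))
  if (sigw2 <= 0) return(0)
  (w - muw) / sqrt(sigw2)
}

fcToGraph <- function(fc) {
  w <- (fc + t(fc)) / 2   # exact symmetry for igraph
  w[w < 0] <- 0           # negative weights are zeroed by convention
  diag(w) <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Louvain community detection across a resolution sweep
#'
#' For every resolution `gamma`, runs the Louvain algorithm `nRuns` times
#' on the (negative-thresholded) weighted graph, scores the consistency of
#' each run against every other with the z-Rand score, picks the medoid
#' run (most similar to all others) as the representative partition, and
#' multiplies its modularity by the mean pairwise z-Rand to form the
#' modularity-weighted z-Rand score. The sweep's argmax is flagged.
#'
#' @param fc N x N symmetric connectivity matrix.
#' @param gammas resolutions to sweep (default `seq(1.2, 2.5, by = 0.01)`).
#' @param nRuns Louvain runs per resolution (default 1000).
#' @param seed integer seed.
#' @return list of [BrainPartition-class]; the element maximizing the
#'   weighted score carries attribute `best = TRUE` and the list carries
#'   attribute `bestIndex`.
#' @export
louvainSweep <- function(fc, gammas = seq(1.2, 2.5, by = 0.01),
                         nRuns = 1000L, seed = 1L) {
  if (max(abs(fc - t(fc))) > 1e-8) stop("fc must be symmetric")
  g <- fcToGraph(fc)
  if (igraph::ecount(g) == 0L)
    stop("no positive-weight edges after thresholding")
  out <- vector("list", length(gammas))
  for (gi in seq_along(gammas)) {
    gamma <- gammas[gi]
    memberships <- withSeed(childSeed(seed, "louvain", gi), {
      lapply(seq_len(nRuns), function(r)
        as.integer(igraph::membership(
          igraph::cluster_louvain(g, resolution = gamma))))
    })
    if (nRuns == 1L) {
      zm <- matrix(0, 1, 1)
    } else {
      zm <- matrix(0, nRuns, nRuns)
      for (i in seq_len(nRuns - 1L)) for (j in (i + 1L):nRuns) {
        z <- zRandScore(memberships[[i]], memberships[[j]])
        zm[i, j] <- z; zm[j, i] <- z
      }
    }
    perRun <- if (nRuns == 1L) 0 else rowSums(zm) / (nRuns - 1L)
    rep <- which.max(perRun)
    labels <- memberships[[rep]]
    labels <- as.integer(factor(labels, levels = unique(labels)))
    q <- igraph::modularity(g, labels,
                            weights = igraph::E(g)$weight,
                            resolution = gamma)
    zmean <- if (nRuns == 1L) 0 else mean(zm[upper.tri(zm)])
    out[[gi]] <- new("BrainPartition", labels = labels, gamma = gamma,
                     q = q, zrandMean = zmean,
                     weightedScore = q * zmean)
  }
  scores <- vapply(out, function(p) p@weightedScore, 0)
  attr(out, "bestIndex") <- which.max(scores)
  out
}

#' State-specific functional connectivity
#'
#' Pearson correlation over the time points the Viterbi path assigns to a
#' given state.
#'
#' @param series a [NetworkTimeSeries-class].
#' @param path length-T decoded state sequence.
#' @param state state index.
#' @return N x N correlation matrix.
#' @export
stateSpecificFC <- function(series, path, state) {
  idx <- which(path == state)
  N <- ncol(series@data)
  if (length(idx) < N + 2L)
    stop("insufficient occupancy: state ", state, " visited ",
         length(idx), " time points (need >= ", N + 2L, ")")
  sub <- series@data[idx, , drop = FALSE]
  sdv <- apply(sub, 2L, sd)
  if (any(sdv < 1e-12)) stop("zero-variance network within state ", state)
  cor(sub)
}

#' Weighted global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length on the
#' weighted graph, with negative weights zeroed and edge length defined as
#' the reciprocal of the connection weight. Disconnected pairs contribute
#' zero. For correlation-weighted graphs this lies in \[0, 1\].
#'
#' @param fc N x N symmetric connectivity matrix (N >= 2).
#' @return global efficiency.
#' @export
#' @examples
#' globalEfficiency(matrix(1, 3, 3))  # complete unit graph: 1
globalEfficiency <- function(fc) {
  if (nrow(fc) < 2L) stop("need at least 2 nodes")
  if (max(abs(fc - t(fc))) > 1e-8) stop("fc must be symmetric")
  g <- fcToGraph(fc)
  if (igraph::ecount(g) == 0L) return(0)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (nrow(fc) * (nrow(fc) - 1))
}

#' Louvain modularity of a connectivity matrix
#'
#' Best modularity over `nRuns` Louvain runs at resolution `gamma`
#' (default 1), with negative weights zeroed.
#'
#' @param fc N x N symmetric connectivity matrix.
#' @param gamma resolution parameter (default 1).
#' @param nRuns Louvain runs (default 100).
#' @param seed integer seed.
#' @return list with `q` and `labels` of the best run.
#' @export
modularityQ <- function(fc, gamma = 1, nRuns = 100L, seed = 1L) {
  if (max(abs(fc - t(fc))) > 1e-8) stop("fc must be symmetric")
  if (gamma <= 0) stop("gamma must be positive")
  g <- fcToGraph(fc)
  if (igraph::ecount(g) == 0L) stop("no positive-weight edges")
  bestQ <- -Inf; bestLab <- NULL
  withSeed(childSeed(seed, "modq"), {
    for (r in seq_len(nRuns)) {
      cl <- igraph::cluster_louvain(g, resolution = gamma)
      q <- igraph::modularity(g, igraph::membership(cl),
                              weights = igraph::E(g)$weight,
                              resolution = gamma)
      if (q > bestQ) {
        bestQ <- q
        bestLab <- as.integer(igraph::membership(cl))
      }
    }
  })
  list(q = bestQ, labels = bestLab)
}

#' Per-state network topology contrast across subjects
#'
#' For each subject and state, builds the state-specific FC graph and
#' computes weighted global efficiency and Louvain modularity (gamma = 1),
#' then contrasts states with paired two-tailed t-tests. Subjects missing
#' a state (insufficient occupancy) are excluded and reported. A
#' model-derived variant computes the same metrics from the per-state
#' model covariance converted to correlation.
#'
#' @param seriesList list of [NetworkTimeSeries-class].
#' @param posteriors list of [StatePosterior-class] (Viterbi paths used).
#' @param model the fitted [GaussianHMM-class].
#' @param nRuns Louvain runs per graph (default 20).
#' @param seed integer seed.
#' @return list with `geff` and `q` (subjects x states, NA where
#'   excluded), `tests` (data frame of pairwise paired t-tests), `modelDerived`
#'   (per-state geff and q from the model FC), and `excluded` (subject
#'   indices with any missing state).
#' @export
stateTopologyContrast <- function(seriesList, posteriors, model,
                                  nRuns = 20L, seed = 1L) {
  if (is(seriesList, "SimulatedCohort")) seriesList <- seriesList@series
  k <- model@k
  n <- length(seriesList)
  geff <- matrix(NA_real_, n, k)
  qmat <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    for (s in seq_len(k)) {
      fc <- tryCatch(stateSpecificFC(seriesList[[i]], posteriors[[i]]@path, s),
                     error = function(e) NULL)
      if (is.null(fc)) next
      geff[i, s] <- globalEfficiency(fc)
      qmat[i, s] <- modularityQ(fc, gamma = 1, nRuns = nRuns,
                                seed = childSeed(seed, "q", i, s))$q
    }
  }
  excluded <- which(apply(is.na(geff), 1L, any))
  keep <- setdiff(seq_len(n), excluded)
  if (length(keep) < 3L)
    stop("fewer than 3 subjects with all states visited")
  tests <- do.call(rbind, lapply(utils::combn(k, 2L, simplify = FALSE),
    function(pr) {
      a <- pr[1]; b <- pr[2]
      tg <- t.test(geff[keep, a], geff[keep, b], paired = TRUE)
      tq <- t.test(qmat[keep, a], qmat[keep, b], paired = TRUE)
      data.frame(stateA = a, stateB = b,
                 tGeff = unname(tg$statistic), pGeff = tg$p.value,
                 tQ = unname(tq$statistic), pQ = tq$p.value)
    }))
  md <- lapply(seq_len(k), function(s) {
    fc <- stats::cov2cor(model@covs[, , s])
    list(geff = globalEfficiency(fc),
         q = modularityQ(fc, gamma = 1, nRuns = nRuns,
                         seed = childSeed(seed, "mq", s))$q)
  })
  list(geff = geff, q = qmat, tests = tests,
       modelDerived = data.frame(
         state = seq_len(k),
         geff = vapply(md, `[[`, 0, "geff"),
         q = vapply(md, `[[`, 0, "q")),
       excluded = excluded)
}
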