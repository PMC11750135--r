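#' Standardize a network time series
#'
#' Column-wise z-scoring (within subject, within network), the
#' normalization applied before any model fitting so that state mean
#' vectors are on the z-unit scale. TR and labels are unchanged.
#'
#' @param series a [NetworkTimeSeries-class].
#' @return the series with each column at mean 0, sd 1.
#' @export
standardizeSeries <- function(series) {
  series@data <- zscoreColumns(series@data)
  series
}

gaussHMMFromFit <- function(fit, k, nRestarts, seed, networks, trace) {
  new("GaussianHMM", k = as.integer(k), means = fit$means,
      covs = fit$covs, transition = fit$transition,
      initial = as.numeric(fit$initial), evidence = fit$evidence,
      loglikTrace = trace, converged = fit$converged,
      nRestarts = as.integer(nRestarts), seed = as.integer(seed),
      networks = networks)
}

#' Fit a Gaussian-emission HMM to a cohort
#'
#' Baum-Welch EM on the concatenation of all subjects' (standardized)
#' time series, with the forward recursion restarting from the initial
#' distribution at each subject boundary so that no transition is counted
#' across subjects. The fit is repeated `nRestarts` times from k-means
#' initializations (seeded per restart) and the restart with the highest
#' model evidence (training log-likelihood) is returned.
#'
#' Covariances are full, per state, and regularized by adding `reg` to the
#' diagonal at every M-step. Initialization: k-means centres for the means
#' (computed on a row-sorted copy of the data so the result does not
#' depend on subject order), the pooled covariance for every state, a
#' transition matrix with 0.9 self-transition mass, and a uniform initial
#' distribution.
#'
#' @param seriesList list of [NetworkTimeSeries-class] with a common
#'   number of networks.
#' @param k number of latent states.
#' @param nRestarts number of EM restarts (default 10).
#' @param seed integer seed; the fit is deterministic given it.
#' @param maxIter maximum EM iterations per restart (default 100).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param reg diagonal covariance regularizer (default 1e-6).
#' @return a [GaussianHMM-class].
#' @export
#' @examples
#' coh <- simulateCohort(defaultGroundTruth(nSubjects = 4, nTimepoints = 60))
#' fitHMM(cohortSeries(coh), k = 3, nRestarts = 2, seed = 1)
fitHMM <- function(seriesList, k, nRestarts = 10L, seed = 1L,
                   maxIter = 100L, tol = 1e-6, reg = 1e-6) {
  if (is(seriesList, "SimulatedCohort")) seriesList <- seriesList@series
  if (is(seriesList, "NetworkTimeSeries")) seriesList <- list(seriesList)
  Ns <- vapply(seriesList, function(s) ncol(s@data), 1L)
  if (length(unique(Ns)) != 1L)
    stop("all series must share the same number of networks")
  N <- Ns[1]
  segLens <- vapply(seriesList, function(s) nrow(s@data), 1L)
  X <- do.call(rbind, lapply(seriesList, function(s) s@data))
  Tt <- nrow(X)
  if (Tt <= k * N)
    stop("not enough time points (", Tt, ") to fit k = ", k,
         " states over ", N, " networks")
  if (k < 1L) stop("k must be at least 1")
  networks <- colnames(seriesList[[1]]@data)
  if (is.null(networks)) networks <- sprintf("net%d", seq_len(N))

  pooled <- cov(X) * (Tt - 1) / Tt
  Xsorted <- X[do.call(order, as.data.frame(X)), , drop = FALSE]
  A0 <- if (k == 1L) matrix(1, 1, 1) else {
    a <- matrix(0.1 / (k - 1), k, k); diag(a) <- 0.9; a
  }
  best <- NULL
  for (r in seq_len(nRestarts)) {
    covs0 <- array(pooled + reg * diag(N), c(N, N, k))
    means0 <- withSeed(childSeed(seed, "restart", r), {
      if (k == 1L) matrix(colMeans(X), 1L, N)
      else {
        km <- suppressWarnings(
          kmeans(Xsorted, centers = k, nstart = 3L, iter.max = 50L,
                 algorithm = "Lloyd"))
        # cluster-specific covariance start: fewer EM iterations than a
        # pooled start, same fixed points
        for (j in seq_len(k)) {
          idx <- which(km$cluster == j)
          if (length(idx) > N + 1L)
            covs0[, , j] <- cov(Xsorted[idx, , drop = FALSE]) *
              (length(idx) - 1) / length(idx) + reg * diag(N)
        }
        km$centers
      }
    })
    fit <- .emFitCpp(X, segLens, means0, covs0, A0, rep(1 / k, k),
                     as.integer(maxIter), tol, reg)
    if (is.null(best) || fit$evidence > best$evidence) best <- fit
  }
  # non-convergence is recorded in the `converged` slot (best-so-far
  # parameters are still returned)
  dimnames(best$means) <- list(NULL, networks)
  gaussHMMFromFit(best, k, nRestarts, seed, networks,
                  as.numeric(best$loglikTrace))
}

logDensities <- function(series, model) {
  if (ncol(series@data) != ncol(model@means))
    stop("series has ", ncol(series@data), " networks but the model expects ",
         ncol(model@means))
  .gaussLogDensCpp(series@data, model@means, model@covs)
}

#' Posterior state expression probabilities
#'
#' Scaled forward-backward posteriors (`gamma`) for one subject under a
#' fitted model, together with the Viterbi path and the data
#' log-likelihood.
#'
#' @param series a [NetworkTimeSeries-class].
#' @param model a [GaussianHMM-class] with matching network count.
#' @return a [StatePosterior-class].
#' @export
posteriorProbs <- function(series, model) {
  logB <- logDensities(series, model)
  fb <- .forwardBackwardCpp(logB, model@transition, model@initial,
                            nrow(logB))
  path <- .viterbiCpp(logB, log(model@transition), log(model@initial))
  new("StatePosterior", gamma = fb$gamma, path = as.integer(path),
      loglik = fb$loglik)
}

#' Most likely state sequence (Viterbi decoding)
#'
#' @inheritParams posteriorProbs
#' @return a [StatePosterior-class] whose `path` maximizes the joint
#'   log-probability; ties are broken toward the lower state index.
#' @export
viterbiPath <- function(series, model) posteriorProbs(series, model)

#' Align state labels between two fitted models
#'
#' Independently fitted HMMs label their states arbitrarily. This returns
#' the permutation of the candidate's states that best matches the
#' reference, maximizing the summed Pearson correlation between matched
#' state mean vectors over all assignments (exhaustive optimal assignment
#' for k up to 8, greedy beyond).
#'
#' @param candidate,reference [GaussianHMM-class] objects with equal `k`
#'   and network count (matrices of state means are also accepted).
#' @return integer vector `perm`: candidate state `i` corresponds to
#'   reference state `perm[i]`.
#' @seealso [relabelModel()] to apply the permutation.
#' @export
alignStateLabels <- function(candidate, reference) {
  mc <- if (is(candidate, "GaussianHMM")) candidate@means else candidate
  mr <- if (is(reference, "GaussianHMM")) reference@means else reference
  if (nrow(mc) != nrow(mr)) stop("models must have the same number of states")
  k <- nrow(mc)
  S <- matrix(0, k, k)  # S[i, j] = cor(candidate i, reference j)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    S[i, j] <- if (sd(mc[i, ]) < 1e-12 || sd(mr[j, ]) < 1e-12) 0
               else cor(mc[i, ], mr[j, ])
  }
  if (k <= 8L) {
    perms <- permutationsAll(k)
    sums <- vapply(seq_len(nrow(perms)), function(p)
      sum(S[cbind(seq_len(k), perms[p, ])]), 0)
    perms[which.max(sums), ]
  } else {
    perm <- integer(k)
    taken <- logical(k)
    for (i in order(apply(S, 1L, max), decreasing = TRUE)) {
      j <- which.max(replace(S[i, ], taken, -Inf))
      perm[i] <- j
      taken[j] <- TRUE
    }
    perm
  }
}

# all permutations of 1..k as rows
permutationsAll <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsAll(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  r <- 1L
  for (pos in seq_len(k)) for (s in seq_len(nrow(sub))) {
    out[r, ] <- append(sub[s, ], k, after = pos - 1L)
    r <- r + 1L
  }
  out
}

#' Relabel the states of a fitted model
#'
#' Reorders means, covariances, transition matrix and initial distribution
#' so that candidate state `i` (which [alignStateLabels()] matched to
#' reference state `perm[i]`) becomes state `perm[i]`.
#'
#' @param model a [GaussianHMM-class].
#' @param perm permutation as returned by [alignStateLabels()].
#' @return the relabelled model.
#' @export
relabelModel <- function(model, perm) {
  inv <- order(perm)  # new state j was candidate inv[j]
  model@means <- model@means[inv, , drop = FALSE]
  model@covs <- model@covs[, , inv, drop = FALSE]
  model@transition <- model@transition[inv, inv, drop = FALSE]
  model@initial <- model@initial[inv]
  model
}

#' Relabel a state path
#'
#' @param path integer state sequence from the candidate model.
#' @param perm permutation from [alignStateLabels()].
#' @return the path in reference labels.
#' @export
relabelPath <- function(path, perm) as.integer(perm[path])
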