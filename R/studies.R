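#' Validation studies
#'
#' Self-contained simulation studies that exercise the pipeline end to end
#' on synthetic cohorts and summarize how well each stage recovers the
#' planted truth. They back the package's acceptance checks and can be
#' re-run at any time; every study derives all randomness from its `seed`.
#'
#' @name validationStudies
NULL

# brute-force reference: exact posteriors/Viterbi by enumerating all k^T
# paths; independent of the forward-backward implementation
bruteForcePosterior <- function(X, model) {
  Tn <- nrow(X)
  k <- model@k
  logB <- vapply(seq_len(k), function(j) {
    S <- model@covs[, , j]
    mu <- model@means[j, ]
    apply(X, 1L, function(x)
      -0.5 * (length(mu) * log(2 * pi) +
                as.numeric(determinant(S)$modulus) +
                stats::mahalanobis(matrix(x, 1), mu, S)))
  }, numeric(Tn))
  logB <- matrix(logB, Tn, k)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), Tn)))
  logp <- apply(paths, 1L, function(p) {
    lp <- log(model@initial[p[1]]) + logB[1, p[1]]
    if (Tn > 1) for (t in 2:Tn)
      lp <- lp + log(model@transition[p[t - 1], p[t]]) + logB[t, p[t]]
    lp
  })
  M <- max(logp)
  w <- exp(logp - M)
  gamma <- matrix(0, Tn, k)
  for (t in seq_len(Tn)) for (j in seq_len(k))
    gamma[t, j] <- sum(w[paths[, t] == j]) / sum(w)
  list(gamma = gamma, loglik = M + log(sum(w)),
       path = as.integer(paths[which.max(logp), ]))
}

randomStudyModel <- function(k, N) {
  means <- matrix(rnorm(k * N, sd = 2), k, N)
  covs <- array(0, c(N, N, k))
  for (j in seq_len(k)) {
    A <- matrix(rnorm(N * N, sd = 0.3), N, N)
    covs[, , j] <- crossprod(A) + diag(N)
  }
  A <- matrix(runif(k * k) + 0.2, k, k)
  pinit <- runif(k) + 0.2
  new("GaussianHMM", k = as.integer(k), means = means, covs = covs,
      transition = A / rowSums(A), initial = pinit / sum(pinit),
      evidence = 0, loglikTrace = numeric(0), converged = TRUE,
      nRestarts = 1L, seed = 1L, networks = sprintf("net%d", seq_len(N)))
}

#' @describeIn validationStudies Exact-inference check: maximum absolute
#'   deviation of forward-backward posteriors and log-likelihoods from
#'   exhaustive path enumeration, and the Viterbi agreement rate, over
#'   `nInstances` random models with k <= 3 and T <= 8.
#' @param nInstances number of random instances.
#' @param seed integer seed.
#' @export
studyExactInference <- function(nInstances = 100L, seed = 1L) {
  maxGammaErr <- 0
  maxLoglikErr <- 0
  pathAgree <- logical(nInstances)
  withSeed(childSeed(seed, "exact"), {
    for (i in seq_len(nInstances)) {
      k <- sample(2:3, 1L)
      Tn <- sample(4:8, 1L)
      model <- randomStudyModel(k, N = 2L)
      X <- matrix(rnorm(Tn * 2, sd = 1.5), Tn, 2L)
      post <- posteriorProbs(makeStudySeries(X), model)
      ref <- bruteForcePosterior(X, model)
      maxGammaErr <- max(maxGammaErr, max(abs(post@gamma - ref$gamma)))
      maxLoglikErr <- max(maxLoglikErr, abs(post@loglik - ref$loglik))
      pathAgree[i] <- identical(statePath(post), ref$path)
    }
  })
  list(maxGammaError = maxGammaErr, maxLoglikError = maxLoglikErr,
       viterbiAgreement = mean(pathAgree), n = nInstances)
}

makeStudySeries <- function(X) {
  new("NetworkTimeSeries", subjectId = "study", data = X, tr = 2,
      narrative = "n1", condition = "task")
}

#' @describeIn validationStudies Parameter recovery on homogeneous cohorts
#'   (no narrative drive or stimulus coupling, so the base transition
#'   matrix is the true time-averaged kernel): per-seed maximum absolute
#'   errors of fitted state means (vs the standardized truth) and
#'   transition entries after label alignment.
#' @param nSeeds number of independent cohorts.
#' @param nSubjects,nTimepoints cohort geometry.
#' @param nRestarts EM restarts.
#' @export
studyParameterRecovery <- function(nSeeds = 10L, nSubjects = 20L,
                                   nTimepoints = 300L, nRestarts = 10L,
                                   seed = 1L) {
  meanErr <- transErr <- numeric(nSeeds)
  for (i in seq_len(nSeeds)) {
    cfg <- defaultGroundTruth(nSubjects = nSubjects,
                              nTimepoints = nTimepoints,
                              couplingStrength = 0,
                              narrativeDriveStrength = 0,
                              seed = childSeed(seed, "recov", i))
    coh <- simulateCohort(cfg)
    m <- fitHMM(cohortSeries(coh), 3L, nRestarts = nRestarts,
                seed = childSeed(seed, "recovfit", i))
    m <- relabelModel(m, alignStateLabels(m, standardizedStateMeans(cfg)))
    meanErr[i] <- max(abs(stateMeans(m) - standardizedStateMeans(cfg)))
    transErr[i] <- max(abs(transitionMatrix(m) - transitionMatrix(cfg)))
  }
  list(meanErrors = meanErr, transErrors = transErr,
       nRecovered = sum(meanErr < 0.15 & transErr < 0.05), n = nSeeds)
}

#' @describeIn validationStudies Number-of-states selection recovery:
#'   fraction of synthetic cohorts (true K = 3) for which the dual
#'   criterion selects K = 3 over the grid 2..6.
#' @param kGrid candidate state numbers.
#' @export
studyKSelection <- function(nSeeds = 10L, nSubjects = 12L, kGrid = 2:6,
                            nRestarts = 5L, seed = 1L) {
  kStars <- integer(nSeeds)
  for (i in seq_len(nSeeds)) {
    cfg <- defaultGroundTruth(nSubjects = nSubjects,
                              seed = childSeed(seed, "ksel", i))
    coh <- simulateCohort(cfg)
    sel <- selectNumStates(coh, kGrid = kGrid, nRestarts = nRestarts,
                           seed = childSeed(seed, "kselrun", i))
    kStars[i] <- sel@kStar
  }
  list(kStars = kStars, nCorrect = sum(kStars == 3L), n = nSeeds)
}

#' @describeIn validationStudies Calibration of the transition-hub
#'   surrogate test on structureless cohorts (independent white-noise
#'   columns): the number of cohorts rejected at the 0.05 level should be
#'   binomially consistent with the nominal rate.
#' @param nCohorts number of null cohorts.
#' @param nPerm surrogate permutations per cohort.
#' @export
studyHubCalibration <- function(nCohorts = 100L, nSubjects = 4L,
                                nTimepoints = 100L, nPerm = 50L,
                                seed = 1L) {
  ps <- numeric(nCohorts)
  for (i in seq_len(nCohorts)) {
    sl <- withSeed(childSeed(seed, "nullcoh", i), {
      lapply(seq_len(nSubjects), function(s) {
        x <- matrix(rnorm(nTimepoints * 9L), nTimepoints, 9L)
        makeStudySeries(zscoreColumns(x))
      })
    })
    sn <- transitionSurrogateNull(sl, k = 3L, nPerm = nPerm,
                                  nRestarts = 1L, collectOccupancy = FALSE,
                                  seed = childSeed(seed, "nullperm", i))
    ps[i] <- sn@empiricalP
  }
  list(pValues = ps, nRejected = sum(ps < 0.05), n = nCohorts)
}

#' Hub-identifiable ground truth for the surrogate power study
#'
#' A cohort configuration with a pronounced transitional hub (mean
#' asymmetry 0.11), network loadings at half the default amplitude, and no
#' stimulus or narrative tilts. The reduced loadings keep any single
#' network's univariate dynamics close to unimodal, which is the regime
#' where circular shifting genuinely destroys the latent structure; at
#' full amplitude the surrogate fits simply track individual shifted
#' columns and inherit the chain's asymmetry, flooring the null.
#'
#' @param nSubjects,nTimepoints cohort geometry.
#' @param seed integer seed.
#' @return a [GroundTruthConfig-class].
#' @export
hubStudyGroundTruth <- function(nSubjects = 32L, nTimepoints = 300L,
                                seed = 1L) {
  cfg <- defaultGroundTruth(nSubjects = nSubjects,
                            nTimepoints = nTimepoints,
                            couplingStrength = 0,
                            narrativeDriveStrength = 0, seed = seed)
  cfg@stateMeans <- cfg@stateMeans * 0.5
  cfg@baseTransition <- rbind(c(0.87, 0.12, 0.01),
                              c(0.05, 0.90, 0.05),
                              c(0.01, 0.12, 0.87))
  cfg
}

#' @describeIn validationStudies Power of the transition-hub surrogate
#'   test on hub-identifiable cohorts (see [hubStudyGroundTruth()]):
#'   per-seed empirical p-values and the number detected at 0.05.
#' @export
studyHubPower <- function(nSeeds = 10L, nSubjects = 32L, nPerm = 100L,
                          seed = 1L) {
  ps <- obs <- numeric(nSeeds)
  for (i in seq_len(nSeeds)) {
    coh <- simulateCohort(hubStudyGroundTruth(
      nSubjects = nSubjects, seed = childSeed(seed, "hubcoh", i)))
    m <- fitHMM(cohortSeries(coh), 3L, nRestarts = 5L,
                seed = childSeed(seed, "hubfit", i))
    sn <- transitionSurrogateNull(cohortSeries(coh), 3L, nPerm = nPerm,
                                  nRestarts = 1L, collectOccupancy = FALSE,
                                  seed = childSeed(seed, "hubperm", i),
                                  observedModel = m)
    ps[i] <- sn@empiricalP
    obs[i] <- sn@observed
  }
  list(pValues = ps, observed = obs, nDetected = sum(ps < 0.05), n = nSeeds)
}

# fit a cohort once and return aligned per-subject posteriors + model
fitAndDecode <- function(coh, nRestarts, seed) {
  cfg <- coh@truth
  m <- fitHMM(cohortSeries(coh), nStates(cfg), nRestarts = nRestarts,
              seed = seed)
  m <- relabelModel(m, alignStateLabels(m, standardizedStateMeans(cfg)))
  list(model = m,
       posteriors = lapply(cohortSeries(coh), posteriorProbs, model = m))
}

perSubjectRegressors <- function(coh) {
  feats <- coh@truth@features
  out <- lapply(feats, function(f)
    lapply(coh@narrativeLabels, function(m) coh@regressors[[m]][[f]]))
  names(out) <- feats
  out
}

#' @describeIn validationStudies Type-I error of the stimulus-modulation
#'   permutation test at zero coupling: rejection fraction across all
#'   (feature, state) pairs of `nCohorts` cohorts.
#' @export
studyModulationCalibration <- function(nCohorts = 100L, nSubjects = 12L,
                                       nTimepoints = 200L, nPerm = 200L,
                                       seed = 1L) {
  rej <- 0L
  total <- 0L
  for (i in seq_len(nCohorts)) {
    cfg <- defaultGroundTruth(nSubjects = nSubjects,
                              nTimepoints = nTimepoints,
                              couplingStrength = 0,
                              seed = childSeed(seed, "modnull", i))
    coh <- simulateCohort(cfg)
    fd <- fitAndDecode(coh, nRestarts = 1L,
                       seed = childSeed(seed, "modnullfit", i))
    sc <- modulationScan(perSubjectRegressors(coh),
                         lapply(fd$posteriors, expressionProbs),
                         nPerm = nPerm,
                         seed = childSeed(seed, "modnullperm", i))
    rej <- rej + sum(sc$empiricalP < 0.05)
    total <- total + nrow(sc)
  }
  list(nRejected = rej, nTests = total, rate = rej / total)
}

#' @describeIn validationStudies Power and selectivity of the
#'   stimulus-modulation test on coupled cohorts: per-seed detection of
#'   every truly coupled (feature, state) pair and any false detection
#'   among uncoupled pairs.
#' @export
studyModulationPower <- function(nSeeds = 10L, nSubjects = 30L,
                                 nPerm = 500L, seed = 1L) {
  allCoupled <- anyLeak <- logical(nSeeds)
  for (i in seq_len(nSeeds)) {
    cfg <- defaultGroundTruth(nSubjects = nSubjects,
                              seed = childSeed(seed, "modpow", i))
    coh <- simulateCohort(cfg)
    fd <- fitAndDecode(coh, nRestarts = 3L,
                       seed = childSeed(seed, "modpowfit", i))
    sc <- modulationScan(perSubjectRegressors(coh),
                         lapply(fd$posteriors, expressionProbs),
                         nPerm = nPerm,
                         seed = childSeed(seed, "modpowperm", i))
    coupledPair <- sc$state == match(sc$feature, coh@truth@features)
    allCoupled[i] <- all(sc$empiricalP[coupledPair] < 0.05)
    anyLeak[i] <- any(sc$empiricalP[!coupledPair] < 0.05)
  }
  list(nAllCoupledDetected = sum(allCoupled), nWithLeakage = sum(anyLeak),
       n = nSeeds)
}

#' @describeIn validationStudies Graph oracles: maximum absolute deviation
#'   of weighted global efficiency from a Floyd-Warshall shortest-path
#'   reference over random 9-node graphs, and the modularity of two equal
#'   disconnected cliques at resolution 1.
#' @export
studyGraphOracles <- function(nInstances = 100L, seed = 1L) {
  floyd <- function(fc) {
    n <- nrow(fc)
    w <- fc
    w[w < 0] <- 0
    diag(w) <- 0
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    d[w > 0] <- 1 / w[w > 0]
    for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
      if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (n * (n - 1))
  }
  maxErr <- withSeed(childSeed(seed, "geff"), {
    errs <- vapply(seq_len(nInstances), function(i) {
      fc <- matrix(runif(81, -0.3, 1), 9, 9)
      fc <- (fc + t(fc)) / 2
      diag(fc) <- 1
      abs(globalEfficiency(fc) - floyd(fc))
    }, 0)
    max(errs)
  })
  fc2 <- matrix(0, 8, 8)
  fc2[1:4, 1:4] <- 1
  fc2[5:8, 5:8] <- 1
  diag(fc2) <- 1
  q <- modularityQ(fc2, gamma = 1, nRuns = 20L,
                   seed = childSeed(seed, "cliq"))$q
  list(maxEfficiencyError = maxErr, twoCliqueQ = q, n = nInstances)
}

#' @describeIn validationStudies Metastate reconstruction: a 10-state HMM
#'   is fitted to a cohort generated from 3 macro-states split into
#'   well-separated sub-states; its transition matrix is clustered into 3
#'   metastates, member states merged, and the result scored against the
#'   generator's macro truth (minimum matched spatial correlation and
#'   overall temporal overlap). The correlation against a fitted K = 3
#'   target model is also reported.
#' @export
studyMetastate <- function(nSubjects = 24L, seed = 1L) {
  base <- defaultGroundTruth(nSubjects = nSubjects,
                             seed = childSeed(seed, "meta"))
  base@stateMeans <- base@stateMeans * 2.5
  nest <- nestedGroundTruth(base)
  coh <- simulateCohort(nest$config)
  sl <- cohortSeries(coh)
  fine <- fitHMM(sl, 10L, nRestarts = 10L,
                 seed = childSeed(seed, "metafine"))
  cl <- clusterTransitions(transitionMatrix(fine), 3L)
  finePaths <- lapply(sl, function(s) statePath(posteriorProbs(s, fine)))
  mg <- mergeClusterStates(fine, cl, finePaths)
  stds <- standardizedStateMeans(nest$config)
  macroMeans <- t(vapply(1:3, function(m)
    colMeans(stds[nest$macroOf == m, , drop = FALSE]), numeric(9)))
  mm <- spatialMatch(mg$means, macroMeans)
  mapped <- lapply(mg$paths, function(p) mm@mapping[p])
  truthMacro <- lapply(truePaths(coh), function(p) nest$macroOf[p])
  overlap <- temporalJaccard(unlist(mapped), unlist(truthMacro))$overall
  # descriptive comparison against a fitted K = 3 target, as one would do
  # with real data where the generator truth is unavailable
  target <- fitHMM(sl, 3L, nRestarts = 5L,
                   seed = childSeed(seed, "metatarget"))
  mmT <- spatialMatch(mg$means, stateMeans(target))
  list(minSpatialR = min(mm@similarity), overlap = overlap,
       clusterSizes = as.integer(table(cl)),
       minSpatialRFittedTarget = min(mmT@similarity))
}

#' @describeIn validationStudies Behaviour pipeline: on behaviour-coupled
#'   cohorts, the correlation between decoded hub-state alignment and
#'   comprehension scores (detection at 0.05 per seed), with
#'   fractional-occupancy-score correlations as the null-calibrated
#'   comparison; plus the worst-case deviation of the partial correlation
#'   from its residual-regression oracle.
#' @export
studyBehavior <- function(nSeeds = 10L, nSubjects = 30L, seed = 1L) {
  detected <- logical(nSeeds)
  foRejected <- integer(nSeeds)
  alignR <- numeric(nSeeds)
  for (i in seq_len(nSeeds)) {
    cfg <- defaultGroundTruth(nSubjects = nSubjects, behaviorNoiseSd = 0.25,
                              seed = childSeed(seed, "beh", i))
    coh <- simulateBehavior(simulateCohort(cfg))
    fd <- fitAndDecode(coh, nRestarts = 2L,
                       seed = childSeed(seed, "behfit", i))
    gam <- lapply(fd$posteriors, expressionProbs)
    grp <- alignmentToGroup(gam, 2L, narrativeLabels(coh))
    bc <- behaviorCorrelation(grp, comprehensionScores(coh))
    detected[i] <- bc$r > 0 && bc$p < 0.05
    alignR[i] <- bc$r
    foRejected[i] <- sum(vapply(1:3, function(s) {
      fo <- vapply(fd$posteriors, function(p)
        fractionalOccupancy(statePath(p), 3L)[s], 0)
      behaviorCorrelation(fo, comprehensionScores(coh))$p < 0.05
    }, TRUE))
  }
  # residual oracle for the partial correlation on one synthetic sample
  oracleErr <- withSeed(childSeed(seed, "behoracle"), {
    z <- rnorm(40)
    x <- 0.5 * z + rnorm(40)
    y <- -0.3 * z + rnorm(40)
    bc <- behaviorCorrelation(x, y, covariate = z)
    abs(bc$partialR - cor(residuals(lm(x ~ z)), residuals(lm(y ~ z))))
  })
  list(nDetected = sum(detected), alignmentR = alignR,
       foRejectionRate = sum(foRejected) / (3 * nSeeds),
       partialOracleError = oracleErr, n = nSeeds)
}
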