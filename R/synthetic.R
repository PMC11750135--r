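#' Default ground truth for the synthetic cohort generator
#'
#' The default configuration mirrors the geometry and structure of a
#' naturalistic-listening fMRI study: 64 subjects, 300 time points at
#' TR = 2 s, 9 network time courses generated by a 3-state Gaussian HMM.
#' The three state mean vectors load positively on disjoint network groups
#' (sensory-motor, language + frontoparietal, DMN + frontoparietal), and
#' the base transition matrix makes state 2 a transitional hub: both
#' peripheral states are more likely to switch to it than to each other.
#' Three narrative groups share smooth stimulus-drive signals, and each of
#' the three stimulus features (envelope, word-level coherence,
#' clause-level coherence) is coupled to exactly one state.
#'
#' @param nSubjects number of subjects (default 64).
#' @param nTimepoints time points per run (default 300).
#' @param tr repetition time in seconds (default 2).
#' @param nNarratives number of narrative groups (default 3).
#' @param couplingStrength log-odds tilt of the transition kernel per unit
#'   of the coupled feature (default 0.5 for the diagonal feature-state
#'   pairing, 0 elsewhere). Together with `narrativeDriveStrength` this is
#'   calibrated so that the cohort reproduces the qualitative regime of
#'   naturalistic-listening studies: moderate within-narrative
#'   inter-subject correlation, narrative decoding accuracy that rises
#'   with the number of states without saturating at K = 2, and
#'   clustering quality that declines with K.
#' @param narrativeDriveStrength log-odds scale of the shared
#'   narrative drive (default 0.25; see `couplingStrength`).
#' @param behaviorGain logit-scale slope from alignment to score
#'   (default 3).
#' @param behaviorNoiseSd logit-scale score noise sd (default 0.5).
#' @param fdBase,fdNoiseSd,fdEngagementWeight framewise-displacement model:
#'   baseline level in mm, per-frame noise sd, and the decrease in baseline
#'   per unit engagement (defaults 0.15, 0.05, 0.1).
#' @param seed master seed.
#' @return a [GroundTruthConfig-class].
#' @export
#' @examples
#' cfg <- defaultGroundTruth(nSubjects = 4)
#' transitionMatrix(cfg)
defaultGroundTruth <- function(nSubjects = 64L, nTimepoints = 300L, tr = 2,
                               nNarratives = 3L, couplingStrength = 0.5,
                               narrativeDriveStrength = 0.25,
                               behaviorGain = 3, behaviorNoiseSd = 0.5,
                               fdBase = 0.15, fdNoiseSd = 0.05,
                               fdEngagementWeight = 0.1, seed = 1L) {
  networks <- c("auditory", "visual", "somatomotor", "language",
                "medial_temporal", "frontoparietal", "ventral_attention",
                "subcortical", "dmn")
  N <- length(networks)
  means <- rbind(
    c(1.2,  0.3,  1.0, -0.2,  0.0, -0.5,  0.2,  0.0, -0.8),  # sensory-motor
    c(-0.8, 0.0, -0.6,  1.2,  0.2,  0.9,  0.0,  0.1, -0.4),  # language+FPN
    c(-0.6, 0.1, -0.1, -0.7,  0.3,  0.8,  0.0,  0.0,  1.2))  # DMN+FPN
  colnames(means) <- networks
  # exchangeable within-state correlation; the hub state is the most
  # globally coupled, so its state-specific FC is densest
  rho <- c(0.15, 0.35, 0.15)
  covs <- array(0, c(N, N, 3L))
  for (j in 1:3) covs[, , j] <- (1 - rho[j]) * diag(N) + rho[j]
  base <- rbind(c(0.90, 0.08, 0.02),
                c(0.05, 0.90, 0.05),
                c(0.02, 0.08, 0.90))
  features <- c("envelope", "word_coherence", "clause_coherence")
  coupling <- diag(couplingStrength, 3L)  # feature f drives state f
  dimnames(coupling) <- list(features, NULL)
  new("GroundTruthConfig", nSubjects = as.integer(nSubjects),
      nNetworks = N, nTimepoints = as.integer(nTimepoints), tr = tr,
      kTrue = 3L, stateMeans = means, stateCovs = covs,
      baseTransition = base, nNarratives = as.integer(nNarratives),
      couplingStrength = coupling,
      narrativeDriveStrength = narrativeDriveStrength,
      behaviorGain = behaviorGain, behaviorNoiseSd = behaviorNoiseSd,
      fdBase = fdBase, fdNoiseSd = fdNoiseSd,
      fdEngagementWeight = fdEngagementWeight, seed = as.integer(seed),
      networks = networks, features = features)
}

#' Ground truth with macro-states split into sub-states
#'
#' Builds a finer generative model in which each macro-state of a base
#' configuration is split into several sub-states: sub-state means are
#' small perturbations of their macro-state mean, and the transition
#' matrix is block-dominant, so sub-states of the same macro-state
#' preferentially switch among themselves. Fitting a fine HMM to such a
#' cohort and clustering its transition matrix should recover the
#' macro-states (the metastate property).
#'
#' @param base a [GroundTruthConfig-class] whose states become the
#'   macro-states.
#' @param subPerMacro integer vector, number of sub-states per macro-state.
#' @param withinMass total within-block transition mass;
#'   the complement leaks across blocks following the base chain's
#'   off-diagonal pattern (default 0.94).
#' @param selfMass self-transition probability of each sub-state (default
#'   0.6); the rest of the within-block mass is shared among siblings, so
#'   sub-states switch quickly within their metastate — the property that
#'   makes metastates identifiable from the transition matrix.
#' @param jitterSd sd of the mean perturbation per sub-state (default 1.4, so
#'   sub-states are spatially distinct enough for a fine HMM to identify
#'   them).
#' @param seed seed for the perturbations.
#' @return list with `config` (the finer [GroundTruthConfig-class]) and
#'   `macroOf` (macro-state id per sub-state).
#' @export
nestedGroundTruth <- function(base, subPerMacro = c(4L, 3L, 3L),
                              withinMass = 0.94, selfMass = 0.6,
                              jitterSd = 1.4, seed = base@seed) {
  kMacro <- base@kTrue
  stopifnot(length(subPerMacro) == kMacro)
  k <- sum(subPerMacro)
  macroOf <- rep(seq_len(kMacro), subPerMacro)
  N <- base@nNetworks
  means <- matrix(0, k, N, dimnames = list(NULL, base@networks))
  covs <- array(0, c(N, N, k))
  withSeed(childSeed(seed, "nested"), {
    for (s in seq_len(k)) {
      m <- macroOf[s]
      means[s, ] <- base@stateMeans[m, ] + rnorm(N, 0, jitterSd)
      covs[, , s] <- base@stateCovs[, , m]
    }
  })
  A <- matrix(0, k, k)
  for (i in seq_len(k)) {
    within <- which(macroOf == macroOf[i])
    between <- setdiff(seq_len(k), within)
    others <- setdiff(within, i)
    if (length(others)) {
      A[i, i] <- selfMass
      A[i, others] <- (withinMass - selfMass) / length(others)
    } else {
      A[i, i] <- withinMass
    }
    leak <- base@baseTransition[macroOf[i], ]
    leak[macroOf[i]] <- 0
    w <- leak[macroOf[between]]
    A[i, between] <- (1 - withinMass) * w / sum(w)
  }
  cfg <- base
  cfg@kTrue <- as.integer(k)
  cfg@stateMeans <- means
  cfg@stateCovs <- covs
  cfg@baseTransition <- A / rowSums(A)
  cfg@couplingStrength <- matrix(0, length(base@features), k,
                                 dimnames = list(base@features, NULL))
  list(config = cfg, macroOf = macroOf)
}

# per-narrative drives and feature regressors on the TR grid, seeded by
# the narrative id so every subject in a narrative shares them. Feature
# signals are orthogonalized (Gram-Schmidt) against the drives and
# against each other within the narrative: smooth signals of this length
# carry chance correlations of ~0.2 that would otherwise leak one
# feature's coupling into another state and make selective modulation
# unidentifiable.
narrativeSignals <- function(cfg) {
  Tn <- cfg@nTimepoints
  lapply(seq_len(cfg@nNarratives), function(m) {
    drive <- withSeed(childSeed(cfg@seed, "drive", m), {
      sapply(seq_len(cfg@kTrue), function(k) smoothRandomSignal(Tn))
    })
    raw <- withSeed(childSeed(cfg@seed, "regressor", m), {
      sapply(seq_along(cfg@features), function(f) smoothRandomSignal(Tn))
    })
    basis <- drive
    feat <- matrix(0, Tn, length(cfg@features))
    for (f in seq_along(cfg@features)) {
      r <- residuals(lm(raw[, f] ~ basis))
      feat[, f] <- as.numeric(scale(r))
      basis <- cbind(basis, feat[, f])
    }
    regs <- lapply(seq_along(cfg@features), function(f)
      new("StimulusRegressor", name = cfg@features[f],
          values = feat[, f], nativeRate = 1 / cfg@tr,
          tr = cfg@tr, hrfApplied = TRUE))
    names(regs) <- cfg@features
    list(drive = drive, regressors = regs)
  })
}

#' Ground-truth state means in standardized (z-scored) space
#'
#' The generator z-scores every network column after sampling, so fitted
#' state means live in standardized space. This maps the configured state
#' means through the same transformation analytically, using the
#' stationary distribution of the base chain for the occupancy weights:
#' for network j, `mu'_kj = (mu_kj - mbar_j) / s_j` with
#' `mbar_j = sum_k pi_k mu_kj` and
#' `s_j^2 = sum_k pi_k (Sigma_k[j,j] + (mu_kj - mbar_j)^2)`. It is the
#' appropriate comparator for parameter-recovery studies (exact for the
#' homogeneous chain; an approximation when narrative drives or stimulus
#' coupling tilt the kernel).
#'
#' @param cfg a [GroundTruthConfig-class].
#' @return kTrue x nNetworks matrix of z-space state means.
#' @export
standardizedStateMeans <- function(cfg) {
  pi0 <- stationaryDistribution(cfg@baseTransition)
  mu <- cfg@stateMeans
  mbar <- colSums(pi0 * mu)
  v <- vapply(seq_len(ncol(mu)), function(j)
    sum(pi0 * (cfg@stateCovs[j, j, ] + (mu[, j] - mbar[j])^2)), 0)
  sweep(sweep(mu, 2L, mbar, "-"), 2L, sqrt(v), "/")
}

#' Simulate a cohort from a ground-truth configuration
#'
#' Each subject's state path is sampled from a time-inhomogeneous Markov
#' chain: at every time point the log transition odds of the base chain are
#' tilted by the subject's narrative drive (scaled by
#' `narrativeDriveStrength`) and by the narrative's stimulus regressors
#' (scaled by the feature-state coupling matrix). Emissions are drawn from
#' the active state's Gaussian and every network column is z-scored
#' afterwards. Subjects are assigned to narratives in round-robin order.
#'
#' @param cfg a [GroundTruthConfig-class].
#' @return a [SimulatedCohort-class] (without behaviour; see
#'   [simulateBehavior()]).
#' @export
#' @examples
#' coh <- simulateCohort(defaultGroundTruth(nSubjects = 4, nTimepoints = 80))
#' coh
simulateCohort <- function(cfg) {
  validObject(cfg)
  Tn <- cfg@nTimepoints
  k <- cfg@kTrue
  N <- cfg@nNetworks
  sig <- narrativeSignals(cfg)
  narrative <- rep_len(seq_len(cfg@nNarratives), cfg@nSubjects)
  chols <- lapply(seq_len(k), function(j) chol(cfg@stateCovs[, , j]))
  pi0 <- stationaryDistribution(cfg@baseTransition)
  logBase <- log(cfg@baseTransition)
  series <- vector("list", cfg@nSubjects)
  paths <- vector("list", cfg@nSubjects)
  withSeed(childSeed(cfg@seed, "emit"), {
    for (i in seq_len(cfg@nSubjects)) {
      m <- narrative[i]
      drive <- sig[[m]]$drive
      regs <- sapply(sig[[m]]$regressors, slot, "values")
      tilt <- cfg@narrativeDriveStrength * drive +
        regs %*% cfg@couplingStrength           # T x k log-odds tilt
      path <- integer(Tn)
      path[1] <- sample.int(k, 1L, prob = pi0 * exp(pmin(tilt[1, ], 30)))
      for (t in 2:Tn) {
        lo <- logBase[path[t - 1], ] + tilt[t, ]
        p <- exp(lo - max(lo))
        path[t] <- sample.int(k, 1L, prob = p)
      }
      z <- matrix(rnorm(Tn * N), Tn, N)
      x <- cfg@stateMeans[path, , drop = FALSE]
      for (j in seq_len(k)) {
        idx <- which(path == j)
        if (length(idx))
          x[idx, ] <- x[idx, , drop = FALSE] +
            z[idx, , drop = FALSE] %*% chols[[j]]
      }
      x <- zscoreColumns(x)
      colnames(x) <- cfg@networks
      series[[i]] <- new("NetworkTimeSeries",
                         subjectId = sprintf("sub-%03d", i), data = x,
                         tr = cfg@tr, narrative = sprintf("narrative%d", m),
                         condition = "task")
      paths[[i]] <- path
    }
  })
  regressors <- lapply(sig, `[[`, "regressors")
  names(regressors) <- sprintf("narrative%d", seq_len(cfg@nNarratives))
  new("SimulatedCohort", series = series, truePaths = paths,
      narrativeLabels = sprintf("narrative%d", narrative),
      regressors = regressors, scores = numeric(0), alignment = numeric(0),
      fdTraces = list(), truth = cfg)
}

#' Attach behaviour and head motion to a simulated cohort
#'
#' Comprehension scores are generated from each subject's alignment with
#' their narrative group: the Pearson correlation between the subject's
#' ground-truth hub-state indicator time course and the narrative-group
#' mean indicator. Scores are
#' `100 * logistic(gain * alignment + noise)`, keeping them on the 0-100
#' percentage scale. Framewise-displacement traces are baseline plus noise
#' minus an engagement term, with engagement correlated with the same
#' alignment, so more aligned (engaged) subjects move slightly less.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param hubState state whose indicator defines alignment (default 2).
#' @return the cohort with `scores`, `alignment` and `fdTraces` filled in.
#' @export
simulateBehavior <- function(cohort, hubState = 2L) {
  cfg <- cohort@truth
  Tn <- cfg@nTimepoints
  ind <- sapply(cohort@truePaths, function(p) as.numeric(p == hubState))
  align <- numeric(ncol(ind))
  for (m in unique(cohort@narrativeLabels)) {
    idx <- which(cohort@narrativeLabels == m)
    gm <- rowMeans(ind[, idx, drop = FALSE])
    for (i in idx) {
      align[i] <- if (sd(ind[, i]) < 1e-12 || sd(gm) < 1e-12) 0
                  else cor(ind[, i], gm)
    }
  }
  withSeed(childSeed(cfg@seed, "behavior"), {
    noise <- rnorm(length(align), 0, cfg@behaviorNoiseSd)
    scores <- 100 * logistic01(cfg@behaviorGain * align + noise)
    engagement <- align + rnorm(length(align), 0, 0.3)
    fd <- lapply(seq_along(align), function(i) {
      pmax(cfg@fdBase + rnorm(Tn, 0, cfg@fdNoiseSd) -
             cfg@fdEngagementWeight * engagement[i], 1e-3)
    })
    cohort@scores <- scores
    cohort@alignment <- align
    cohort@fdTraces <- fd
  })
  cohort
}
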