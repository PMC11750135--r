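# Shared fixtures and independent oracles for the test suite. The oracles
# are deliberately naive (exhaustive enumeration, Floyd-Warshall, direct
# formula evaluation) and never call the code paths they check.

makeSeries <- function(data, id = "s1", tr = 2, narrative = "n1",
                       condition = "task") {
  new("NetworkTimeSeries", subjectId = id, data = as.matrix(data), tr = tr,
      narrative = narrative, condition = condition)
}

# small random HMM instance (means/covs/transition/initial) for oracles
randomModel <- function(k, N, seed) {
  set.seed(seed)
  means <- matrix(rnorm(k * N, sd = 2), k, N)
  covs <- array(0, c(N, N, k))
  for (j in seq_len(k)) {
    A <- matrix(rnorm(N * N, sd = 0.3), N, N)
    covs[, , j] <- crossprod(A) + diag(N)
  }
  A <- matrix(runif(k * k) + 0.2, k, k)
  A <- A / rowSums(A)
  pinit <- runif(k) + 0.2
  new("GaussianHMM", k = as.integer(k), means = means, covs = covs,
      transition = A, initial = pinit / sum(pinit), evidence = 0,
      loglikTrace = numeric(0), converged = TRUE, nRestarts = 1L,
      seed = as.integer(seed), networks = sprintf("net%d", seq_len(N)))
}

mvnLogDens <- function(x, mu, S) {
  N <- length(mu)
  -0.5 * (N * log(2 * pi) + determinant(S)$modulus[1] +
            mahalanobis(matrix(x, 1), mu, S))
}

# exhaustive-path oracle: exact posteriors, loglik and best path by
# enumerating all k^T state sequences
enumeratePosterior <- function(X, model) {
  Tn <- nrow(X)
  k <- model@k
  logB <- sapply(seq_len(k), function(j)
    apply(X, 1, mvnLogDens, mu = model@means[j, ], S = model@covs[, , j]))
  logB <- matrix(logB, Tn, k)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), Tn)))
  logp <- apply(paths, 1, function(p) {
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
  best <- which(logp == max(logp))[1]  # enumeration order = lower-index first
  list(gamma = gamma, loglik = M + log(sum(w)), path = paths[best, ],
       logp = logp)
}

# all-pairs shortest paths by Floyd-Warshall on 1/weight lengths
efficiencyOracle <- function(fc) {
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

# tiny standard cohort used across module tests
tinyCohort <- function(n = 6, Tn = 120, seed = 1, ...) {
  simulateCohort(defaultGroundTruth(nSubjects = n, nTimepoints = Tn,
                                    seed = seed, ...))
}

# white-noise cohort with independent columns (no latent structure)
nullCohort <- function(n, Tn, N = 9, seed = 1) {
  series <- withSeed(seed, lapply(seq_len(n), function(i) {
    makeSeries(zscoreColsOracle(matrix(rnorm(Tn * N), Tn, N)),
               id = sprintf("null-%02d", i),
               narrative = sprintf("narrative%d", 1 + (i - 1) %% 3)
    )
  }))
  series
}

zscoreColsOracle <- function(x)
  apply(x, 2, function(v) (v - mean(v)) / sd(v))

withSeed <- brainstates:::withSeed
childSeed <- brainstates:::childSeed
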