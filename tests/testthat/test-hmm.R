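test_that("standardization z-scores columns and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 1, 0))
  s <- standardizeSeries(makeSeries(x))
  d <- seriesData(s)
  expect_equal(unname(colMeans(d)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(d, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(d[, "a"], (x[, "a"] - 2) / sd(x[, "a"]), ignore_attr = TRUE)
  expect_equal(seriesData(standardizeSeries(s)), d, tolerance = 1e-12)
  expect_error(standardizeSeries(makeSeries(cbind(a = c(1, 1, 1),
                                                  b = c(1, 2, 3)))),
               "zero-variance network: a")
})

test_that("k = 1 fit recovers the pooled closed form", {
  set.seed(7)
  X1 <- matrix(rnorm(60), 30, 2)
  X2 <- matrix(rnorm(40), 20, 2)
  m <- fitHMM(list(makeSeries(X1), makeSeries(X2, id = "s2")), k = 1,
              nRestarts = 2, seed = 1)
  X <- rbind(X1, X2)
  expect_equal(unname(stateMeans(m)[1, ]), unname(colMeans(X)),
               tolerance = 1e-8)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(stateCovs(m)[, , 1],
               crossprod(Xc) / nrow(X) + 1e-6 * diag(2), tolerance = 1e-8)
  expect_equal(transitionMatrix(m), matrix(1, 1, 1))
})

test_that("forward-backward posteriors match exhaustive enumeration", {
  for (seed in c(11, 12, 13, 14)) {
    set.seed(seed)
    k <- sample(2:3, 1)
    Tn <- sample(4:7, 1)
    model <- randomModel(k, N = 2, seed = seed)
    X <- matrix(rnorm(Tn * 2, sd = 1.5), Tn, 2)
    post <- posteriorProbs(makeSeries(X), model)
    oracle <- enumeratePosterior(X, model)
    expect_lt(max(abs(expressionProbs(post) - oracle$gamma)), 1e-10)
    expect_equal(post@loglik, oracle$loglik, tolerance = 1e-10)
    expect_equal(statePath(post), as.integer(oracle$path))
    expect_equal(unname(rowSums(expressionProbs(post))), rep(1, Tn),
                 tolerance = 1e-10)
  }
})

test_that("Viterbi handles its limit cases", {
  # uniform transition and initial: path factorizes into per-time argmax
  model <- randomModel(3, 2, seed = 21)
  model@transition <- matrix(1 / 3, 3, 3)
  model@initial <- rep(1 / 3, 3)
  set.seed(22)
  X <- matrix(rnorm(20), 10, 2)
  logB <- sapply(1:3, function(j)
    apply(X, 1, mvnLogDens, mu = model@means[j, ], S = model@covs[, , j]))
  expect_equal(statePath(viterbiPath(makeSeries(X), model)),
               as.integer(apply(logB, 1, which.max)))
  # k = 1: constant path, gamma all ones
  m1 <- randomModel(1, 2, seed = 23)
  p1 <- posteriorProbs(makeSeries(X), m1)
  expect_equal(statePath(p1), rep(1L, 10))
  expect_equal(expressionProbs(p1), matrix(1, 10, 1))
  # overwhelming emission evidence makes gamma one-hot
  m2 <- randomModel(2, 2, seed = 24)
  m2@means <- rbind(c(0, 0), c(100, 100))
  X2 <- matrix(c(0.1, -0.1, 0.05, 0.02), 2, 2)
  g <- expressionProbs(posteriorProbs(makeSeries(X2), m2))
  expect_equal(g[, 1], c(1, 1), tolerance = 1e-10)
})

test_that("EM evidence is non-decreasing and restarts pick the best", {
  coh <- tinyCohort(n = 4, Tn = 100, seed = 3)
  m <- fitHMM(cohortSeries(coh), k = 3, nRestarts = 3, seed = 5)
  expect_true(all(diff(m@loglikTrace) >
                    -1e-8 * (abs(m@loglikTrace[-1]) + 1)))
  expect_equal(modelEvidence(m), m@loglikTrace[length(m@loglikTrace)])
  expect_true(validObject(m))
})

test_that("fitting is deterministic and invariant to subject order", {
  coh <- tinyCohort(n = 5, Tn = 100, seed = 8)
  sl <- cohortSeries(coh)
  m1 <- fitHMM(sl, k = 3, nRestarts = 2, seed = 4)
  m2 <- fitHMM(sl, k = 3, nRestarts = 2, seed = 4)
  expect_identical(stateMeans(m1), stateMeans(m2))
  m3 <- fitHMM(sl[c(3, 1, 5, 2, 4)], k = 3, nRestarts = 2, seed = 4)
  m3 <- relabelModel(m3, alignStateLabels(m3, m1))
  expect_equal(stateMeans(m3), stateMeans(m1), tolerance = 1e-4)
  expect_equal(transitionMatrix(m3), transitionMatrix(m1), tolerance = 1e-4)
})

test_that("label alignment matches brute force over all permutations", {
  ref <- randomModel(3, 5, seed = 31)
  # reference with rows swapped: alignment returns the inverse swap
  cand <- ref
  swap <- c(2L, 3L, 1L)
  cand@means <- ref@means[swap, ]
  expect_equal(alignStateLabels(cand, ref), swap)
  expect_equal(alignStateLabels(ref, ref), 1:3)
  # random models: equals exhaustive search over the 6 permutations
  for (seed in 32:34) {
    a <- randomModel(3, 6, seed = seed)
    b <- randomModel(3, 6, seed = seed + 100)
    S <- outer(1:3, 1:3, Vectorize(function(i, j)
      cor(a@means[i, ], b@means[j, ])))
    perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    scores <- vapply(perms, function(p) sum(S[cbind(1:3, p)]), 0)
    expect_equal(alignStateLabels(a, b),
                 as.integer(perms[[which.max(scores)]]))
  }
  expect_error(alignStateLabels(randomModel(2, 3, 1), randomModel(3, 3, 1)),
               "same number of states")
})

test_that("relabelModel moves state parameters coherently", {
  m <- randomModel(3, 4, seed = 41)
  perm <- c(3L, 1L, 2L)  # candidate i plays reference role perm[i]
  r <- relabelModel(m, perm)
  for (i in 1:3) {
    expect_equal(r@means[perm[i], ], m@means[i, ])
    expect_equal(r@covs[, , perm[i]], m@covs[, , i])
    expect_equal(r@initial[perm[i]], m@initial[i])
  }
  expect_equal(r@transition[perm[1], perm[2]], m@transition[1, 2])
  expect_equal(relabelPath(c(1L, 2L, 3L, 1L), perm), c(3L, 1L, 2L, 3L))
})

test_that("well-separated emissions give near-perfect path recovery", {
  cfg <- defaultGroundTruth(nSubjects = 4, nTimepoints = 200, seed = 17)
  cfg@stateMeans <- cfg@stateMeans * 5
  for (j in 1:3) cfg@stateCovs[, , j] <- diag(9)
  coh <- simulateCohort(cfg)
  m <- fitHMM(cohortSeries(coh), k = 3, nRestarts = 3, seed = 2)
  m <- relabelModel(m, alignStateLabels(m, standardizedStateMeans(cfg)))
  acc <- mean(unlist(lapply(seq_len(4), function(i)
    statePath(posteriorProbs(cohortSeries(coh)[[i]], m)) ==
      truePaths(coh)[[i]])))
  expect_gte(acc, 0.98)
})

test_that("fitHMM validates its inputs", {
  coh <- tinyCohort(n = 3, Tn = 30, seed = 1)
  expect_error(fitHMM(cohortSeries(coh), k = 12, seed = 1),
               "not enough time points")
  short <- makeSeries(matrix(rnorm(20), 10, 2))
  expect_error(fitHMM(list(short, makeSeries(matrix(rnorm(30), 10, 3),
                                             id = "s2")), k = 2),
               "same number of networks")
})
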