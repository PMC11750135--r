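test_that("default ground truth has hub-structured, separable states", {
  cfg <- defaultGroundTruth()
  A <- transitionMatrix(cfg)
  expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-12)
  # both peripheral states prefer the hub over each other
  expect_gt(A[1, 2], A[1, 3])
  expect_gt(A[3, 2], A[3, 1])
  expect_equal(unname(hubAsymmetry(A)[c("dA", "dB")]), c(0.06, 0.06))
  # stationary mass concentrates on the hub state (eigen oracle)
  e <- eigen(t(A))
  pi0 <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi0 <- pi0 / sum(pi0)
  expect_equal(which.max(pi0), 2L)
  # spatially separable mean patterns
  mu <- stateMeans(cfg)
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(cor(mu[i, ], mu[j, ]), 0.5)
  # SPD covariances
  for (j in 1:3)
    expect_gt(min(eigen(stateCovs(cfg)[, , j])$values), 0)
})

test_that("simulated cohorts are reproducible and z-scored", {
  cfg <- defaultGroundTruth(nSubjects = 4, nTimepoints = 100)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(lapply(cohortSeries(a), seriesData),
                   lapply(cohortSeries(b), seriesData))
  expect_identical(truePaths(a), truePaths(b))
  for (s in cohortSeries(a)) {
    expect_equal(unname(colMeans(seriesData(s))), rep(0, 9),
                 tolerance = 1e-8)
    expect_equal(unname(apply(seriesData(s), 2, sd)), rep(1, 9),
                 tolerance = 1e-8)
  }
  expect_error(simulateCohort(
    defaultGroundTruth(narrativeDriveStrength = -1)), "nonnegative")
})

test_that("with no drives, occupancy approaches the stationary distribution", {
  cfg <- defaultGroundTruth(nSubjects = 1, nTimepoints = 10000,
                            couplingStrength = 0,
                            narrativeDriveStrength = 0, seed = 42)
  coh <- simulateCohort(cfg)
  e <- eigen(t(transitionMatrix(cfg)))
  pi0 <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi0 <- pi0 / sum(pi0)
  fo <- fractionalOccupancy(truePaths(coh)[[1]], 3)
  expect_lt(max(abs(fo - pi0)), 0.05)
})

test_that("empirical transition matrices of sampled chains are row-stochastic", {
  coh <- tinyCohort(n = 3, Tn = 200, seed = 9)
  for (p in truePaths(coh)) {
    tab <- table(factor(head(p, -1), 1:3), factor(p[-1], 1:3))
    emp <- tab / pmax(rowSums(tab), 1)
    expect_equal(unname(rowSums(emp)[rowSums(tab) > 0]),
                 rep(1, sum(rowSums(tab) > 0)), tolerance = 1e-12)
  }
})

test_that("subjects are exchangeable when drives and coupling vanish", {
  cfg <- defaultGroundTruth(nSubjects = 30, nTimepoints = 150,
                            couplingStrength = 0,
                            narrativeDriveStrength = 0, seed = 5)
  coh <- simulateCohort(cfg)
  ind <- sapply(truePaths(coh), function(p) as.numeric(p == 2))
  cc <- cor(ind)
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.02)
})

test_that("narrative drive strength raises within-narrative ISC monotonically", {
  iscAt <- function(drv) {
    vals <- sapply(1:10, function(sd0) {
      cfg <- defaultGroundTruth(nSubjects = 9, nTimepoints = 150,
                                narrativeDriveStrength = drv,
                                couplingStrength = 0, seed = sd0)
      coh <- simulateCohort(cfg)
      ind <- sapply(truePaths(coh), function(p) as.numeric(p == 2))
      within <- c()
      for (m in unique(narrativeLabels(coh))) {
        idx <- which(narrativeLabels(coh) == m)
        cc <- cor(ind[, idx])
        within <- c(within, cc[upper.tri(cc)])
      }
      mean(within)
    })
    mean(vals)
  }
  curve <- vapply(c(0, 0.5, 1.5), iscAt, 0)
  expect_true(all(diff(curve) > 0))
})

test_that("noise-free scores preserve the rank order of alignments", {
  cfg <- defaultGroundTruth(nSubjects = 9, nTimepoints = 120,
                            behaviorNoiseSd = 0, seed = 2)
  coh <- simulateBehavior(simulateCohort(cfg))
  expect_equal(order(comprehensionScores(coh)), order(coh@alignment))
  expect_true(all(comprehensionScores(coh) >= 0 &
                    comprehensionScores(coh) <= 100))
})

test_that("behaviour coupling yields positive alignment-score correlation", {
  rs <- vapply(1:20, function(sd0) {
    coh <- simulateBehavior(simulateCohort(
      defaultGroundTruth(nSubjects = 12, nTimepoints = 120, seed = sd0)))
    cor(coh@alignment, comprehensionScores(coh))
  }, 0)
  expect_gte(sum(rs > 0), 19)
})

test_that("FD traces decouple from scores when the engagement weight is zero", {
  rs <- vapply(1:20, function(sd0) {
    coh <- simulateBehavior(simulateCohort(
      defaultGroundTruth(nSubjects = 12, nTimepoints = 120, seed = sd0,
                         fdEngagementWeight = 0)))
    meanFD <- vapply(coh@fdTraces, mean, 0)
    cor(meanFD, comprehensionScores(coh))
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("nested ground truth splits macro-states into block-dominant sub-states", {
  nest <- nestedGroundTruth(defaultGroundTruth(nSubjects = 4))
  cfg <- nest$config
  expect_equal(nStates(cfg), 10L)
  A <- transitionMatrix(cfg)
  expect_equal(rowSums(A), rep(1, 10), tolerance = 1e-12)
  for (i in 1:10) {
    within <- sum(A[i, nest$macroOf == nest$macroOf[i]])
    expect_gt(within, 0.5)
  }
  expect_true(validObject(cfg))
})
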