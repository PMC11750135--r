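test_that("group FC averages per-subject correlations", {
  set.seed(3)
  x1 <- matrix(rnorm(30), 10, 3)
  x2 <- matrix(rnorm(30), 10, 3)
  fc <- groupFC(list(makeSeries(x1), makeSeries(x2, id = "s2")))
  expect_equal(fc, (cor(x1) + cor(x2)) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
  # perfectly correlated / anticorrelated pairs
  y <- cbind(1:10, 2 * (1:10), 10:1)
  fcy <- groupFC(list(makeSeries(y)))
  expect_equal(fcy[1, 2], 1)
  expect_equal(fcy[1, 3], -1)
  expect_error(groupFC(list(makeSeries(cbind(rep(1, 5), rnorm(5))))),
               "zero-variance")
})

test_that("global efficiency equals the Floyd-Warshall oracle", {
  # closed forms first
  expect_equal(globalEfficiency(matrix(1, 4, 4)), 1)
  path3 <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))
  expect_equal(globalEfficiency(path3), (1 + 1 + 1 / 2) / 3)
  # random weighted graphs vs oracle
  for (seed in 1:100) {
    set.seed(seed)
    fc <- matrix(runif(81, -0.3, 1), 9, 9)
    fc <- (fc + t(fc)) / 2
    diag(fc) <- 1
    expect_lt(abs(globalEfficiency(fc) - efficiencyOracle(fc)), 1e-10)
  }
  expect_error(globalEfficiency(matrix(1, 1, 1)), "at least 2 nodes")
})

test_that("adding an edge never decreases global efficiency", {
  for (seed in 1:50) {
    set.seed(seed)
    fc <- matrix(runif(36, 0, 1), 6, 6)
    fc <- (fc + t(fc)) / 2
    diag(fc) <- 1
    off <- which(upper.tri(fc), arr.ind = TRUE)
    drop <- off[sample.int(nrow(off), 1), ]
    fc2 <- fc
    fc2[drop[1], drop[2]] <- fc2[drop[2], drop[1]] <- 0
    expect_gte(globalEfficiency(fc) - globalEfficiency(fc2), -1e-12)
  }
})

test_that("two disconnected equal cliques give Q = 0.5 at gamma 1", {
  fc <- matrix(0, 8, 8)
  fc[1:4, 1:4] <- 1
  fc[5:8, 5:8] <- 1
  diag(fc) <- 1
  res <- modularityQ(fc, gamma = 1, nRuns = 20, seed = 2)
  expect_equal(res$q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(res$labels)), 2L)
  expect_equal(res$labels[1:4], rep(res$labels[1], 4))
  # fully connected uniform graph has (near) no modular structure
  full <- matrix(1, 8, 8)
  expect_lte(modularityQ(full, nRuns = 20, seed = 3)$q, 0.05)
})

test_that("z-Rand behaves as an agreement score", {
  a <- rep(1:3, each = 10)
  selfz <- zRandScore(a, a)
  # invariant to label permutation
  expect_equal(zRandScore(a, c(2L, 3L, 1L)[a]), selfz)
  # self-agreement beats any non-trivial relabelling
  set.seed(4)
  for (r in 1:20) expect_lte(zRandScore(a, sample(a)), selfz)
  # independent random partitions center near zero
  set.seed(5)
  zs <- replicate(1000, zRandScore(sample(1:4, 40, TRUE),
                                   sample(1:4, 40, TRUE)))
  expect_lt(abs(mean(zs)), 0.1)
})

test_that("louvain sweep recovers planted cliques and scores them", {
  fc <- matrix(0, 8, 8)
  fc[1:4, 1:4] <- 1
  fc[5:8, 5:8] <- 1
  diag(fc) <- 1
  parts <- louvainSweep(fc, gammas = c(1, 1.3), nRuns = 10, seed = 1)
  expect_length(parts, 2L)
  p1 <- parts[[1]]
  expect_equal(length(unique(p1@labels)), 2L)
  expect_equal(p1@labels[1:4], rep(p1@labels[1], 4))
  expect_equal(p1@q, 0.5, tolerance = 1e-12)
  # all runs identical on planted structure: pairwise z-Rand is maximal
  expect_equal(p1@zrandMean, zRandScore(p1@labels, p1@labels))
  expect_equal(p1@weightedScore, p1@q * p1@zrandMean)
  expect_true(!is.null(attr(parts, "bestIndex")))
})

test_that("state-specific FC isolates planted covariance structure", {
  set.seed(21)
  # path all one state: equals the full-series correlation
  x <- matrix(rnorm(200), 50, 4)
  s <- makeSeries(x)
  expect_equal(stateSpecificFC(s, rep(1L, 50), 1), cor(x))
  expect_error(stateSpecificFC(s, rep(1L, 50), 2), "insufficient occupancy")
  # planted: state-1 time points correlated, state-2 independent
  wins <- vapply(1:20, function(sd0) {
    set.seed(sd0)
    path <- rep(1:2, each = 40)
    z <- rnorm(40)
    x1 <- sapply(1:4, function(j) 0.8 * z + 0.6 * rnorm(40))
    x2 <- matrix(rnorm(160), 40, 4)
    ser <- makeSeries(rbind(x1, x2))
    f1 <- stateSpecificFC(ser, path, 1)
    f2 <- stateSpecificFC(ser, path, 2)
    mean(f1[upper.tri(f1)]) > mean(f2[upper.tri(f2)])
  }, TRUE)
  expect_true(all(wins))
})

test_that("state topology contrast finds the denser state more integrated", {
  hits <- vapply(1:5, function(sd0) {
    cfg <- defaultGroundTruth(nSubjects = 6, nTimepoints = 240, seed = sd0)
    # exaggerate the hub state's coupling so the contrast is identifiable
    # at this small n
    N <- 9
    cfg@stateCovs[, , 2] <- 0.4 * diag(N) + 0.6
    cfg@stateCovs[, , 1] <- 0.95 * diag(N) + 0.05
    cfg@stateCovs[, , 3] <- 0.95 * diag(N) + 0.05
    coh <- simulateCohort(cfg)
    m <- fitHMM(cohortSeries(coh), 3, nRestarts = 2, seed = sd0)
    m <- relabelModel(m, alignStateLabels(m, standardizedStateMeans(cfg)))
    posts <- lapply(cohortSeries(coh), posteriorProbs, model = m)
    topo <- stateTopologyContrast(cohortSeries(coh), posts, m,
                                  nRuns = 5, seed = sd0)
    g <- colMeans(topo$geff, na.rm = TRUE)
    q <- colMeans(topo$q, na.rm = TRUE)
    md <- topo$modelDerived
    # subject-level and model-derived contrasts agree in sign
    g[2] > max(g[1], g[3]) && q[2] < min(q[1], q[3]) &&
      md$geff[2] > max(md$geff[1], md$geff[3])
  }, TRUE)
  expect_gte(sum(hits), 4)
})
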