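test_that("the canonical HRF peaks at 6 s with a late undershoot", {
  t <- seq(0, 32, by = 0.1)
  h <- canonicalHRF(t)
  expect_equal(t[which.max(h)], 6, tolerance = 0.2)
  expect_equal(max(h), 1)
  expect_lt(min(h), 0)                      # undershoot exists
  expect_gt(t[which.min(h)], 10)            # and is late
  expect_equal(canonicalHRF(c(0, 33)), c(0, 0))
})

test_that("the Hilbert envelope recovers amplitude structure", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  # pure sine of amplitude A: envelope constant at A
  A <- 0.7
  env <- hilbertEnvelope(A * sin(2 * pi * 50 * t), fs)
  inner <- env[200:1800]
  expect_lt(max(abs(inner - A)), 0.01 * A)
  # AM carrier: envelope tracks |modulator|
  m <- 1 + 0.8 * sin(2 * pi * 1.5 * t)
  env2 <- hilbertEnvelope(m * sin(2 * pi * 100 * t), fs)
  expect_gt(cor(env2[100:1900], m[100:1900]), 0.99)
  expect_equal(hilbertEnvelope(rep(0, 100), fs), rep(0, 100))
  expect_error(hilbertEnvelope(numeric(0), fs), "at least 2")
})

test_that("an impulse regressor is the sampled HRF peaking 6 s post-onset", {
  reg <- hrfRegressor(1, nativeRate = 10, nTime = 30, tr = 2, onsets = 20,
                      name = "impulse")
  v <- regressorValues(reg)
  expect_length(v, 30L)
  expect_lt(max(abs(v[1:10])), 1e-10)       # nothing before onset
  peakT <- (which.max(v) - 0.5) * 2         # bin centre, seconds
  expect_lt(abs(peakT - 20 - 6), 1 + 1)     # peak at onset + 6 s (1 TR grid)
  # all-zero input stays zero; a 600 s run at TR 2 gives 300 samples
  expect_equal(regressorValues(hrfRegressor(rep(0, 100), 10, 300)),
               rep(0, 300))
  expect_error(hrfRegressor(1, 10, 30, onsets = 70), "beyond run end")
})

test_that("HRF convolution is linear", {
  set.seed(8)
  a <- rnorm(200); b <- rnorm(200)
  ra <- regressorValues(hrfRegressor(a, 10, 10))
  rb <- regressorValues(hrfRegressor(b, 10, 10))
  rab <- regressorValues(hrfRegressor(a + b, 10, 10))
  expect_equal(rab, ra + rb, tolerance = 1e-10)
})

test_that("semantic coherence follows cosine identities and a PCA oracle", {
  v <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0))
  coh <- semanticCoherence(v, nPcs = NULL)
  expect_equal(coh, c(1, 0, 1), tolerance = 1e-12)
  # hand PCA oracle: centre, SVD, project to 2 PCs, cosine chain
  set.seed(12)
  w <- matrix(rnorm(15), 5, 3)
  ctr <- sweep(w, 2, colMeans(w))
  sv <- svd(ctr)
  proj <- ctr %*% sv$v[, 1:2]
  expected <- sapply(2:5, function(i)
    sum(proj[i, ] * proj[i - 1, ]) /
      (sqrt(sum(proj[i, ]^2)) * sqrt(sum(proj[i - 1, ]^2))))
  expect_equal(semanticCoherence(w, nPcs = 2), expected, tolerance = 1e-10)
  expect_error(semanticCoherence(w[1, , drop = FALSE]), "at least 2")
  expect_error(semanticCoherence(rbind(c(1, 1), c(-1, -1), c(0, 0)),
                                 nPcs = 1), "zero-norm")
})

test_that("clause embeddings average member words", {
  v <- rbind(c(1, 0), c(3, 2), c(5, 5))
  ce <- clauseEmbeddings(v, onsets = c(0, 1, 4), clauseIds = c(1, 1, 2))
  expect_equal(ce$vectors, rbind(c(2, 1), c(5, 5)))
  expect_equal(ce$onsets, c(0, 4))
})

test_that("modulation test validates input and centres its null", {
  set.seed(30)
  gam <- lapply(1:8, function(i) {
    g <- matrix(runif(150), 50, 3)
    g / rowSums(g)
  })
  expect_error(modulationTest(rep(1, 50), gam, 1, nPerm = 10), "constant")
  reg <- rnorm(50)
  res <- modulationTest(reg, gam, 2, nPerm = 400, seed = 9)
  expect_lt(abs(res$nullMean), 0.02)
  expect_true(res$empiricalP > 0 && res$empiricalP <= 1)
  # determinism
  res2 <- modulationTest(reg, gam, 2, nPerm = 400, seed = 9)
  expect_identical(res$empiricalP, res2$empiricalP)
  # per-subject regressor lists are accepted
  regs <- lapply(1:8, function(i) rnorm(50))
  res3 <- modulationTest(regs, gam, 1, nPerm = 50, seed = 2)
  expect_true(is.finite(res3$meanR))
  expect_error(modulationTest(regs[1:3], gam, 1), "one regressor per")
})

test_that("the FFT shift-correlation equals direct circular shifting", {
  set.seed(33)
  for (r in 1:5) {
    Tn <- sample(20:60, 1)
    x <- rnorm(Tn); y <- rnorm(Tn)
    direct <- vapply(0:(Tn - 1), function(s) cor(x, circularShift(y, s)), 0)
    expect_equal(brainstates:::allShiftCor(x, y), direct,
                 tolerance = 1e-12)
  }
})

test_that("modulation scan corrects over the feature-state family", {
  set.seed(31)
  gam <- lapply(1:6, function(i) {
    g <- matrix(runif(90), 30, 3)
    g / rowSums(g)
  })
  regs <- list(a = rnorm(30), b = rnorm(30))
  sc <- modulationScan(regs, gam, nPerm = 50, seed = 3)
  expect_equal(nrow(sc), 6L)
  expect_equal(sc$fdrQ, p.adjust(sc$tP, "BH"))
  expect_equal(sc$fdrQEmpirical, p.adjust(sc$empiricalP, "BH"))
})
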