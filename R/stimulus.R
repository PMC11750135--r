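#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with response peak at 6 s, undershoot
#' peak at 16 s and a 6:1 response-to-undershoot ratio, truncated at 32 s
#' and scaled to unit peak.
#'
#' @param t time points in seconds (nonnegative).
#' @return HRF values at `t`.
#' @export
canonicalHRF <- function(t) {
  stopifnot(all(t >= 0))
  resp <- t^6 * exp(-t) / gamma(7)       # gamma(shape 7, rate 1): mode 6 s
  under <- t^16 * exp(-t) / gamma(17)    # gamma(shape 17, rate 1): mode 16 s
  h <- resp - under / 6
  h[t > 32] <- 0
  peak <- 6^6 * exp(-6) / gamma(7) - 6^16 * exp(-6) / (6 * gamma(17))
  h / peak
}

#' Amplitude envelope of a sound waveform
#'
#' Magnitude of the analytic signal (Hilbert transform via FFT), smoothed
#' with a 50 ms moving average: the slow amplitude contour of the speech
#' signal.
#'
#' @param waveform numeric samples.
#' @param fs sampling rate in Hz.
#' @param smoothMs moving-average window in milliseconds (default 50).
#' @return envelope at the native rate.
#' @export
hilbertEnvelope <- function(waveform, fs, smoothMs = 50) {
  n <- length(waveform)
  if (n < 2L) stop("waveform must contain at least 2 samples")
  if (fs <= 0) stop("fs must be positive")
  f <- fft(waveform)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(fft(f * h, inverse = TRUE) / n)
  w <- max(1L, round(fs * smoothMs / 1000))
  if (w > 1L) {
    sm <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2L))
    # shrink the window at the edges instead of dropping samples
    na <- which(is.na(sm))
    for (i in na) {
      lo <- max(1L, i - w %/% 2L); hi <- min(n, i + w %/% 2L)
      sm[i] <- mean(env[lo:hi])
    }
    env <- sm
  }
  env
}

#' Build an HRF-convolved stimulus regressor on the TR grid
#'
#' Either convolves a continuous native-rate feature signal with the
#' canonical HRF, or places item values as impulses at their onset times
#' first; the convolved signal is then down-sampled to the TR grid by
#' averaging within TR bins, yielding exactly `nTime` values.
#'
#' @param x continuous native-rate signal, or per-item values when
#'   `onsets` is given.
#' @param nativeRate sampling rate of the native grid, Hz.
#' @param nTime number of TR-grid time points of the run.
#' @param tr repetition time, seconds (default 2).
#' @param onsets optional item onset times in seconds (within the run).
#' @param name regressor name.
#' @return a [StimulusRegressor-class] with `hrfApplied = TRUE`.
#' @export
hrfRegressor <- function(x, nativeRate, nTime, tr = 2, onsets = NULL,
                         name = "custom") {
  duration <- nTime * tr
  nNative <- round(duration * nativeRate)
  if (is.null(onsets)) {
    signal <- rep(0, nNative)
    signal[seq_len(min(length(x), nNative))] <-
      x[seq_len(min(length(x), nNative))]
  } else {
    if (length(onsets) != length(x))
      stop("one onset per item value required")
    if (any(onsets < 0 | onsets >= duration))
      stop("onset beyond run end")
    signal <- rep(0, nNative)
    pos <- pmin(nNative, floor(onsets * nativeRate) + 1L)
    for (i in seq_along(pos)) signal[pos[i]] <- signal[pos[i]] + x[i]
  }
  hrf <- canonicalHRF(seq(0, 32, by = 1 / nativeRate))
  conv <- convolve(signal, rev(hrf), type = "open")[seq_len(nNative)]
  bins <- ceiling(seq_len(nNative) / (tr * nativeRate))
  bins <- pmin(bins, nTime)
  values <- as.numeric(tapply(conv, factor(bins, levels = seq_len(nTime)),
                              mean))
  values[is.na(values)] <- 0
  new("StimulusRegressor", name = name, values = values,
      nativeRate = nativeRate, tr = tr, hrfApplied = TRUE)
}

#' Semantic coherence of consecutive item embeddings
#'
#' Optionally projects the item embedding matrix onto its first `nPcs`
#' principal components (fit on the same items), then computes the cosine
#' similarity between every item's vector and the immediately preceding
#' item's. The first item has no predecessor and is dropped.
#'
#' @param vectors item x D embedding matrix.
#' @param nPcs number of principal components retained (default 50);
#'   `NULL` or `nPcs >= D` skips the projection and uses the raw vectors.
#' @return numeric vector of length `nrow(vectors) - 1`:
#'   `coherence[i] = cos(v[i + 1], v[i])` in projected space.
#' @export
semanticCoherence <- function(vectors, nPcs = 50L) {
  vectors <- as.matrix(vectors)
  nItems <- nrow(vectors)
  if (nItems < 2L) stop("need at least 2 items")
  D <- ncol(vectors)
  if (!is.null(nPcs) && nPcs < D) {
    if (nPcs > min(nItems - 1L, D))
      stop("nPcs exceeds the feasible number of components")
    pc <- prcomp(vectors, center = TRUE, scale. = FALSE)
    proj <- pc$x[, seq_len(nPcs), drop = FALSE]
  } else {
    proj <- vectors
  }
  nrm <- sqrt(rowSums(proj^2))
  if (any(nrm < 1e-300)) stop("zero-norm vector after projection")
  vapply(2:nItems, function(i)
    sum(proj[i, ] * proj[i - 1L, ]) / (nrm[i] * nrm[i - 1L]), 0)
}

#' Average word embeddings into clause embeddings
#'
#' Builds clause-level vectors by averaging the embedding vectors of the
#' words within each clause; the clause onset is its first word's onset.
#'
#' @param vectors word x D embedding matrix.
#' @param onsets word onset times, seconds (non-decreasing).
#' @param clauseIds integer clause id per word.
#' @return list with `vectors` (clause x D) and `onsets`.
#' @export
clauseEmbeddings <- function(vectors, onsets, clauseIds) {
  ids <- unique(clauseIds)
  v <- t(vapply(ids, function(cid)
    colMeans(vectors[clauseIds == cid, , drop = FALSE]),
    numeric(ncol(vectors))))
  list(vectors = v,
       onsets = vapply(ids, function(cid) min(onsets[clauseIds == cid]), 0))
}

# correlation of x with every circular shift of y at once, via the
# circular cross-covariance (FFT); allShiftCor(x, y)[s + 1] equals
# cor(x, circularShift(y, s)) exactly (shifting preserves y's moments)
allShiftCor <- function(x, y) {
  Tn <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  cross <- Re(fft(fft(xc) * Conj(fft(yc)), inverse = TRUE)) / Tn
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (denom < 1e-300) rep(0, Tn) else cross / denom
}

# `valuesList` carries one regressor vector per subject (subjects in
# different narrative groups have different feature time courses)
modulationOne <- function(valuesList, gammas, state, nPerm, seed) {
  Tn <- length(valuesList[[1]])
  n <- length(gammas)
  # per subject, correlations with the observed and every shifted column
  cc <- vapply(seq_len(n), function(i) {
    col <- gammas[[i]][, state]
    if (sd(col) < 1e-12) rep(0, Tn)
    else allShiftCor(valuesList[[i]], col)
  }, numeric(Tn))
  rs <- cc[1L, ]
  meanR <- mean(rs)
  tt <- t.test(rs, mu = 0, alternative = "two.sided")
  offsets <- withSeed(seed, {
    matrix(sample.int(Tn - 1L, nPerm * n, replace = TRUE), nPerm, n)
  })
  nullMeans <- vapply(seq_len(nPerm), function(p)
    mean(cc[cbind(offsets[p, ] + 1L, seq_len(n))]), 0)
  list(meanR = meanR, tP = tt$p.value, tStat = unname(tt$statistic),
       empiricalP = (1 + sum(nullMeans >= meanR)) / (1 + nPerm),
       rawProportion = mean(nullMeans >= meanR),
       nullMean = mean(nullMeans))
}

regressorToList <- function(regressor, n) {
  one <- function(r) {
    v <- if (is(r, "StimulusRegressor")) r@values else as.numeric(r)
    if (sd(v) < 1e-12) stop("constant regressor")
    v
  }
  if (is.list(regressor) && !is(regressor, "StimulusRegressor")) {
    if (length(regressor) != n)
      stop("need one regressor per subject")
    lapply(regressor, one)
  } else {
    rep(list(one(regressor)), n)
  }
}

#' Stimulus-feature modulation of state expression
#'
#' Per-subject Pearson correlation between a feature regressor and the
#' expression probability of a state, summarized by the group mean,
#' a two-tailed one-sample t-test against zero, and an empirical p-value
#' from a circular-shift permutation null: on each permutation every
#' subject's expression time course is circularly shifted by an
#' independent uniform offset and the group-mean correlation recomputed.
#'
#' @param regressor a [StimulusRegressor-class], a numeric vector on the
#'   TR grid (shared by all subjects), or a list with one regressor per
#'   subject (subjects exposed to different narratives).
#' @param gammas list of per-subject T x k gamma matrices (or
#'   [StatePosterior-class] objects).
#' @param state state index to test.
#' @param nPerm number of permutations (default 5000).
#' @param seed integer seed.
#' @return list with `meanR`, `tStat`, `tP`, `empiricalP` (add-one),
#'   `rawProportion`, `nullMean`.
#' @export
modulationTest <- function(regressor, gammas, state, nPerm = 5000L,
                           seed = 1L) {
  gammas <- lapply(gammas, function(g)
    if (is(g, "StatePosterior")) g@gamma else g)
  valuesList <- regressorToList(regressor, length(gammas))
  if (nPerm < 1L) stop("at least one permutation required")
  if (any(vapply(gammas, nrow, 1L) != length(valuesList[[1]])))
    stop("regressor length must match the gamma time courses")
  modulationOne(valuesList, gammas, state, nPerm,
                childSeed(seed, "mod", state))
}

#' Modulation scan over all feature-state pairs with FDR correction
#'
#' Runs [modulationTest()] for every combination of the supplied feature
#' regressors and states, and applies Benjamini-Hochberg FDR correction
#' across the family to both the t-test and the empirical p-values.
#'
#' @param regressors named list of [StimulusRegressor-class] (or numeric
#'   vectors).
#' @param gammas list of per-subject T x k gamma matrices.
#' @param states states to test (default all columns).
#' @param nPerm permutations per test.
#' @param seed integer seed.
#' @return data frame with one row per (feature, state) pair: `meanR`,
#'   `tStat`, `tP`, `empiricalP`, `fdrQ` (BH over `tP`), `fdrQEmpirical`
#'   (BH over `empiricalP`).
#' @export
modulationScan <- function(regressors, gammas, states = NULL,
                           nPerm = 5000L, seed = 1L) {
  gammas <- lapply(gammas, function(g)
    if (is(g, "StatePosterior")) g@gamma else g)
  if (is.null(states)) states <- seq_len(ncol(gammas[[1]]))
  if (is.null(names(regressors)))
    names(regressors) <- sprintf("feature%d", seq_along(regressors))
  rows <- list()
  for (f in names(regressors)) for (s in states) {
    res <- modulationTest(regressors[[f]], gammas, s, nPerm = nPerm,
                          seed = childSeed(seed, f, s))
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, state = s, meanR = res$meanR, tStat = res$tStat,
      tP = res$tP, empiricalP = res$empiricalP,
      rawProportion = res$rawProportion)
  }
  out <- do.call(rbind, rows)
  out$fdrQ <- p.adjust(out$tP, method = "BH")
  out$fdrQEmpirical <- p.adjust(out$empiricalP, method = "BH")
  out
}
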