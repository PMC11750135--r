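#' Fractional occupancy of each state
#'
#' Fraction of time points a decoded path spends in each state; computed
#' from the Viterbi path.
#'
#' @param path integer state sequence with labels in 1..k.
#' @param k number of states.
#' @return length-k simplex vector.
#' @export
#' @examples
#' fractionalOccupancy(c(1, 1, 2, 2), k = 3)
fractionalOccupancy <- function(path, k) {
  path <- as.integer(path)
  if (!length(path)) stop("empty path")
  if (any(path < 1L | path > k)) stop("path labels must lie in 1..k")
  tabulate(path, k) / length(path)
}

#' Mean dwell time of each state
#'
#' Mean duration (seconds) of the contiguous runs of each state before it
#' switches to another one. States never visited are reported as `NA`
#' rather than zero.
#'
#' @param path integer state sequence.
#' @param tr sampling interval in seconds.
#' @param k number of states (default `max(path)`).
#' @return length-k vector of seconds, `NA` for unvisited states.
#' @export
#' @examples
#' meanDwellTime(c(1, 1, 2, 2, 2, 1), tr = 2, k = 2)
meanDwellTime <- function(path, tr, k = max(path)) {
  path <- as.integer(path)
  if (!length(path)) stop("empty path")
  r <- rle(path)
  out <- rep(NA_real_, k)
  for (s in seq_len(k)) {
    runs <- r$lengths[r$values == s]
    if (length(runs)) out[s] <- mean(runs) * tr
  }
  out
}

#' Transition-hub asymmetry of a transition matrix
#'
#' For a designated hub state and two peripheral states, the discrepancies
#' `d_a = P(perA -> hub) - P(perA -> perB)` and
#' `d_b = P(perB -> hub) - P(perB -> perA)`, and their mean. Positive
#' values mean each peripheral state prefers switching through the hub
#' over switching directly to the other peripheral state.
#'
#' @param transition k x k row-stochastic matrix (rows checked to 1e-6).
#' @param hub hub state index (default 2).
#' @param peripheral the two peripheral state indices (default `c(1, 3)`).
#' @return named vector `c(dA, dB, mean)`.
#' @export
hubAsymmetry <- function(transition, hub = 2L, peripheral = c(1L, 3L)) {
  if (any(abs(rowSums(transition) - 1) > 1e-6))
    stop("transition rows must sum to 1")
  idx <- c(hub, peripheral)
  if (anyDuplicated(idx)) stop("hub and peripheral states must be distinct")
  pA <- peripheral[1]; pB <- peripheral[2]
  dA <- transition[pA, hub] - transition[pA, pB]
  dB <- transition[pB, hub] - transition[pB, pA]
  c(dA = dA, dB = dB, mean = (dA + dB) / 2)
}

# detect a transitional hub in a k=3 transition matrix: a state receiving
# higher transition probability from both other states than they exchange
# directly; returns the mean asymmetry of the strongest hub, or 0 when no
# state qualifies (the convention used to build the surrogate null)
hubStatistic <- function(transition) {
  k <- nrow(transition)
  if (k < 3L) return(0)  # a hub needs two distinct peripheral states
  best <- 0
  for (h in seq_len(k)) {
    for (pair in utils::combn(setdiff(seq_len(k), h), 2L,
                              simplify = FALSE)) {
      a <- hubAsymmetry(transition, h, pair)
      if (a["dA"] > 0 && a["dB"] > 0 && a["mean"] > best)
        best <- unname(a["mean"])
    }
  }
  best
}

#' Surrogate null for the transition-hub asymmetry
#'
#' Builds surrogate cohorts by circularly shifting every network column of
#' every subject by an independent uniform offset (which preserves each
#' column's marginal and autocorrelation but destroys between-network
#' covariance), refits the HMM at the same k, and records the hub
#' statistic: when some state receives higher transition probability from
#' both other states than they exchange directly, the mean of the two
#' asymmetries; otherwise zero. The observed statistic is compared to
#' this null with the add-one empirical p-value convention (the raw
#' proportion is also reported).
#'
#' @param seriesList list of [NetworkTimeSeries-class] or a
#'   [SimulatedCohort-class].
#' @param k number of states (default 3).
#' @param nPerm number of surrogate permutations (at least 1).
#' @param nRestarts EM restarts per fit.
#' @param seed integer seed.
#' @param observedModel optional pre-fitted [GaussianHMM-class] for the
#'   observed cohort.
#' @param collectOccupancy also decode each surrogate cohort and record
#'   the per-permutation maxima of group-mean fractional occupancy and
#'   dwell time, for occupancy percentile comparisons (default TRUE).
#' @param tr sampling interval used for surrogate dwell times, seconds.
#' @return a [SurrogateNull-class].
#' @export
transitionSurrogateNull <- function(seriesList, k = 3L, nPerm = 1000L,
                                    nRestarts = 5L, seed = 1L,
                                    observedModel = NULL,
                                    collectOccupancy = TRUE, tr = 2) {
  if (is(seriesList, "SimulatedCohort")) seriesList <- seriesList@series
  if (nPerm < 1L) stop("at least one permutation required")
  if (is.null(observedModel))
    observedModel <- fitHMM(seriesList, k, nRestarts = nRestarts,
                            seed = childSeed(seed, "obs"))
  observed <- hubStatistic(observedModel@transition)
  Tn <- nrow(seriesList[[1]]@data)
  values <- numeric(nPerm)
  foValues <- dwellValues <- if (collectOccupancy) numeric(nPerm)
                             else numeric(0)
  nRedrawn <- 0L
  for (p in seq_len(nPerm)) {
    draw <- 0L
    repeat {
      shifted <- withSeed(childSeed(seed, "perm", p, draw), {
        lapply(seriesList, function(s) {
          s@data <- circularShift(s@data,
                                  sample.int(Tn - 1L, ncol(s@data),
                                             replace = TRUE))
          s
        })
      })
      fit <- tryCatch(
        fitHMM(shifted, k, nRestarts = nRestarts,
               seed = childSeed(seed, "permfit", p, draw)),
        error = function(e) NULL)
      if (!is.null(fit)) break
      nRedrawn <- nRedrawn + 1L
      draw <- draw + 1L
      if (draw > 20L) stop("surrogate fit failed repeatedly at permutation ", p)
    }
    values[p] <- hubStatistic(fit@transition)
    if (collectOccupancy) {
      paths <- lapply(shifted, function(s) statePath(posteriorProbs(s, fit)))
      fo <- t(vapply(paths, fractionalOccupancy, numeric(k), k = k))
      dw <- t(vapply(paths, meanDwellTime, numeric(k), tr = tr, k = k))
      foValues[p] <- max(colMeans(fo))
      dwellValues[p] <- max(colMeans(dw, na.rm = TRUE))
    }
  }
  new("SurrogateNull", nPerm = as.integer(nPerm), values = values,
      observed = observed,
      empiricalP = (1 + sum(values >= observed)) / (1 + nPerm),
      rawProportion = mean(values >= observed),
      foValues = foValues, dwellValues = dwellValues,
      nRedrawn = nRedrawn, seed = as.integer(seed))
}

#' Percentile of an observed value in a surrogate null
#'
#' Fraction of null values strictly below the observed value, matching the
#' "higher than x% of surrogate instances" convention.
#'
#' @param observed observed statistic (e.g. a state's fractional occupancy
#'   or dwell time).
#' @param nullValues non-empty numeric vector of surrogate values.
#' @return percentile in \[0, 1\].
#' @export
#' @examples
#' occupancySurrogatePercentile(3.5, c(1, 2, 3, 4))
occupancySurrogatePercentile <- function(observed, nullValues) {
  if (!length(nullValues)) stop("empty null distribution")
  mean(nullValues < observed)
}

#' Dynamics summary of a decoded cohort
#'
#' Per-subject fractional occupancy and mean dwell time from the Viterbi
#' paths, plus the model transition matrix and its hub asymmetry.
#'
#' @param posteriors list of [StatePosterior-class].
#' @param model the fitted [GaussianHMM-class].
#' @param tr sampling interval, seconds.
#' @param hub,peripheral hub and peripheral state indices for the
#'   asymmetry summary.
#' @return list with `fo` (subjects x k), `meanDwell` (subjects x k,
#'   seconds), `transition`, `hubAsym`.
#' @export
dynamicsSummary <- function(posteriors, model, tr = 2,
                            hub = 2L, peripheral = c(1L, 3L)) {
  k <- model@k
  fo <- t(vapply(posteriors, function(p) fractionalOccupancy(p@path, k),
                 numeric(k)))
  dw <- t(vapply(posteriors, function(p) meanDwellTime(p@path, tr, k),
                 numeric(k)))
  list(fo = fo, meanDwell = dw, transition = model@transition,
       hubAsym = hubAsymmetry(model@transition, hub, peripheral))
}
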