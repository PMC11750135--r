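#' Framewise displacement from rigid-body motion parameters
#'
#' Power convention: the sum of absolute backward differences of the three
#' translations (mm) plus 50 mm times the sum of absolute differences of
#' the three rotations (radians, small-angle arc length on a 50 mm head
#' radius). The first frame is zero.
#'
#' @param motion T x 6 matrix: translations x/y/z in mm, rotations
#'   pitch/roll/yaw in radians.
#' @param headRadius assumed head radius in mm (default 50).
#' @return length-T FD trace in mm.
#' @export
#' @examples
#' framewiseDisplacement(matrix(0, 5, 6))
framewiseDisplacement <- function(motion, headRadius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  if (nrow(motion) < 2L) stop("need at least 2 frames")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      headRadius * rowSums(d[, 4:6, drop = FALSE]))
}

#' Alignment of state expression with the best performer(s)
#'
#' Within each narrative group, the subject(s) with the highest
#' comprehension score are the best performers. Every other subject's
#' alignment is the Pearson correlation between their state expression
#' time course and each best performer's, averaged when the best score is
#' tied. Best performers are excluded from the returned sample.
#'
#' @param gammas list of per-subject T x k gamma matrices (or
#'   [StatePosterior-class]).
#' @param scores per-subject comprehension scores.
#' @param narrativeLabels per-subject narrative labels.
#' @param state state index.
#' @return list with `alignment` (named, non-best subjects only, in input
#'   order) and `isBest` (logical per subject).
#' @export
alignmentToBest <- function(gammas, scores, narrativeLabels, state) {
  gammas <- lapply(gammas, function(g)
    if (is(g, "StatePosterior")) g@gamma else g)
  n <- length(gammas)
  isBest <- logical(n)
  align <- rep(NA_real_, n)
  for (m in unique(narrativeLabels)) {
    idx <- which(narrativeLabels == m)
    if (length(idx) < 2L)
      stop("narrative ", m, " has a single subject")
    best <- idx[scores[idx] == max(scores[idx])]
    isBest[best] <- TRUE
    for (i in setdiff(idx, best)) {
      rs <- vapply(best, function(b)
        cor(gammas[[i]][, state], gammas[[b]][, state]), 0)
      align[i] <- mean(rs)
    }
  }
  out <- align[!isBest]
  names(out) <- sprintf("sub%03d", which(!isBest))
  list(alignment = out, isBest = isBest)
}

#' Leave-one-out alignment with the group-mean expression time course
#'
#' For each subject, the Pearson correlation between their state
#' expression time course and the average time course of the remaining
#' subjects (within the same narrative group when labels are supplied).
#'
#' @inheritParams alignmentToBest
#' @param narrativeLabels optional per-subject narrative labels; when
#'   `NULL` all subjects form one group.
#' @return per-subject alignment vector.
#' @export
alignmentToGroup <- function(gammas, state, narrativeLabels = NULL) {
  gammas <- lapply(gammas, function(g)
    if (is(g, "StatePosterior")) g@gamma else g)
  n <- length(gammas)
  if (is.null(narrativeLabels)) narrativeLabels <- rep("all", n)
  align <- numeric(n)
  cols <- sapply(gammas, function(g) g[, state])
  for (m in unique(narrativeLabels)) {
    idx <- which(narrativeLabels == m)
    if (length(idx) < 3L)
      stop("narrative ", m, " needs at least 3 subjects for leave-one-out")
    for (i in idx) {
      others <- rowMeans(cols[, setdiff(idx, i), drop = FALSE])
      align[i] <- cor(cols[, i], others)
    }
  }
  align
}

#' Correlation of alignment with behaviour, with optional motion control
#'
#' Pearson correlation between an alignment sample and comprehension
#' scores with a two-tailed p-value; when a covariate (e.g. the
#' inter-subject similarity of head-motion trajectories) is supplied, also
#' the partial correlation computed by the residual method — both
#' variables are regressed on the covariate and the residuals correlated —
#' with a t-based two-tailed p on n - 3 degrees of freedom.
#'
#' @param alignment per-subject alignment values.
#' @param scores matching comprehension scores.
#' @param covariate optional per-subject control variable.
#' @return list with `r`, `p`, `n`, and (given a covariate) `partialR`,
#'   `partialP`.
#' @export
behaviorCorrelation <- function(alignment, scores, covariate = NULL) {
  keep <- stats::complete.cases(alignment, scores,
                                if (is.null(covariate)) alignment
                                else covariate)
  x <- alignment[keep]; y <- scores[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 subjects")
  if (sd(x) < 1e-12 || sd(y) < 1e-12) stop("constant vector")
  ct <- cor.test(x, y)
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = n)
  if (!is.null(covariate)) {
    z <- covariate[keep]
    if (sd(z) < 1e-12) stop("constant covariate")
    rx <- residuals(lm(x ~ z))
    ry <- residuals(lm(y ~ z))
    if (sd(rx) < 1e-12 || sd(ry) < 1e-12)
      stop("zero residual variance after covariate adjustment")
    pr <- cor(rx, ry)
    tstat <- pr * sqrt((n - 3) / (1 - pr^2))
    out$partialR <- pr
    out$partialP <- 2 * pt(-abs(tstat), df = n - 3)
  }
  out
}

#' Inter-subject similarity of framewise-displacement trajectories
#'
#' Correlation of each non-best subject's FD trace with the best
#' performer(s)' traces within the narrative, averaged over ties: the
#' head-motion analogue of [alignmentToBest()], used as the engagement
#' covariate in [behaviorCorrelation()].
#'
#' @param fdTraces list of per-subject FD traces.
#' @param scores per-subject scores.
#' @param narrativeLabels per-subject narrative labels.
#' @return list with `alignment` (non-best subjects) and `isBest`.
#' @export
fdAlignmentToBest <- function(fdTraces, scores, narrativeLabels) {
  gam <- lapply(fdTraces, function(v) matrix(v, ncol = 1L))
  alignmentToBest(gam, scores, narrativeLabels, 1L)
}
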