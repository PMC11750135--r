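#' Circularly shift the columns of a matrix
#'
#' Rotates each column by its own offset, wrapping values from the end to
#' the start. Shifting preserves each column's marginal distribution and
#' autocorrelation structure while destroying its temporal alignment with
#' the other columns, which is what makes it the surrogate primitive used
#' throughout the permutation tests.
#'
#' @param x numeric matrix (or vector, treated as a one-column matrix).
#' @param shifts integer offset per column, recycled if scalar.
#' @return matrix (or vector) of the same shape.
#' @export
#' @examples
#' circularShift(matrix(1:6, ncol = 2), c(1, 2))
circularShift <- function(x, shifts) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  Tn <- nrow(x)
  shifts <- rep_len(as.integer(shifts) %% Tn, ncol(x))
  out <- x
  for (j in seq_len(ncol(x))) {
    s <- shifts[j]
    if (s > 0L) out[, j] <- x[c((Tn - s + 1L):Tn, 1L:(Tn - s)), j]
  }
  if (vec) out[, 1L] else out
}

# deterministic child seed derived from a master seed, kept within
# 32-bit integer range
childSeed <- function(seed, ...) {
  num <- function(x) {
    if (is.character(x)) vapply(x, function(s) sum(utf8ToInt(s)), 0)
    else as.numeric(x)
  }
  parts <- c(as.numeric(seed), unlist(lapply(list(...), num)))
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}

# run expr under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# column z-scoring with an informative error on constant columns
zscoreColumns <- function(x, tol = 1e-12) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  bad <- which(sdv < tol)
  if (length(bad)) {
    nm <- colnames(x)
    lab <- if (is.null(nm)) as.character(bad) else nm[bad]
    stop("zero-variance network: ", paste(lab, collapse = ", "))
  }
  sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
}

# smooth standardized random signal on a grid of length Tn: Gaussian
# random walk, moving-average low-passed, z-scored
smoothRandomSignal <- function(Tn, window = 10L) {
  w <- cumsum(rnorm(Tn))
  sm <- as.numeric(stats::filter(w, rep(1 / window, window), sides = 2L))
  idx <- which(!is.na(sm))
  sm[is.na(sm)] <- sm[c(rep(idx[1], idx[1] - 1),
                        rep(idx[length(idx)], Tn - idx[length(idx)]))]
  as.numeric(scale(sm))
}

# stationary distribution of a row-stochastic matrix via eigendecomposition
stationaryDistribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

logistic01 <- function(x) 1 / (1 + exp(-x))
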