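#' Write a cohort to delimited text files with a JSON manifest
#'
#' One tab-delimited file per subject (T rows x N named columns), stimulus
#' regressors as two-column TSV (`time_s`, `value`) per narrative and
#' feature, framewise-displacement traces as TSV, and a JSON manifest
#' recording subject ids, narratives, conditions, scores and relative file
#' paths.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  dir.create(file.path(dir, "regressors"), showWarnings = FALSE)
  dir.create(file.path(dir, "fd"), showWarnings = FALSE)
  cfg <- cohort@truth
  subjects <- lapply(seq_along(cohort@series), function(i) {
    s <- cohort@series[[i]]
    rel <- file.path("timeseries", paste0(s@subjectId, ".tsv"))
    write.table(s@data, file.path(dir, rel), sep = "\t", row.names = FALSE,
                quote = FALSE)
    fdRel <- NULL
    if (length(cohort@fdTraces)) {
      fdRel <- file.path("fd", paste0(s@subjectId, "_fd.tsv"))
      write.table(data.frame(fd_mm = cohort@fdTraces[[i]]),
                  file.path(dir, fdRel), sep = "\t", row.names = FALSE,
                  quote = FALSE)
    }
    entry <- list(subject_id = s@subjectId, narrative = s@narrative,
                  condition = s@condition, tr = s@tr, timeseries = rel)
    if (length(cohort@scores)) entry$score <- cohort@scores[i]
    if (!is.null(fdRel)) entry$fd <- fdRel
    entry
  })
  regFiles <- list()
  for (m in names(cohort@regressors)) {
    for (f in names(cohort@regressors[[m]])) {
      reg <- cohort@regressors[[m]][[f]]
      rel <- file.path("regressors", paste0(m, "_", f, ".tsv"))
      write.table(data.frame(
        time_s = (seq_along(reg@values) - 1) * reg@tr,
        value = reg@values), file.path(dir, rel), sep = "\t",
        row.names = FALSE, quote = FALSE)
      regFiles[[m]][[f]] <- rel
    }
  }
  manifest <- list(version = "1.0", tr = cfg@tr,
                   networks = cfg@networks, subjects = subjects,
                   regressors = regFiles)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a cohort from a manifest
#'
#' Reads the manifest written by [writeCohort()] (or assembled by hand for
#' real data), validates shapes, and rebuilds the series, regressors, FD
#' traces and scores. Errors name the offending subject.
#'
#' @param manifestPath path to `manifest.json`.
#' @return list with `series`, `narrativeLabels`, `conditions`, `scores`,
#'   `fdTraces`, `regressors`, `tr`, `networks`.
#' @export
loadCohort <- function(manifestPath) {
  if (!file.exists(manifestPath)) stop("manifest not found: ", manifestPath)
  man <- jsonlite::read_json(manifestPath, simplifyVector = FALSE)
  dir <- dirname(manifestPath)
  networks <- unlist(man$networks)
  series <- list(); fd <- list(); scores <- numeric(0)
  narratives <- character(0); conditions <- character(0)
  Tref <- NULL
  for (sub in man$subjects) {
    f <- file.path(dir, sub$timeseries)
    if (!file.exists(f))
      stop("missing time-series file for subject ", sub$subject_id)
    d <- as.matrix(read.table(f, header = TRUE, sep = "\t"))
    if (anyNA(d)) stop("NaN values in subject ", sub$subject_id)
    if (ncol(d) != length(networks))
      stop("subject ", sub$subject_id, " has ", ncol(d),
           " networks, expected ", length(networks))
    if (is.null(Tref)) Tref <- nrow(d)
    if (nrow(d) != Tref)
      stop("subject ", sub$subject_id, " has ", nrow(d),
           " time points, expected ", Tref)
    colnames(d) <- networks
    series[[length(series) + 1L]] <-
      new("NetworkTimeSeries", subjectId = sub$subject_id, data = d,
          tr = as.numeric(sub$tr), narrative = sub$narrative,
          condition = sub$condition)
    narratives <- c(narratives, sub$narrative)
    conditions <- c(conditions, sub$condition)
    scores <- c(scores, if (is.numeric(sub$score)) as.numeric(sub$score)
                        else NA_real_)
    if (is.character(sub$fd) && length(sub$fd) == 1L) {
      fdTab <- read.table(file.path(dir, sub$fd), header = TRUE, sep = "\t")
      fd[[length(fd) + 1L]] <- fdTab[[1]]
    }
  }
  regressors <- list()
  for (m in names(man$regressors)) {
    for (fn in names(man$regressors[[m]])) {
      tab <- read.table(file.path(dir, man$regressors[[m]][[fn]]),
                        header = TRUE, sep = "\t")
      regressors[[m]][[fn]] <- new("StimulusRegressor", name = fn,
                                   values = tab$value,
                                   tr = as.numeric(man$tr),
                                   nativeRate = 1 / as.numeric(man$tr),
                                   hrfApplied = TRUE)
    }
  }
  message(sprintf("loaded cohort: %d subjects x %d time points x %d networks; narratives: %s",
                  length(series), Tref, length(networks),
                  paste(unique(narratives), collapse = ", ")))
  list(series = series, narrativeLabels = narratives,
       conditions = conditions, scores = scores, fdTraces = fd,
       regressors = regressors, tr = as.numeric(man$tr),
       networks = networks)
}
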