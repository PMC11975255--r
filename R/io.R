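## Flat-file readers and writers: minute-level CSV, covariate CSV and
## JSON sidecars, so every pipeline stage can be inspected or replaced.

#' Write a cohort's minute-level data as CSV
#'
#' Long format: \code{subject_id, date, minute_of_day} (0-1439),
#' \code{count} (empty = missing), \code{wear}.
#'
#' @param cohort an [ActigraphyCohort-class] or named list of
#'   [MinuteSeries-class] objects.
#' @param path output file.
#' @export
writeMinuteCsv <- function(cohort, path) {
  series <- if (is(cohort, "ActigraphyCohort")) cohortSeries(cohort) else
    cohort
  rows <- lapply(series, function(s) {
    nd <- nDays(s)
    data.frame(subject_id = subjectId(s),
               date = rep(as.character(s@dates), each = MINUTES_PER_DAY),
               minute_of_day = rep(0:(MINUTES_PER_DAY - 1L), nd),
               count = as.vector(t(s@counts)),
               wear = as.vector(t(s@wear)),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
}

#' Read minute-level CSV into per-subject series
#'
#' Accepts the format written by [writeMinuteCsv()], or a long epoch
#' export with columns \code{subject_id} (optional for one subject),
#' \code{timestamp} (parseable date-time) and \code{count}; minute of day
#' and date are then derived from the timestamp.
#'
#' @param path input file.
#' @return Named list of [MinuteSeries-class] objects.
#' @export
readMinuteCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"minute_of_day" %in% names(df)) {
    if (!"timestamp" %in% names(df))
      stop("need either minute_of_day/date or timestamp columns")
    ts <- as.POSIXct(df$timestamp, tz = "UTC")
    df$date <- as.character(as.Date(ts))
    df$minute_of_day <- as.integer(format(ts, "%H")) * 60L +
      as.integer(format(ts, "%M"))
  }
  if (!"subject_id" %in% names(df)) df$subject_id <- "S1"
  out <- list()
  for (sid in unique(df$subject_id)) {
    d <- df[df$subject_id == sid, ]
    dates <- sort(unique(d$date))
    cm <- matrix(NA_real_, length(dates), MINUTES_PER_DAY)
    wm <- matrix(TRUE, length(dates), MINUTES_PER_DAY)
    di <- match(d$date, dates)
    mi <- d$minute_of_day + 1L
    cm[cbind(di, mi)] <- d$count
    if ("wear" %in% names(df)) wm[cbind(di, mi)] <- as.logical(d$wear)
    s <- minuteSeries(sid, cm, wear = wm, dates = as.Date(dates))
    out[[sid]] <- s
  }
  out
}

#' Write the subject covariate table
#'
#' @param subjects data.frame as in [subjectTable()].
#' @param path output file.
#' @export
writeCovariatesCsv <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE)
}

#' @rdname writeCovariatesCsv
#' @export
readCovariatesCsv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write generating-truth sidecar JSON
#'
#' Serializes the per-subject generating parameters of a synthetic
#' cohort (scalar parameters only; the minute-level state masks stay in
#' memory).
#'
#' @param cohort an [ActigraphyCohort-class].
#' @param path output file.
#' @export
writeTruthJson <- function(cohort, path) {
  tr <- lapply(cohortTruth(cohort), function(t) {
    p <- t$params
    c(p[vapply(p, function(v) is.numeric(v) && length(v) <= 2,
               logical(1))],
      list(trueMvpaMinPerDay = t$trueMvpaMinPerDay,
           trueLipaMinPerDay = t$trueLipaMinPerDay))
  })
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA)
}

#' Serialize a fitted fPCA model to JSON
#'
#' @param model an [FPCAModel-class].
#' @param path output file.
#' @export
writeFpcaJson <- function(model, path) {
  jsonlite::write_json(
    list(binWidth = model@binWidth, meanFn = model@meanFn,
         eigenvalues = model@eigenvalues,
         varExplained = model@varExplained,
         eigenfunctions = apply(model@eigenfunctions, 2, identity,
                                simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
}
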