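## Nonwear, valid-day, daylight-saving and subject-inclusion rules.
##
## Rules operate on minute-epoch data: a nonwear interval is a maximal run
## of >= 90 all-zero minutes (computed on the concatenated series so runs
## straddling midnight are caught), a valid day carries >= 1296 wear
## minutes (90% of 1440), and an included subject has >= 3 valid days.

VALID_DAY_MIN_WEAR <- 1296L
NONWEAR_MIN_RUN <- 90L
SUBJECT_MIN_VALID_DAYS <- 3L

#' Detect nonwear intervals
#'
#' Flags every maximal run of zero counts of length >= 90 minutes as
#' nonwear (\code{wear = FALSE}); all other minutes are wear.  Runs are
#' computed on the day-concatenated series, so an episode straddling
#' midnight is detected even if neither within-day part reaches 90
#' minutes.  Missing minutes break zero runs (a missing observation is not
#' evidence of zero movement).
#'
#' @param series a [MinuteSeries-class].
#' @return The series with its wear matrix set.
#' @export
detectNonwear <- function(series) {
  v <- as.vector(t(series@counts))
  isZero <- !is.na(v) & v == 0
  r <- rle(isZero)
  wear <- rep(TRUE, length(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values & r$lengths >= NONWEAR_MIN_RUN
  for (i in which(hit)) wear[starts[i]:ends[i]] <- FALSE
  series@wear <- matrix(wear, ncol = MINUTES_PER_DAY, byrow = TRUE)
  series
}

wearMinutesPerDay <- function(series) {
  rowSums(series@wear & !is.na(series@counts))
}

#' Mark valid days
#'
#' A day is valid iff it carries at least 1296 wear minutes (90% of the
#' day).  Wear minutes are worn, non-missing minute slots; minutes imputed
#' by [resolveDst()] count as wear.
#'
#' @param series a [MinuteSeries-class] with nonwear detected.
#' @return The series with per-day \code{valid} flags set.
#' @export
markValidDays <- function(series) {
  series@valid <- wearMinutesPerDay(series) >= VALID_DAY_MIN_WEAR
  series
}

#' Resolve daylight-saving transitions
#'
#' Fall-back (repeated) hours are replaced by the minute-wise mean of
#' their two observed copies.  Spring-forward (missing) hours are imputed
#' minute-wise by the mean of the same minute of day over the subject's
#' other valid days; imputed minutes count as wear.  If the subject has no
#' other valid source day, the hour is left missing and the series is
#' flagged (attribute \code{dstUnresolved}).
#'
#' @param series a [MinuteSeries-class] with validity marked
#'   (imputation draws only on valid days).
#' @return The series with duplicates averaged, missing hours imputed and
#'   validity re-marked.
#' @export
resolveDst <- function(series) {
  ## fall back: average the duplicated hour's two copies
  for (b in series@dupBlocks) {
    orig <- series@counts[b$day, b$minutes]
    series@counts[b$day, b$minutes] <- (orig + b$values) / 2
  }
  series@dupBlocks <- list()

  ## spring forward: impute missing minutes from the other valid days
  unresolved <- FALSE
  fwdDays <- unique(series@dstEvents$day[
    series@dstEvents$direction == "forward"])
  for (d in fwdDays) {
    miss <- which(is.na(series@counts[d, ]))
    if (!length(miss)) next
    src <- which(series@valid %in% TRUE & seq_len(nDays(series)) != d)
    if (!length(src)) { unresolved <- TRUE; next }
    for (m in miss) {
      vals <- series@counts[src, m]
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        series@counts[d, m] <- mean(vals)
        series@wear[d, m] <- TRUE
      } else unresolved <- TRUE
    }
  }
  series <- markValidDays(series)
  attr(series, "dstUnresolved") <- unresolved
  series
}

#' Exclusion record for a subject failing the inclusion rule
#'
#' @param subjectId subject identifier.
#' @param reason human-readable reason.
#' @param nValid number of valid days observed.
#' @return List of class \code{"ExclusionRecord"}.
#' @export
exclusionRecord <- function(subjectId, reason, nValid = NA_integer_) {
  structure(list(subjectId = subjectId, reason = reason,
                 nValid = nValid), class = "ExclusionRecord")
}

#' @rdname exclusionRecord
#' @param x object to test.
#' @export
isExcluded <- function(x) inherits(x, "ExclusionRecord")

#' Apply the subject-inclusion rule
#'
#' Retains only valid days and includes the subject iff at least three
#' remain; otherwise returns an [exclusionRecord()] stating the reason.
#'
#' @param series a [MinuteSeries-class] with validity marked.
#' @return A [CleanSeries-class] or an \code{ExclusionRecord}.
#' @export
includeSubject <- function(series) {
  if (all(is.na(series@valid)))
    stop("mark validity before applying the inclusion rule")
  keep <- which(series@valid %in% TRUE)
  if (length(keep) < SUBJECT_MIN_VALID_DAYS)
    return(exclusionRecord(series@subjectId, "insufficient valid days",
                           length(keep)))
  new("CleanSeries", subjectId = series@subjectId,
      counts = series@counts[keep, , drop = FALSE],
      wear = series@wear[keep, , drop = FALSE],
      nValid = length(keep))
}

#' Full preprocessing of one series
#'
#' Nonwear detection, valid-day marking, daylight-saving resolution and
#' re-marking, in order.  Idempotent on already-processed series.
#'
#' @param series a [MinuteSeries-class].
#' @return The processed series (validity marked, DST resolved).
#' @export
preprocessSeries <- function(series) {
  series <- detectNonwear(series)
  series <- markValidDays(series)
  resolveDst(series)
}

#' Preprocess a cohort and apply the inclusion rule
#'
#' @param cohort an [ActigraphyCohort-class] or a list of
#'   [MinuteSeries-class] objects.
#' @return List with \code{clean} (named list of [CleanSeries-class]),
#'   \code{exclusions} (data.frame subject_id / reason / n_valid) and
#'   \code{log} (per-subject valid-day counts).
#' @export
preprocessCohort <- function(cohort) {
  series <- if (is(cohort, "ActigraphyCohort")) cohortSeries(cohort) else
    cohort
  clean <- list(); excl <- list(); logRows <- list()
  for (s in series) {
    p <- preprocessSeries(s)
    r <- includeSubject(p)
    nv <- sum(p@valid %in% TRUE)
    logRows[[subjectId(s)]] <- data.frame(
      subject_id = subjectId(s), n_days = nDays(s), n_valid = nv,
      included = !isExcluded(r), stringsAsFactors = FALSE)
    if (isExcluded(r)) {
      excl[[subjectId(s)]] <- data.frame(
        subject_id = r$subjectId, reason = r$reason, n_valid = r$nValid,
        stringsAsFactors = FALSE)
    } else clean[[subjectId(s)]] <- r
  }
  list(clean = clean,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(subject_id = character(), reason = character(),
                    n_valid = integer()),
       log = do.call(rbind, logRows))
}
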