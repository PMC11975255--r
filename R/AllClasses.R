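#' @import methods
#' @importFrom stats coef complete.cases cor glm lm median plogis qlogis
#'   qnorm quantile rbinom rlnorm rnorm runif sd setNames t.test var
#'   binomial chisq.test p.adjust pnorm
#' @importFrom utils head read.csv write.csv
NULL

MINUTES_PER_DAY <- 1440L

#' Intensity cut points for minute classification
#'
#' Holds the pair of activity-count thresholds separating nonactive, light
#' (LIPA) and moderate-to-vigorous (MVPA) minutes.  The reference
#' configuration is \code{nonactiveMax = 2000}, \code{mvpaMin = 6750}
#' (vector-magnitude counts per 60-s epoch): a minute is nonactive when its
#' count is \eqn{\le} \code{nonactiveMax}, MVPA when \eqn{>} \code{mvpaMin},
#' and LIPA otherwise.
#'
#' @slot nonactiveMax upper count bound (inclusive) of the nonactive class.
#' @slot mvpaMin lower count bound (exclusive) of the MVPA class.
#' @seealso [cutPoints()], [classifyMinute()], [calibrateCutPoints()]
#' @export
setClass("CutPoints",
  representation(nonactiveMax = "numeric", mvpaMin = "numeric"))

setValidity("CutPoints", function(object) {
  if (length(object@nonactiveMax) != 1L || length(object@mvpaMin) != 1L)
    return("nonactiveMax and mvpaMin must be scalars")
  if (!is.finite(object@nonactiveMax) || !is.finite(object@mvpaMin))
    return("cut points must be finite")
  if (object@nonactiveMax <= 0)
    return("nonactiveMax must be positive")
  if (object@nonactiveMax >= object@mvpaMin)
    return("nonactiveMax must be strictly below mvpaMin")
  TRUE
})

#' Construct intensity cut points
#'
#' @param nonactiveMax inclusive upper count of a nonactive minute
#'   (default 2000).
#' @param mvpaMin exclusive lower count of an MVPA minute (default 6750).
#' @return A [CutPoints-class] object.
#' @examples
#' cp <- cutPoints()
#' classifyMinute(c(2000, 2001, 6751), cp)
#' @export
cutPoints <- function(nonactiveMax = 2000, mvpaMin = 6750) {
  new("CutPoints", nonactiveMax = as.numeric(nonactiveMax),
      mvpaMin = as.numeric(mvpaMin))
}

#' @describeIn CutPoints-class inclusive nonactive upper bound.
#' @param object,x a \code{CutPoints} object.
#' @export
nonactiveMax <- function(object) object@nonactiveMax

#' @describeIn CutPoints-class exclusive MVPA lower bound.
#' @export
mvpaMin <- function(object) object@mvpaMin

setMethod("show", "CutPoints", function(object) {
  cat(sprintf(
    "CutPoints: nonactive <= %g < LIPA <= %g < MVPA (counts/min)\n",
    object@nonactiveMax, object@mvpaMin))
})

#' Minute-epoch activity count series for one subject
#'
#' The raw substrate of the pipeline: a days-by-1440 matrix of nonnegative
#' vector-magnitude activity counts (one column per minute of day, midnight
#' to 23:59), with a parallel wear-flag matrix and a per-day validity flag.
#' Missing observations (e.g. the hour skipped by a spring-forward
#' daylight-saving transition) are \code{NA}, never zero: a zero count means
#' "worn but no movement".
#'
#' A fall-back daylight-saving transition yields two observed values for
#' each minute of the repeated hour; the second copy is kept in
#' \code{dupBlocks} until [resolveDst()] averages the copies.
#'
#' @slot subjectId subject identifier.
#' @slot counts numeric matrix, days x 1440; \code{NA} = missing.
#' @slot wear logical matrix, days x 1440; \code{FALSE} where nonwear was
#'   detected.
#' @slot valid logical vector, one flag per day (\code{NA} until
#'   [markValidDays()] runs).
#' @slot dates the calendar date of each row.
#' @slot dstEvents data.frame with columns \code{day}, \code{direction}
#'   recording injected daylight-saving transitions.
#' @slot dupBlocks list of duplicate-hour records (\code{day},
#'   \code{minutes}, \code{values}) from fall-back transitions.
#' @seealso [minuteSeries()], [detectNonwear()], [markValidDays()],
#'   [resolveDst()], [includeSubject()]
#' @export
setClass("MinuteSeries",
  representation(subjectId = "character", counts = "matrix",
                 wear = "matrix", valid = "logical", dates = "Date",
                 dstEvents = "data.frame", dupBlocks = "list"))

setValidity("MinuteSeries", function(object) {
  d <- dim(object@counts)
  if (d[2] != MINUTES_PER_DAY)
    return("counts must have 1440 columns (one per minute of day)")
  if (!identical(dim(object@wear), d))
    return("wear must match counts in dimension")
  if (length(object@valid) != d[1])
    return("valid must have one flag per day")
  if (length(object@dates) != d[1])
    return("dates must have one entry per day")
  v <- object@counts
  if (any(v < 0, na.rm = TRUE))
    return("counts must be nonnegative (use NA for missing)")
  TRUE
})

#' Construct a minute-epoch series
#'
#' @param subjectId subject identifier.
#' @param counts days x 1440 matrix of counts (or a length-multiple-of-1440
#'   vector, reshaped row-wise by day); \code{NA} marks missing minutes.
#' @param wear optional logical matrix; defaults to all-\code{TRUE}.
#' @param dates optional vector of dates, one per day.
#' @return A [MinuteSeries-class] object with validity flags unset.
#' @export
minuteSeries <- function(subjectId, counts, wear = NULL, dates = NULL) {
  if (is.vector(counts)) {
    stopifnot(length(counts) %% MINUTES_PER_DAY == 0L)
    counts <- matrix(counts, ncol = MINUTES_PER_DAY, byrow = TRUE)
  }
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  nd <- nrow(counts)
  if (is.null(wear))
    wear <- matrix(TRUE, nd, MINUTES_PER_DAY)
  if (is.null(dates))
    dates <- as.Date("2022-01-01") + seq_len(nd) - 1L
  new("MinuteSeries", subjectId = as.character(subjectId), counts = counts,
      wear = wear, valid = rep(NA, nd), dates = as.Date(dates),
      dstEvents = data.frame(day = integer(), direction = character()),
      dupBlocks = list())
}

#' @describeIn MinuteSeries-class number of recorded days.
#' @export
nDays <- function(object) nrow(object@counts)

#' @describeIn MinuteSeries-class the subject identifier.
#' @export
subjectId <- function(object) object@subjectId

#' @describeIn MinuteSeries-class the days x 1440 count matrix.
#' @export
countsMatrix <- function(object) object@counts

#' @describeIn MinuteSeries-class the days x 1440 logical wear matrix.
#' @export
wearMatrix <- function(object) object@wear

#' @describeIn MinuteSeries-class per-day validity flags.
#' @export
validDays <- function(object) object@valid

setMethod("show", "MinuteSeries", function(object) {
  nv <- sum(object@valid, na.rm = TRUE)
  cat(sprintf("MinuteSeries '%s': %d day(s) x 1440 min; %s valid; %d DST event(s)\n",
              object@subjectId, nDays(object),
              if (all(is.na(object@valid))) "validity unmarked" else
                sprintf("%d day(s)", nv),
              nrow(object@dstEvents)))
})

#' Valid-day series of an included subject
#'
#' The post-inclusion form of a subject's data: only valid days (wear time
#' at least 1296 minutes) are retained, and the subject met the minimum of
#' three valid days.
#'
#' @slot subjectId subject identifier.
#' @slot counts valid-days x 1440 count matrix (DST-resolved).
#' @slot wear matching logical wear matrix.
#' @slot nValid number of valid days (>= 3).
#' @seealso [includeSubject()], [paFeatures()], [crFeatures()]
#' @export
setClass("CleanSeries",
  representation(subjectId = "character", counts = "matrix",
                 wear = "matrix", nValid = "integer"))

setValidity("CleanSeries", function(object) {
  if (object@nValid < 3L)
    return("an included subject must have >= 3 valid days")
  if (nrow(object@counts) != object@nValid)
    return("counts must hold exactly the valid days")
  if (!identical(dim(object@wear), dim(object@counts)))
    return("wear must match counts in dimension")
  TRUE
})

setMethod("show", "CleanSeries", function(object) {
  cat(sprintf("CleanSeries '%s': %d valid day(s)\n",
              object@subjectId, object@nValid))
})

#' @describeIn CleanSeries-class number of valid days.
#' @export
nValid <- function(object) object@nValid

#' Synthetic or observed actigraphy cohort
#'
#' Bundles per-subject minute series with the subject covariate table and
#' (for synthetic cohorts) the generating ground truth used by recovery
#' tests.
#'
#' @slot series named list of [MinuteSeries-class] objects.
#' @slot subjects data.frame with one row per subject: \code{subject_id},
#'   \code{group}, \code{age}, \code{sex}, \code{bmi}, \code{ipaq_met_min},
#'   \code{ipaq_category}.
#' @slot truth named list of per-subject generating parameters (empty for
#'   observed data).
#' @seealso [simulateCohort()], [preprocessCohort()]
#' @export
setClass("ActigraphyCohort",
  representation(series = "list", subjects = "data.frame", truth = "list"))

setValidity("ActigraphyCohort", function(object) {
  if (length(object@series) != nrow(object@subjects))
    return("one covariate row per series is required")
  ids <- vapply(object@series, subjectId, character(1))
  if (!identical(unname(ids), as.character(object@subjects$subject_id)))
    return("series order must match the subject table")
  TRUE
})

#' @describeIn ActigraphyCohort-class list of per-subject minute series.
#' @export
cohortSeries <- function(object) object@series

#' @describeIn ActigraphyCohort-class the subject covariate table.
#' @export
subjectTable <- function(object) object@subjects

#' @describeIn ActigraphyCohort-class per-subject generating truth.
#' @export
cohortTruth <- function(object) object@truth

setMethod("show", "ActigraphyCohort", function(object) {
  tab <- table(object@subjects$group)
  cat(sprintf("ActigraphyCohort: %d subject(s) [%s]\n",
              length(object@series),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

#' Functional PCA of diurnal activity profiles
#'
#' Eigen-decomposition of the between-subject covariance of mean diurnal
#' activity profiles.  Eigenfunctions are orthonormal with respect to the
#' Euclidean inner product on the binned grid and oriented by a
#' deterministic sign rule (positive integral, see [orientComponents()]).
#'
#' @slot meanFn mean diurnal profile on the binned grid.
#' @slot eigenfunctions grid-points x K orthonormal matrix.
#' @slot eigenvalues K nonnegative values, nonincreasing.
#' @slot scores subjects x K score matrix (centered-profile projections).
#' @slot varExplained proportion of total profile variance per component.
#' @slot binWidth grid resolution in minutes.
#' @slot subjectIds row identifiers of \code{scores}.
#' @seealso [fitFpca()], [orientComponents()]
#' @export
setClass("FPCAModel",
  representation(meanFn = "numeric", eigenfunctions = "matrix",
                 eigenvalues = "numeric", scores = "matrix",
                 varExplained = "numeric", binWidth = "integer",
                 subjectIds = "character"))

setValidity("FPCAModel", function(object) {
  K <- length(object@eigenvalues)
  if (ncol(object@eigenfunctions) != K || ncol(object@scores) != K ||
      length(object@varExplained) != K)
    return("component dimensions disagree")
  if (any(diff(object@eigenvalues) > 1e-8))
    return("eigenvalues must be nonincreasing")
  if (any(object@eigenvalues < -1e-8))
    return("eigenvalues must be nonnegative")
  G <- crossprod(object@eigenfunctions)
  if (max(abs(G - diag(K))) > 1e-6)
    return("eigenfunctions must be orthonormal")
  if (sum(object@varExplained) > 1 + 1e-8)
    return("variance-explained proportions must sum to at most 1")
  TRUE
})

#' @describeIn FPCAModel-class mean diurnal profile.
#' @param object an \code{FPCAModel}.
#' @export
meanFunction <- function(object) object@meanFn

#' @describeIn FPCAModel-class orthonormal eigenfunction matrix.
#' @export
eigenfunctions <- function(object) object@eigenfunctions

#' @describeIn FPCAModel-class component eigenvalues.
#' @export
eigenvalues <- function(object) object@eigenvalues

#' @describeIn FPCAModel-class subject score matrix.
#' @export
fpcaScores <- function(object) object@scores

#' @describeIn FPCAModel-class proportion of variance per component.
#' @export
varExplained <- function(object) object@varExplained

setMethod("show", "FPCAModel", function(object) {
  cat(sprintf("FPCAModel: %d subject(s), %d component(s) on a %d-min grid\n",
              nrow(object@scores), length(object@eigenvalues),
              object@binWidth))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * object@varExplained),
                    collapse = ", ")))
})

#' Joint and Individual Variation Explained decomposition
#'
#' Decomposition of two z-scored feature blocks (physical activity and
#' circadian rhythm) into joint variation shared across the blocks,
#' block-specific individual variation, and residual:
#' \eqn{X_k = J_k + A_k + E_k}, with the joint components of both blocks
#' sharing a common row (subject-score) space and each block's individual
#' row space orthogonal to it.
#'
#' @slot blockNames names of the blocks (e.g. \code{c("PA", "CR")}).
#' @slot jointRank rank of the joint structure.
#' @slot individualRanks named integer vector of per-block ranks.
#' @slot jointScores subjects x jointRank matrix (orthonormal basis of the
#'   shared row space, scaled to unit column SD on export).
#' @slot jointLoadings per-block feature x jointRank loading matrices.
#' @slot individualScores per-block subjects x rank score matrices.
#' @slot individualLoadings per-block feature x rank loading matrices.
#' @slot varDecomposition blocks x 3 matrix of variance proportions
#'   (joint, individual, residual).
#' @slot scaledBlocks the z-scored, block-scaled input matrices
#'   (subjects x features), retained for reconstruction checks.
#' @slot scaling per-block list of feature centers/scales and the block
#'   scale factor.
#' @slot iterations,converged fit diagnostics.
#' @slot subjectIds row identifiers of the score matrices.
#' @seealso [fitJive()], [selectJiveRanks()], [exportJiveScores()],
#'   [jiveLoadingReport()]
#' @export
setClass("JIVEModel",
  representation(blockNames = "character", jointRank = "integer",
                 individualRanks = "integer", jointScores = "matrix",
                 jointLoadings = "list", individualScores = "list",
                 individualLoadings = "list", varDecomposition = "matrix",
                 scaledBlocks = "list", scaling = "list",
                 iterations = "integer", converged = "logical",
                 subjectIds = "character"))

setValidity("JIVEModel", function(object) {
  if (length(object@blockNames) != 2L)
    return("exactly two blocks are supported")
  if (!identical(names(object@individualRanks), object@blockNames))
    return("individualRanks must be named by block")
  TRUE
})

#' @describeIn JIVEModel-class rank of the joint structure.
#' @param object a \code{JIVEModel}.
#' @export
jointRank <- function(object) object@jointRank

#' @describeIn JIVEModel-class named per-block individual ranks.
#' @export
individualRanks <- function(object) object@individualRanks

#' @describeIn JIVEModel-class blocks x (joint, individual, residual)
#'   variance proportions.
#' @export
varDecomposition <- function(object) object@varDecomposition

setMethod("show", "JIVEModel", function(object) {
  cat(sprintf("JIVEModel [%s]: joint rank %d; individual ranks %s\n",
              paste(object@blockNames, collapse = " + "),
              object@jointRank,
              paste(sprintf("%s=%d", names(object@individualRanks),
                            object@individualRanks), collapse = ", ")))
  vd <- object@varDecomposition
  for (b in rownames(vd))
    cat(sprintf("  %s: joint %.1f%%, individual %.1f%%, residual %.1f%%\n",
                b, 100 * vd[b, 1], 100 * vd[b, 2], 100 * vd[b, 3]))
})
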