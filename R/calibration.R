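## Cohort-specific intensity cut points.
##
## The reference configuration (nonactive <= 2000 < LIPA <= 6750 < MVPA)
## can be re-derived for a cohort by exhaustive grid search maximizing
## concordance between accelerometry-estimated activity and the subjects'
## self-reported IPAQ summaries.

#' Classify minutes into intensity classes
#'
#' @param count vector of minute counts (\code{NA} = missing).
#' @param cp a [CutPoints-class].
#' @return Factor with levels \code{nonactive}, \code{LIPA}, \code{MVPA};
#'   \code{NA} where the count is missing.
#' @examples
#' classifyMinute(c(0, 2000, 2001, 6750, 6751, NA), cutPoints())
#' @export
classifyMinute <- function(count, cp) {
  stopifnot(is(cp, "CutPoints"))
  if (any(count < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  out <- ifelse(count <= cp@nonactiveMax, "nonactive",
                ifelse(count > cp@mvpaMin, "MVPA", "LIPA"))
  factor(out, levels = c("nonactive", "LIPA", "MVPA"))
}

## mean minutes/day with count strictly above `thr`, over wear minutes
minutesAbovePerDay <- function(clean, thr) {
  x <- clean@counts[clean@wear & !is.na(clean@counts)]
  sum(x > thr) / clean@nValid
}

## Linear-weighted Cohen's kappa between two equal-length ordinal factors.
weightedKappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  lev <- union(levels(factor(a)), levels(factor(b)))
  k <- length(lev)
  if (k < 2) stop("weighted kappa undefined for a single category")
  a <- factor(a, levels = lev); b <- factor(b, levels = lev)
  O <- table(a, b) / length(a)
  pa <- rowSums(O); pb <- colSums(O)
  W <- 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  po <- sum(W * O)
  pe <- sum(W * outer(pa, pb))
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

tertiles <- function(x) {
  q <- quantile(x, c(1 / 3, 2 / 3), type = 7)
  cut(x, c(-Inf, q, Inf), labels = c("T1", "T2", "T3"))
}

#' Concordance between an accelerometry summary and IPAQ
#'
#' Average of (i) the Spearman correlation between the accelerometry MVPA
#' minutes/day and the IPAQ MET-minute summary and (ii) the linear-weighted
#' kappa between the tertiles of each.  Handles the continuous and ordinal
#' faces of the self-report with one statistic.
#'
#' @param mvpaPerDay per-subject MVPA minutes/day.
#' @param ipaqMetMin per-subject IPAQ MET-min/week.
#' @return Scalar concordance in \[-1, 1\].
#' @export
ipaqConcordance <- function(mvpaPerDay, ipaqMetMin) {
  if (length(unique(ipaqMetMin)) < 2)
    stop("degenerate IPAQ summaries: concordance undefined")
  rho <- suppressWarnings(cor(mvpaPerDay, ipaqMetMin,
                              method = "spearman"))
  if (is.na(rho)) rho <- 0
  kap <- weightedKappa(tertiles(mvpaPerDay), tertiles(ipaqMetMin))
  (rho + kap) / 2
}

#' Calibrate intensity cut points against IPAQ self-report
#'
#' Exhaustively evaluates a grid of (nonactive, MVPA) cut-point pairs; for
#' each pair computes per-subject MVPA and LIPA minutes/day and the
#' [ipaqConcordance()] of the MVPA summary with the IPAQ MET-minute
#' report, and returns the maximizing pair.  Ties are broken toward the
#' pair closest (Euclidean) to the reference (2000, 6750), then toward the
#' smaller thresholds.
#'
#' @param clean named list of [CleanSeries-class] objects.
#' @param records subject table with \code{subject_id} and
#'   \code{ipaq_met_min}.
#' @param nonactiveGrid candidate nonactive upper bounds (default
#'   500..4000 by 250).
#' @param mvpaGrid candidate MVPA lower bounds (default 4000..10000 by
#'   250).
#' @param reference tie-break anchor pair.
#' @return List of class \code{"CalibrationResult"}: \code{cutpoints}
#'   ([CutPoints-class]), \code{concordance}, and \code{grid} (one row per
#'   evaluated pair).
#' @export
calibrateCutPoints <- function(clean, records,
                               nonactiveGrid = seq(500, 4000, 250),
                               mvpaGrid = seq(4000, 10000, 250),
                               reference = c(2000, 6750)) {
  ids <- names(clean)
  m <- match(ids, records$subject_id)
  if (anyNA(m)) stop("every subject needs an IPAQ record")
  ipaq <- records$ipaq_met_min[m]
  if (length(unique(ipaq)) < 2)
    stop("degenerate IPAQ summaries: concordance undefined")

  ## per-subject wear counts, pooled once
  wearCounts <- lapply(clean, function(cl)
    cl@counts[cl@wear & !is.na(cl@counts)])
  nv <- vapply(clean, function(cl) as.numeric(cl@nValid), numeric(1))

  mvpaPerDay <- vapply(seq_along(mvpaGrid), function(j) {
    thr <- mvpaGrid[j]
    vapply(seq_along(wearCounts),
           function(i) sum(wearCounts[[i]] > thr) / nv[i], numeric(1))
  }, numeric(length(ids)))
  if (is.null(dim(mvpaPerDay)))
    mvpaPerDay <- matrix(mvpaPerDay, nrow = length(ids))

  grid <- expand.grid(nonactive_max = nonactiveGrid, mvpa_min = mvpaGrid)
  conc <- numeric(nrow(grid))
  for (j in seq_along(mvpaGrid)) {
    cj <- ipaqConcordance(mvpaPerDay[, j], ipaq)
    conc[grid$mvpa_min == mvpaGrid[j]] <- cj
  }
  grid$concordance <- conc

  best <- which(conc >= max(conc) - 1e-12)
  if (length(best) > 1) {
    d <- sqrt((grid$nonactive_max[best] - reference[1])^2 +
              (grid$mvpa_min[best] - reference[2])^2)
    best <- best[order(d, grid$nonactive_max[best],
                       grid$mvpa_min[best])][1]
  }
  res <- list(cutpoints = cutPoints(grid$nonactive_max[best],
                                    grid$mvpa_min[best]),
              concordance = grid$concordance[best],
              grid = grid)
  class(res) <- "CalibrationResult"
  res
}

#' @export
print.CalibrationResult <- function(x, ...) {
  cat(sprintf("CalibrationResult: nonactive <= %g, MVPA > %g (concordance %.3f over %d grid pairs)\n",
              nonactiveMax(x$cutpoints), mvpaMin(x$cutpoints),
              x$concordance, nrow(x$grid)))
  invisible(x)
}
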