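## Functional PCA of subjects' mean diurnal profiles.

#' Bin diurnal profiles to a coarser grid
#'
#' @param profiles subjects x 1440 matrix.
#' @param binWidth bin width in minutes (must divide 1440).
#' @return subjects x (1440 / binWidth) matrix of bin means.
#' @export
binProfiles <- function(profiles, binWidth = 10L) {
  stopifnot(MINUTES_PER_DAY %% binWidth == 0)
  nb <- MINUTES_PER_DAY %/% binWidth
  idx <- rep(seq_len(nb), each = binWidth)
  t(apply(profiles, 1, function(row) tapply(row, idx, mean)))
}

#' Fit functional PCA to diurnal profiles
#'
#' Profiles are binned to \code{binWidth}-minute resolution, centered by
#' the cross-subject mean function, and the sample covariance across
#' subjects is eigen-decomposed (via SVD of the centered matrix).  Scores
#' are projections of centered profiles onto the eigenfunctions.
#' Components are sign-oriented by [orientComponents()].
#'
#' @param profiles subjects x time matrix (1440 columns, or already
#'   binned); row names carry subject ids.
#' @param K number of components to retain (default 5).
#' @param binWidth bin width in minutes applied when \code{profiles} has
#'   1440 columns (default 10).
#' @return An [FPCAModel-class].
#' @export
fitFpca <- function(profiles, K = 5L, binWidth = 10L) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < K + 1) stop("fPCA needs at least K + 1 subjects")
  if (anyNA(profiles)) stop("profiles must be complete (impute upstream)")
  if (ncol(profiles) == MINUTES_PER_DAY && binWidth > 1L)
    profiles <- binProfiles(profiles, binWidth)
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  meanFn <- colMeans(profiles)
  Xc <- sweep(profiles, 2, meanFn)
  sv <- svd(Xc)
  evalsAll <- sv$d^2 / (n - 1)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  if (K > r) stop("K exceeds the rank of the centered profile matrix")
  efuns <- sv$v[, seq_len(K), drop = FALSE]
  scores <- Xc %*% efuns
  model <- new("FPCAModel", meanFn = meanFn, eigenfunctions = efuns,
               eigenvalues = evalsAll[seq_len(K)],
               scores = scores,
               varExplained = evalsAll[seq_len(K)] / sum(evalsAll),
               binWidth = as.integer(binWidth), subjectIds = ids)
  orientComponents(model)
}

componentSign <- function(phi) {
  s <- sum(phi)
  if (abs(s) > 1e-8 * sqrt(length(phi))) sign(s)
  else sign(phi[which.max(abs(phi))])
}

#' Fix eigenfunction signs by a deterministic convention
#'
#' Each eigenfunction is flipped, together with its scores, so that its
#' integral is positive (or, when the integral is near zero, so that its
#' value at the point of maximum magnitude is positive).  Signs of
#' principal components are otherwise arbitrary; the convention makes
#' fitted models comparable across runs.  Idempotent, and leaves every
#' reconstruction \eqn{\mu + \sum_k s_k \phi_k} unchanged.
#'
#' @param model an [FPCAModel-class].
#' @return The model with oriented components.
#' @export
orientComponents <- function(model) {
  for (k in seq_along(model@eigenvalues)) {
    s <- componentSign(model@eigenfunctions[, k])
    if (s < 0) {
      model@eigenfunctions[, k] <- -model@eigenfunctions[, k]
      model@scores[, k] <- -model@scores[, k]
    }
  }
  model
}

#' Cohort diurnal profile matrix
#'
#' Stacks per-subject [diurnalProfile()]s into a subjects x 1440 matrix
#' ready for [fitFpca()].
#'
#' @param clean named list of [CleanSeries-class] objects.
#' @param logScale use log(1+count) profiles.
#' @return Matrix with one row per subject.
#' @export
profileMatrix <- function(clean, logScale = FALSE) {
  mats <- lapply(clean, function(cl) {
    if (logScale) cl@counts <- log1p(cl@counts)
    diurnalProfile(cl)
  })
  out <- do.call(rbind, mats)
  rownames(out) <- names(clean)
  out
}
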