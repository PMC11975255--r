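## Joint and Individual Variation Explained (JIVE) for the physical
## activity (PA) and circadian rhythm (CR) feature blocks.
##
## Each block X_k (features x subjects, z-scored per feature then scaled
## to equal total variation) is decomposed as X_k = J_k + A_k + E_k where
## the joint parts J_k of both blocks share one row (subject) space, each
## individual part A_k has a row space orthogonal to the joint one, and
## E_k is residual.  Estimation alternates a truncated SVD of the stacked
## joint residual with per-block truncated SVDs of the individual
## residuals projected off the joint row space.

#' Prepare a feature block for JIVE
#'
#' Z-scores every feature (dropping zero-variance features with a
#' warning), mean-imputes missing entries with a warning, transposes to
#' features x subjects, and scales the block to unit Frobenius norm so
#' blocks with different feature counts carry equal total variation.
#'
#' @param df data.frame with \code{subject_id} plus numeric feature
#'   columns, or a numeric matrix (subjects x features).
#' @param name block name (\code{"PA"} or \code{"CR"}).
#' @param acrophaseAsSinCos replace an \code{Acrophase} column (clock
#'   hours) by its sine and cosine to avoid the 0/24 discontinuity.
#' @return List of class \code{"FeatureBlock"}: \code{name}, \code{X}
#'   (features x subjects), \code{featureNames}, \code{subjectIds},
#'   \code{scaling}.
#' @export
featureBlock <- function(df, name, acrophaseAsSinCos = TRUE) {
  if (is.data.frame(df)) {
    ids <- as.character(df$subject_id)
    M <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
    rownames(M) <- ids
  } else {
    M <- as.matrix(df)
    ids <- rownames(M)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(M)))
  }
  if (acrophaseAsSinCos && "Acrophase" %in% colnames(M)) {
    ang <- 2 * pi * M[, "Acrophase"] / 24
    M <- cbind(M[, colnames(M) != "Acrophase", drop = FALSE],
               Acrophase_sin = sin(ang), Acrophase_cos = cos(ang))
  }
  if (anyNA(M)) {
    warning("mean-imputing missing feature entries in block ", name)
    for (j in seq_len(ncol(M)))
      M[is.na(M[, j]), j] <- mean(M[, j], na.rm = TRUE)
  }
  ctr <- colMeans(M)
  scl <- apply(M, 2, sd)
  drop <- scl < 1e-12
  if (any(drop)) {
    warning("dropping zero-variance feature(s) in block ", name, ": ",
            paste(colnames(M)[drop], collapse = ", "))
    M <- M[, !drop, drop = FALSE]
    ctr <- ctr[!drop]; scl <- scl[!drop]
  }
  Z <- sweep(sweep(M, 2, ctr), 2, scl, "/")
  X <- t(Z)
  blockScale <- sqrt(sum(X^2))
  X <- X / blockScale
  structure(list(name = name, X = X, featureNames = rownames(X),
                 subjectIds = ids,
                 scaling = list(center = ctr, scale = scl,
                                blockScale = blockScale)),
            class = "FeatureBlock")
}

svdTrunc <- function(M, r) {
  if (r == 0L) return(matrix(0, nrow(M), ncol(M)))
  sv <- svd(M, nu = r, nv = r)
  sv$u %*% (diag(sv$d[seq_len(r)], r, r) %*% t(sv$v))
}

rightSingular <- function(M, r) {
  if (r == 0L) return(matrix(0, ncol(M), 0))
  svd(M, nu = 0, nv = r)$v
}

#' Fit the JIVE decomposition of the PA and CR blocks
#'
#' @param blocks list of two [featureBlock()]s with identical subjects in
#'   identical order.
#' @param jointRank rank of the joint structure (default 1).
#' @param individualRanks per-block individual ranks, in block order
#'   (default \code{c(4, 3)}).
#' @param tol convergence tolerance on the change in total squared
#'   residual (default 1e-8).
#' @param maxIter maximum iterations (default 500).
#' @return A [JIVEModel-class].
#' @export
fitJive <- function(blocks, jointRank = 1L, individualRanks = c(4L, 3L),
                    tol = 1e-8, maxIter = 500L) {
  stopifnot(length(blocks) == 2L)
  ids <- blocks[[1]]$subjectIds
  if (!identical(ids, blocks[[2]]$subjectIds))
    stop("blocks must share the same subjects in the same order")
  n <- length(ids)
  rJ <- as.integer(jointRank)
  rI <- as.integer(individualRanks)
  names(rI) <- vapply(blocks, `[[`, character(1), "name")
  p <- vapply(blocks, function(b) nrow(b$X), integer(1))
  if (rJ > min(n, sum(p)) || any(rI > pmin(n, p)))
    stop("requested ranks exceed block dimensions")
  Xs <- lapply(blocks, `[[`, "X")
  X <- do.call(rbind, Xs)
  rowIdx <- split(seq_len(sum(p)), rep(seq_along(p), p))

  A <- lapply(p, function(pk) matrix(0, pk, n))
  J <- matrix(0, sum(p), n)
  prevResid <- Inf; iter <- 0L; converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    J <- svdTrunc(X - do.call(rbind, A), rJ)
    V <- rightSingular(J, rJ)               # n x rJ joint row-space basis
    P <- diag(n) - V %*% t(V)               # projector off the joint space
    for (k in 1:2) {
      Rk <- (Xs[[k]] - J[rowIdx[[k]], , drop = FALSE]) %*% P
      A[[k]] <- svdTrunc(Rk, rI[k])
    }
    resid <- sum((X - J - do.call(rbind, A))^2)
    if (abs(prevResid - resid) < tol) { converged <- TRUE; break }
    prevResid <- resid
  }
  if (!converged)
    stop(sprintf(
      "JIVE did not converge in %d iterations (last residual %.4e, last change %.3e); raise maxIter or lower the requested ranks",
      maxIter, resid, abs(prevResid - resid)))

  V <- rightSingular(J, rJ)
  jointLoadings <- lapply(1:2, function(k) {
    L <- J[rowIdx[[k]], , drop = FALSE] %*% V
    rownames(L) <- blocks[[k]]$featureNames
    colnames(L) <- sprintf("Joint%d", seq_len(rJ))
    L
  })
  indiv <- lapply(1:2, function(k) {
    if (rI[k] == 0L)
      return(list(scores = matrix(0, n, 0),
                  loadings = matrix(0, p[k], 0)))
    sv <- svd(A[[k]], nu = rI[k], nv = rI[k])
    d <- sv$d[seq_len(rI[k])]
    loadings <- sv$u %*% diag(d, rI[k], rI[k])
    rownames(loadings) <- blocks[[k]]$featureNames
    colnames(loadings) <- sprintf("%s_%d", names(rI)[k], seq_len(rI[k]))
    list(scores = sv$v, loadings = loadings)
  })
  varDec <- t(vapply(1:2, function(k) {
    tot <- sum(Xs[[k]]^2)
    jk <- sum(J[rowIdx[[k]], ]^2)
    ak <- sum(A[[k]]^2)
    c(joint = jk / tot, individual = ak / tot,
      residual = (tot - jk - ak) / tot)
  }, numeric(3)))
  rownames(varDec) <- names(rI)

  js <- V
  if (rJ > 0) colnames(js) <- sprintf("Joint%d", seq_len(rJ))
  new("JIVEModel", blockNames = names(rI), jointRank = rJ,
      individualRanks = rI, jointScores = js,
      jointLoadings = setNames(jointLoadings, names(rI)),
      individualScores = setNames(lapply(indiv, `[[`, "scores"),
                                  names(rI)),
      individualLoadings = setNames(lapply(indiv, `[[`, "loadings"),
                                    names(rI)),
      varDecomposition = varDec, scaledBlocks = setNames(Xs, names(rI)),
      scaling = setNames(lapply(blocks, `[[`, "scaling"), names(rI)),
      iterations = iter, converged = converged, subjectIds = ids)
}

#' Reconstruct a block's joint + individual approximation
#'
#' @param model a [JIVEModel-class].
#' @param block block name.
#' @return List with \code{J}, \code{A}, \code{E} (features x subjects)
#'   summing exactly to the scaled block.
#' @export
jiveReconstruction <- function(model, block) {
  X <- model@scaledBlocks[[block]]
  J <- model@jointLoadings[[block]] %*% t(model@jointScores)
  A <- model@individualLoadings[[block]] %*%
    t(model@individualScores[[block]])
  list(J = J, A = A, E = X - J - A)
}

permSingularValues <- function(M, r) svd(M, nu = 0, nv = 0)$d[seq_len(r)]

#' Select JIVE ranks by sequential permutation tests
#'
#' Joint rank: the r-th singular value of the stacked blocks is compared
#' with its null distribution obtained by permuting subject order within
#' the second block (destroying cross-block alignment while preserving
#' within-block structure); the rank grows while the observed value
#' exceeds the (1 - alpha) null quantile.  Individual ranks: after
#' projecting each block off the selected joint row space, singular
#' values are compared with nulls obtained by permuting entries within
#' each feature row (destroying low-rank structure while preserving
#' feature scales).
#'
#' @param blocks list of two [featureBlock()]s.
#' @param nPerm permutations per test (>= 20).
#' @param alpha test level (default 0.05).
#' @param seed integer seed (results are deterministic given it).
#' @param maxRank cap on each rank search (default 8).
#' @return List \code{joint}, \code{individual} (named integer vector).
#' @export
selectJiveRanks <- function(blocks, nPerm = 100L, alpha = 0.05, seed = 1,
                            maxRank = 8L) {
  if (nPerm < 20L) stop("nPerm must be at least 20")
  set.seed(as.integer(seed))
  Xs <- lapply(blocks, `[[`, "X")
  n <- ncol(Xs[[1]])
  X <- do.call(rbind, Xs)
  maxRank <- min(maxRank, n - 1L, nrow(X) - 1L)

  obs <- permSingularValues(X, maxRank)
  nullMat <- t(vapply(seq_len(nPerm), function(b) {
    Xp <- rbind(Xs[[1]], Xs[[2]][, sample.int(n), drop = FALSE])
    permSingularValues(Xp, maxRank)
  }, numeric(maxRank)))
  thr <- apply(nullMat, 2, quantile, probs = 1 - alpha)
  rJ <- 0L
  for (r in seq_len(maxRank)) {
    if (obs[r] > thr[r]) rJ <- r else break
  }

  V <- if (rJ > 0) rightSingular(svdTrunc(X, rJ), rJ) else
    matrix(0, n, 0)
  P <- diag(n) - V %*% t(V)
  rI <- integer(2)
  for (k in 1:2) {
    Rk <- Xs[[k]] %*% P
    mk <- min(maxRank, nrow(Rk) - 1L)
    obsk <- permSingularValues(Rk, mk)
    nullk <- t(vapply(seq_len(nPerm), function(b) {
      Rp <- t(apply(Rk, 1, sample))
      permSingularValues(Rp, mk)
    }, numeric(mk)))
    thrk <- apply(nullk, 2, quantile, probs = 1 - alpha)
    for (r in seq_len(mk)) {
      if (obsk[r] > thrk[r]) rI[k] <- r else break
    }
  }
  names(rI) <- vapply(blocks, `[[`, character(1), "name")
  list(joint = rJ, individual = rI)
}

#' Export standardized JIVE subject scores
#'
#' Joint and individual score columns, each sign-oriented by the same
#' rule as the fPCA components (positive loading integral) and
#' standardized to unit sample SD, ready for regression modeling.
#'
#' @param model a [JIVEModel-class].
#' @return data.frame: \code{subject_id}, \code{Joint1...},
#'   \code{PA_1...}, \code{CR_1...} (empty beyond the header for a
#'   rank-0 model).
#' @export
exportJiveScores <- function(model) {
  out <- data.frame(subject_id = model@subjectIds,
                    stringsAsFactors = FALSE)
  std <- function(s) if (sd(s) > 0) s / sd(s) else s
  if (model@jointRank > 0) {
    L <- do.call(rbind, model@jointLoadings)
    for (r in seq_len(model@jointRank)) {
      sgn <- componentSign(L[, r])
      out[[sprintf("Joint%d", r)]] <- std(sgn * model@jointScores[, r])
    }
  }
  for (b in model@blockNames) {
    for (r in seq_len(model@individualRanks[[b]])) {
      sgn <- componentSign(model@individualLoadings[[b]][, r])
      out[[sprintf("%s_%d", b, r)]] <-
        std(sgn * model@individualScores[[b]][, r])
    }
  }
  out
}

#' Report features driving each JIVE component
#'
#' Lists, per component, the features whose squared loading exceeds
#' \code{threshold} of the component's total squared loading, with the
#' loading sign and the squared-loading proportion ("relative
#' magnitude").
#'
#' @param model a [JIVEModel-class].
#' @param threshold proportional-variation threshold (default 0.05).
#' @return data.frame: \code{component}, \code{block}, \code{variable},
#'   \code{loading}, \code{relative_magnitude}, sorted by magnitude
#'   within component.
#' @export
jiveLoadingReport <- function(model, threshold = 0.05) {
  rows <- list()
  addComp <- function(comp, block, v) {
    tot <- sum(v^2)
    if (tot == 0) return()
    rel <- v^2 / tot
    keep <- if (threshold <= 0) seq_along(rel) else which(rel > threshold)
    if (!length(keep)) return()
    keep <- keep[order(rel[keep], decreasing = TRUE)]
    rows[[length(rows) + 1L]] <<- data.frame(
      component = comp, block = block, variable = names(v)[keep],
      loading = unname(v[keep]), relative_magnitude = unname(rel[keep]),
      stringsAsFactors = FALSE)
  }
  if (model@jointRank > 0) {
    L <- do.call(rbind, model@jointLoadings)
    for (r in seq_len(model@jointRank))
      addComp(sprintf("Joint%d", r), "PA+CR",
              setNames(L[, r], rownames(L)))
  }
  for (b in model@blockNames) {
    Lb <- model@individualLoadings[[b]]
    for (r in seq_len(model@individualRanks[[b]]))
      addComp(sprintf("%s_%d", b, r), b,
              setNames(Lb[, r], rownames(Lb)))
  }
  if (!length(rows))
    return(data.frame(component = character(), block = character(),
                      variable = character(), loading = numeric(),
                      relative_magnitude = numeric()))
  do.call(rbind, rows)
}
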