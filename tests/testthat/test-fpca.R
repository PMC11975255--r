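## small helper: brute-force covariance eigendecomposition oracle
fpcaOracle <- function(X, K) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values[seq_len(K)],
       vectors = e$vectors[, seq_len(K), drop = FALSE])
}

test_that("rank-1 construction yields a single component", {
  set.seed(1)
  phi <- sin(2 * pi * (1:144) / 144); phi <- phi / sqrt(sum(phi^2))
  s <- rnorm(20, 0, 3)
  X <- outer(rep(1, 20), rep(100, 144)) + outer(s, phi)
  m <- fitFpca(X, K = 1, binWidth = 1)
  expect_equal(varExplained(m)[1], 1, tolerance = 1e-10)
  expect_gt(abs(sum(eigenfunctions(m)[, 1] * phi)), 1 - 1e-8)
})

test_that("orthogonal two-shape construction splits variance 0.8 / 0.2", {
  set.seed(2)
  n <- 400
  p1 <- c(rep(1, 72), rep(0, 72)); p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(rep(0, 72), rep(1, 72)); p2 <- p2 / sqrt(sum(p2^2))
  X <- outer(rnorm(n, 0, 2), p1) + outer(rnorm(n, 0, 1), p2)
  m <- fitFpca(X, K = 2, binWidth = 1)
  expect_equal(varExplained(m), c(0.8, 0.2), tolerance = 0.06)
})

test_that("eigenfunctions are recovered from noisy rank-2 data at n = 250", {
  set.seed(3)
  n <- 250; p <- 144
  grid <- (1:p) / p
  phi1 <- cos(2 * pi * grid); phi1 <- phi1 / sqrt(sum(phi1^2))
  phi2 <- sin(4 * pi * grid); phi2 <- phi2 / sqrt(sum(phi2^2))
  X <- outer(rnorm(n, 0, 4), phi1) + outer(rnorm(n, 0, 2), phi2) +
    matrix(rnorm(n * p, 0, 0.2), n, p)
  m <- fitFpca(X, K = 2, binWidth = 1)
  expect_gt(abs(sum(eigenfunctions(m)[, 1] * phi1)), 0.95)
  expect_gt(abs(sum(eigenfunctions(m)[, 2] * phi2)), 0.95)
})

test_that("fit matches the brute-force eigendecomposition oracle", {
  set.seed(4)
  for (i in 1:5) {
    X <- matrix(rnorm(18 * 24, 10, 3), 18, 24)
    m <- fitFpca(X, K = 4, binWidth = 1)
    o <- fpcaOracle(X, 4)
    expect_equal(eigenvalues(m), o$values, tolerance = 1e-8)
    ## eigenfunctions agree up to sign
    align <- abs(colSums(eigenfunctions(m) * o$vectors))
    expect_true(all(align > 1 - 1e-8))
  }
})

test_that("scores are centered and reconstruction improves with K", {
  set.seed(5)
  X <- matrix(rlnorm(40 * 48, 3, 0.5), 40, 48)
  m <- fitFpca(X, K = 6, binWidth = 1)
  expect_lt(max(abs(colMeans(fpcaScores(m)))), 1e-9)
  errs <- vapply(1:6, function(k) {
    R <- outer(rep(1, 40), meanFunction(m)) +
      fpcaScores(m)[, 1:k, drop = FALSE] %*%
      t(eigenfunctions(m)[, 1:k, drop = FALSE])
    sum((X - R)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("orientation is deterministic, idempotent and reconstruction-safe", {
  set.seed(6)
  X <- matrix(rnorm(30 * 36), 30, 36)
  m <- fitFpca(X, K = 3, binWidth = 1)
  ## flipped model reorients back to the same sign convention
  flipped <- m
  flipped@eigenfunctions[, 2] <- -flipped@eigenfunctions[, 2]
  flipped@scores[, 2] <- -flipped@scores[, 2]
  re <- orientComponents(flipped)
  expect_equal(eigenfunctions(re), eigenfunctions(m))
  expect_equal(fpcaScores(re), fpcaScores(m))
  expect_equal(orientComponents(m), m)
  ## reconstruction invariant under orientation
  rec <- function(mm) fpcaScores(mm) %*% t(eigenfunctions(mm))
  expect_equal(rec(flipped), rec(re))
  ## oriented eigenfunctions have nonnegative integral (or tie-break sign)
  for (k in 1:3) {
    phi <- eigenfunctions(m)[, k]
    s <- sum(phi)
    if (abs(s) > 1e-8 * sqrt(length(phi))) expect_gt(s, 0)
    else expect_gt(phi[which.max(abs(phi))], 0)
  }
})

test_that("binning and input guards work", {
  coh <- simulateCohort(cohortConfig(nPerGroup = 3, nDays = 4, seed = 6))
  pre <- preprocessCohort(coh)
  P <- profileMatrix(pre$clean)
  expect_equal(dim(P), c(length(pre$clean), 1440))
  m <- fitFpca(P, K = 5, binWidth = 10)
  expect_equal(nrow(eigenfunctions(m)), 144)
  expect_equal(rownames(fpcaScores(m)), names(pre$clean))
  expect_error(fitFpca(P[1:4, ], K = 5), "K \\+ 1")
  Pna <- P; Pna[1, 5] <- NA
  expect_error(fitFpca(Pna, K = 2), "complete")
})
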