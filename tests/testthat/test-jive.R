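test_that("zero-rank fit on zero structure yields empty scores", {
  set.seed(2)
  b1 <- featureBlock(matrix(rnorm(40), 10, 4,
                            dimnames = list(NULL, letters[1:4])), "PA")
  b2 <- featureBlock(matrix(rnorm(30), 10, 3,
                            dimnames = list(NULL, LETTERS[1:3])), "CR")
  m <- fitJive(list(b1, b2), jointRank = 0, individualRanks = c(0, 0))
  expect_equal(jointRank(m), 0L)
  sc <- exportJiveScores(m)
  expect_equal(names(sc), "subject_id")
  expect_equal(nrow(sc), 10)
  vd <- varDecomposition(m)
  expect_equal(unname(vd[, "residual"]), c(1, 1))
})

test_that("decomposition is exactly additive with orthogonal parts", {
  d <- makeJiveData(n = 120, seed = 3)
  m <- fitJive(d$blocks, jointRank = 1, individualRanks = c(1, 1),
               tol = 1e-12)
  for (b in c("PA", "CR")) {
    r <- jiveReconstruction(m, b)
    X <- m@scaledBlocks[[b]]
    ## exact additivity by construction
    expect_equal(r$J + r$A + r$E, X, tolerance = 1e-12)
    ## norm additivity (orthogonality of the three parts)
    expect_equal(sum(X^2),
                 sum(r$J^2) + sum(r$A^2) + sum(r$E^2), tolerance = 1e-6)
    ## individual row space orthogonal to the joint row space
    expect_lt(max(abs(r$A %*% m@jointScores)), 1e-8)
  }
  ## both joint parts share one row space: principal angle ~ 0
  expect_equal(sum(varDecomposition(m)[1, ]), 1, tolerance = 1e-10)
})

test_that("known subspaces are recovered at n = 250", {
  d <- makeJiveData(n = 250, seed = 4)
  m <- fitJive(d$blocks, jointRank = 1, individualRanks = c(1, 1))
  expect_lt(principalAngleDeg(m@jointScores[, 1], d$vJ), 5)
  expect_lt(principalAngleDeg(m@individualScores$PA[, 1], d$v1), 5)
  expect_lt(principalAngleDeg(m@individualScores$CR[, 1], d$v2), 5)
  ## most block variation is explained
  vd <- varDecomposition(m)
  expect_true(all(vd[, "residual"] < 0.1))
})

test_that("permutation rank selection finds the constructed (1, 1, 1)", {
  d <- makeJiveData(n = 100, p1 = 12, p2 = 10, seed = 5)
  r <- selectJiveRanks(d$blocks, nPerm = 50, seed = 2)
  expect_equal(r$joint, 1L)
  expect_equal(unname(r$individual), c(1L, 1L))
})

test_that("pure-noise blocks select near-zero ranks", {
  set.seed(6)
  ranksTot <- vapply(1:3, function(i) {
    b1 <- featureBlock(matrix(rnorm(80 * 12), 80, 12,
                              dimnames = list(NULL, paste0("a", 1:12))),
                       "PA")
    b2 <- featureBlock(matrix(rnorm(80 * 10), 80, 10,
                              dimnames = list(NULL, paste0("b", 1:10))),
                       "CR")
    r <- selectJiveRanks(list(b1, b2), nPerm = 50, seed = i)
    r$joint + sum(r$individual)
  }, numeric(1))
  ## each of 9 tests rejects at ~5%: expect almost no selected structure
  expect_lte(sum(ranksTot), 2)
})

test_that("rank selection is monotone in alpha and guards nPerm", {
  d <- makeJiveData(n = 60, p1 = 10, p2 = 8, noise = 0.5, seed = 7)
  r05 <- selectJiveRanks(d$blocks, nPerm = 40, alpha = 0.05, seed = 3)
  r99 <- selectJiveRanks(d$blocks, nPerm = 40, alpha = 0.999, seed = 3)
  expect_gte(r99$joint, r05$joint)
  expect_true(all(r99$individual >= r05$individual))
  expect_error(selectJiveRanks(d$blocks, nPerm = 10), "20")
})

test_that("exported scores are standardized, oriented and uncorrelated", {
  d <- makeJiveData(n = 200, seed = 8)
  m <- fitJive(d$blocks, jointRank = 1, individualRanks = c(1, 1))
  sc <- exportJiveScores(m)
  expect_equal(names(sc), c("subject_id", "Joint1", "PA_1", "CR_1"))
  num <- as.matrix(sc[, -1])
  expect_equal(unname(apply(num, 2, sd)), rep(1, 3), tolerance = 1e-10)
  cc <- cor(num)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("consistent subject permutation permutes scores identically", {
  d <- makeJiveData(n = 50, p1 = 8, p2 = 6, seed = 9)
  m1 <- fitJive(d$blocks, jointRank = 1, individualRanks = c(1, 1))
  set.seed(10); perm <- sample(50)
  bp <- lapply(d$blocks, function(b) {
    b$X <- b$X[, perm]; b$subjectIds <- b$subjectIds[perm]; b
  })
  m2 <- fitJive(bp, jointRank = 1, individualRanks = c(1, 1))
  s1 <- exportJiveScores(m1); s2 <- exportJiveScores(m2)
  ## same subject gets the same score up to overall component sign
  for (cn in c("Joint1", "PA_1", "CR_1")) {
    a <- s1[[cn]][perm]; b <- s2[[cn]]
    expect_gt(abs(cor(a, b)), 1 - 1e-6)
  }
})

## FeatureBlock with raw (unscaled) feature rows, for loading mechanics
rawBlock <- function(X, name) {
  structure(list(name = name, X = t(X), featureNames = colnames(X),
                 subjectIds = sprintf("S%03d", seq_len(nrow(X))),
                 scaling = list(center = rep(0, ncol(X)),
                                scale = rep(1, ncol(X)), blockScale = 1)),
            class = "FeatureBlock")
}

test_that("loading reports mirror the squared-loading proportions", {
  ## single-feature component: all structure lives on f1
  X1 <- matrix(0, 30, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  set.seed(11)
  X1[, 1] <- rnorm(30, 0, 5)
  X1[, 2:3] <- rnorm(60, 0, 0.01)
  b1 <- rawBlock(X1, "PA")
  b2 <- rawBlock(matrix(rnorm(30 * 2, 0, 0.01), 30, 2,
                        dimnames = list(NULL, c("g1", "g2"))), "CR")
  m <- fitJive(list(b1, b2), jointRank = 0, individualRanks = c(1, 0))
  rep1 <- jiveLoadingReport(m, threshold = 0.5)
  expect_equal(rep1$variable, "f1")
  expect_gt(rep1$relative_magnitude, 0.9)
  ## threshold 0 lists every feature of the component
  rep0 <- jiveLoadingReport(m, threshold = 0)
  expect_setequal(rep0$variable[rep0$component == "PA_1"],
                  c("f1", "f2", "f3"))
  ## equal four-feature joint component: relative magnitudes 0.25
  n <- 80
  set.seed(12)
  v <- rnorm(n)
  X <- outer(v, rep(1, 4)) + matrix(rnorm(n * 4, 0, 1e-3), n, 4)
  colnames(X) <- paste0("h", 1:4)
  bb1 <- featureBlock(X[, 1:2], "PA")
  bb2 <- featureBlock(X[, 3:4], "CR")
  mj <- fitJive(list(bb1, bb2), jointRank = 1, individualRanks = c(0, 0))
  rj <- jiveLoadingReport(mj, threshold = 0.05)
  expect_equal(rj$relative_magnitude, rep(0.25, 4), tolerance = 0.01)
})
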