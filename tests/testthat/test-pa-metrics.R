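cp <- cutPoints()

test_that("daily volume handles degenerate and single-spike days", {
  w <- rep(TRUE, 1440)
  z <- dailyVolume(rep(0, 1440), w, cp)
  expect_equal(unname(z[c("TAC", "TLAC", "nonactive")]), c(0, 0, 1440))
  ## one minute of 7000 at 03:30, rest zero
  x <- rep(0, 1440); x[211] <- 7000
  v <- dailyVolume(x, w, cp)
  expect_equal(unname(v[c("TAC", "MVPA", "LIPA", "nonactive")]),
               c(7000, 1, 0, 1439))
  expect_equal(unname(v["TAC_02_04"]), 7000)
  expect_equal(sum(v[sprintf("TAC_%02d_%02d", seq(0, 22, 2),
                             seq(2, 24, 2))]), v[["TAC"]])
  ## constant day: uniform bins
  u <- dailyVolume(rep(1000, 1440), w, cp)
  expect_equal(u[["TAC"]], 1440000)
  expect_true(all(abs(u[grep("TAC_", names(u))] - 120000) < 1e-9))
})

test_that("fragmentation matches hand-computed transition probabilities", {
  w <- rep(TRUE, 1440)
  ## strict alternation active/sedentary: every active minute transitions
  alt <- rep(c(3000, 0), 720)
  f <- fragmentation(alt, w, cp)
  expect_equal(f[["ASTP"]], 1)
  ## one 4-minute active bout then sedentary: 1 transition / 4 active min
  x <- rep(0, 1440); x[100:103] <- 3000
  expect_equal(fragmentation(x, w, cp)[["ASTP"]], 0.25)
  ## all-active day: no transitions, SATP undefined
  f <- fragmentation(rep(3000, 1440), w, cp)
  expect_equal(f[["ASTP"]], 0)
  expect_true(is.na(f[["SATP"]]))
})

test_that("fragmentation equals exhaustive bout enumeration (length <= 12)", {
  cp2 <- cutPoints(2000, 6750)
  for (n in c(4L, 8L, 12L)) {
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    for (i in seq_len(nrow(grid))) {
      states <- unlist(grid[i, ], use.names = FALSE)
      counts <- c(ifelse(states, 3000, 100), rep(100, 1440 - n))
      wear <- c(rep(TRUE, n), rep(FALSE, 1440 - n))
      got <- fragmentation(counts, wear, cp2)
      want <- fragOracle(states)
      expect_identical(got, want)
    }
  }
})

test_that("astp is the reciprocal mean active-bout length when ending sedentary", {
  set.seed(7)
  for (i in 1:25) {
    states <- c(runif(200) < 0.4, FALSE)
    nAct <- sum(states)
    if (nAct == 0) next
    r <- rle(states)
    boutLens <- r$lengths[r$values]
    counts <- c(ifelse(states, 5000, 0), rep(0, 1440 - length(states)))
    wear <- c(rep(TRUE, length(states)), rep(FALSE, 1440 - length(states)))
    astp <- fragmentation(counts, wear, cp)[["ASTP"]]
    expect_equal(astp, 1 / mean(boutLens))
  }
})

test_that("nonwear gaps break bouts without contributing transitions", {
  x <- rep(0, 1440)
  x[101:110] <- 3000   # active bout
  x[121:130] <- 3000   # active bout
  w <- rep(TRUE, 1440)
  w[111:120] <- FALSE  # nonwear between the bouts
  f <- fragmentation(x, w, cp)
  ## two 10-min active bouts; only the second bout's end transitions are
  ## adjacent wear pairs: bout 1 ends at a nonwear gap (no transition),
  ## bout 2 ends into sedentary wear minutes (one transition)
  expect_equal(f[["ASTP"]], 1 / 20)
})

test_that("volume metrics are monotone in any single minute's count", {
  set.seed(3)
  x <- round(runif(1440, 0, 4000))
  w <- rep(TRUE, 1440)
  v0 <- dailyVolume(x, w, cp)
  x2 <- x; x2[500] <- x2[500] + 1000
  v1 <- dailyVolume(x2, w, cp)
  expect_gt(v1[["TAC"]], v0[["TAC"]])
  expect_gt(v1[["TLAC"]], v0[["TLAC"]])
})

test_that("aggregation averages days and is order-invariant", {
  d1 <- rep(1000, 1440); d2 <- rep(3000, 1440); d3 <- rep(0, 1440)
  a <- aggregatePa(cleanFromCounts(rbind(d1, d2, d3)), cp)
  b <- aggregatePa(cleanFromCounts(rbind(d3, d1, d2)), cp)
  expect_equal(a, b)
  expect_equal(a[["TAC"]], mean(c(1440000, 3 * 1440000, 0)))
  ## identical days: aggregate equals the single day
  one <- dailyVolume(d2, rep(TRUE, 1440), cp)
  agg <- aggregatePa(cleanFromCounts(rbind(d2, d2, d2)), cp)
  expect_equal(agg[["TAC"]], one[["TAC"]])
  expect_equal(agg[["LIPA"]], one[["LIPA"]])
})

test_that("feature table has one labelled row per subject", {
  coh <- simulateCohort(cohortConfig(nPerGroup = 2, nDays = 4, seed = 3))
  pre <- preprocessCohort(coh)
  tab <- paFeatures(pre$clean, cp)
  expect_equal(tab$subject_id, names(pre$clean))
  expect_true(all(c("TAC", "SATP", "ASTP", "MVPA_LIPA", "TAC_22_24")
                  %in% names(tab)))
  expect_true(all(tab$SATP >= 0 & tab$SATP <= 1, na.rm = TRUE))
})
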