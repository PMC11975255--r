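test_that("nonwear rule flags zero runs at the 90-minute boundary", {
  ## run of exactly 89 zeros: nothing flagged
  d89 <- dayWithRuns(list(101:189))
  s <- detectNonwear(minuteSeries("a", d89))
  expect_true(all(wearMatrix(s)))
  ## run of exactly 90 zeros: exactly those minutes flagged
  d90 <- dayWithRuns(list(101:190))
  s <- detectNonwear(minuteSeries("a", d90))
  expect_equal(which(!wearMatrix(s)[1, ]), 101:190)
  ## an all-zero day is one 1440-minute nonwear run
  s <- detectNonwear(minuteSeries("a", rep(0, 1440)))
  expect_false(any(wearMatrix(s)))
})

test_that("nonwear flagging ignores count values outside zero runs", {
  base <- dayWithRuns(list(201:300), fill = 500)
  alt <- dayWithRuns(list(201:300), fill = 9999)
  wa <- wearMatrix(detectNonwear(minuteSeries("a", base)))
  wb <- wearMatrix(detectNonwear(minuteSeries("a", alt)))
  expect_identical(wa, wb)
})

test_that("nonwear runs spanning midnight are detected", {
  ## 50 zeros at the end of day 1 + 50 at the start of day 2
  m <- matrix(500, 2, 1440)
  m[1, 1391:1440] <- 0
  m[2, 1:50] <- 0
  s <- detectNonwear(minuteSeries("a", m))
  expect_false(any(wearMatrix(s)[1, 1391:1440]))
  expect_false(any(wearMatrix(s)[2, 1:50]))
})

test_that("valid-day rule admits exactly >= 1296 wear minutes", {
  mk <- function(nZero) {
    d <- dayWithRuns(list(seq_len(nZero)))
    markValidDays(detectNonwear(minuteSeries("a", d)))
  }
  expect_true(validDays(mk(1440 - 1296)))   # exactly 1296 wear minutes
  expect_false(validDays(mk(1440 - 1295)))  # 1295 wear minutes
  expect_true(validDays(mk(0)))             # full wear
})

test_that("inclusion rule requires >= 3 valid days", {
  mixed <- function(nValid, nBad) {
    good <- dayWithRuns(list(1:10))
    bad <- rep(0, 1440)
    m <- rbind(matrix(rep(good, nValid), ncol = 1440, byrow = TRUE),
               matrix(rep(bad, nBad), ncol = 1440, byrow = TRUE))
    markValidDays(detectNonwear(minuteSeries("a", m)))
  }
  inc <- includeSubject(mixed(3, 2))
  expect_s4_class(inc, "CleanSeries")
  expect_equal(nValid(inc), 3L)
  exc <- includeSubject(mixed(2, 3))
  expect_true(isExcluded(exc))
  expect_match(exc$reason, "insufficient")
  expect_equal(nValid(includeSubject(mixed(14, 0))), 14L)
})

test_that("forward-DST hours are imputed from other valid days", {
  m <- matrix(100, 4, 1440)
  s <- minuteSeries("a", m)
  s <- injectDst(s, 2, "forward")
  expect_true(anyNA(countsMatrix(s)[2, ]))
  s <- preprocessSeries(s)
  ## all other valid days are constant 100 -> imputed exactly 100
  expect_false(anyNA(countsMatrix(s)))
  expect_equal(unique(as.vector(countsMatrix(s))), 100)
  expect_true(all(validDays(s)))
})

test_that("fall-back duplicated hours are averaged", {
  m <- matrix(80, 3, 1440)
  s <- minuteSeries("a", m)
  s <- injectDst(s, 1, "back", duplicateValues = rep(120, 60))
  s <- preprocessSeries(s)
  ## copies 80 and 120 resolve to 100 in the repeated hour (01:00-01:59)
  expect_equal(unique(countsMatrix(s)[1, 61:120]), 100)
  expect_equal(unique(countsMatrix(s)[1, -(61:120)]), 80)
})

test_that("no valid imputation source leaves the hour missing and flags", {
  m <- matrix(0, 3, 1440)  # every day all-zero -> no valid days
  m[1, ] <- 100            # day 1 valid
  s <- injectDst(minuteSeries("a", m), 1, "forward")
  s <- preprocessSeries(s)
  expect_true(anyNA(countsMatrix(s)[1, ]))
  expect_true(attr(s, "dstUnresolved"))
})

test_that("preprocessing is idempotent and conserves wear off DST days", {
  sub <- simulateSubject(groupParams(), nDays = 7, seed = 21)
  p1 <- preprocessSeries(sub$series)
  p2 <- preprocessSeries(p1)
  expect_identical(countsMatrix(p1), countsMatrix(p2))
  expect_identical(wearMatrix(p1), wearMatrix(p2))
  expect_identical(validDays(p1), validDays(p2))
  ## resolve_dst must not change wear minutes when no DST event exists
  d0 <- detectNonwear(sub$series)
  d0 <- markValidDays(d0)
  r <- resolveDst(d0)
  expect_identical(wearMatrix(d0), wearMatrix(r))
})

test_that("cohort preprocessing logs exclusions", {
  good <- simulateSubject(groupParams(nonwearRate = 0), nDays = 4,
                          seed = 1, subjectId = "G")$series
  bad <- minuteSeries("B", matrix(0, 4, 1440))
  res <- preprocessCohort(list(G = good, B = bad))
  expect_named(res$clean, "G")
  expect_equal(res$exclusions$subject_id, "B")
  expect_equal(sum(res$log$included), 1L)
})
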