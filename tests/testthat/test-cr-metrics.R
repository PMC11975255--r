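test_that("M10/L5 landmarks behave on constructed profiles", {
  ## constant profile: M10 = L5, RA = 0
  r <- m10l5(rep(250, 1440))
  expect_equal(r[["M10"]], 250)
  expect_equal(r[["L5"]], 250)
  expect_equal(r[["RA"]], 0)
  ## zero 22:00-08:00, constant elsewhere: L5 fits in the zero span
  prof <- rep(0, 1440)
  prof[(8 * 60 + 1):(22 * 60)] <- 100
  r <- m10l5(prof)
  expect_equal(r[["L5"]], 0)
  expect_equal(r[["RA"]], 1)
  ## RA arithmetic at reported group-mean magnitudes
  expect_equal((2161 - 146) / (2161 + 146), 0.8734, tolerance = 5e-5)
})

test_that("window search matches the exhaustive circular oracle", {
  set.seed(4)
  for (i in 1:10) {
    prof <- abs(rnorm(1440, 500, 400)) + 50 * sin(2 * pi * (1:1440) / 1440)
    r <- m10l5(prof)
    expect_equal(r[["M10"]], windowOracle(prof, 600, "max"))
    expect_equal(r[["L5"]], windowOracle(prof, 300, "min"))
  }
  ## a window that must wrap midnight
  prof <- rep(1000, 1440)
  prof[c(1:120, 1321:1440)] <- 0  # least-active 4 h split over midnight
  r <- m10l5(prof)
  expect_equal(r[["L5"]], windowOracle(prof, 300, "min"))
  expect_true(r[["Mid_L5"]] < 3 | r[["Mid_L5"]] > 21)
})

test_that("DARE is the in-window proportion of activity", {
  h <- minuteOfDayHours()
  inWin <- h >= 8 & h < 20
  ## all activity inside the daytime window
  prof <- ifelse(inWin, 400, 0)
  expect_equal(dare(prof), 1)
  ## uniform profile, 12-hour window
  expect_equal(dare(rep(7, 1440)), 0.5)
  ## constructed 70/30 split
  prof <- ifelse(inWin, 0.70 / sum(inWin), 0.30 / sum(!inWin))
  expect_equal(dare(prof), 0.70)
  expect_error(dare(rep(0, 1440)), "undefined")
})

test_that("cosinor fit is exact on its own model and flags degeneracy", {
  h <- rep(minuteOfDayHours(), 3)
  x <- 1000 + 500 * cos(2 * pi * (h - 14) / 24)
  cf <- cosinorFit(x, h)
  expect_equal(unname(cf), c(1000, 500, 14), tolerance = 1e-9)
  ## constant series: amplitude 0, acrophase missing
  cf0 <- cosinorFit(rep(5, length(h)), h)
  expect_equal(cf0[["Amplitude"]], 0, tolerance = 1e-9)
  expect_true(is.na(cf0[["Acrophase"]]))
  expect_error(cosinorFit(c(1, 2), c(3, 3)), "distinct")
})

test_that("cosinor never fits worse than the mean-only model", {
  set.seed(9)
  h <- rep(minuteOfDayHours(), 2)
  for (i in 1:5) {
    x <- rlnorm(length(h), 5, 1)
    cf <- cosinorFit(x, h)
    w <- 2 * pi / 24
    fitted <- cf[["MESOR"]] + cf[["Amplitude"]] *
      cos(w * (h - cf[["Acrophase"]]))
    expect_lte(sum((x - fitted)^2), sum((x - mean(x))^2) + 1e-6)
  }
})

test_that("IV and IS hit their analytic anchors", {
  ## identical repeated days: between-hour variance equals total -> IS = 1
  day <- sin(2 * pi * (0:23) / 24) + 2
  r <- ivIs(matrix(rep(day, 6), nrow = 6, byrow = TRUE))
  expect_equal(r[["IS"]], 1)
  ## long pure 24-h cosine sampled hourly: IV -> 2(1 - cos(2*pi/24))
  many <- matrix(rep(cos(2 * pi * (0:23) / 24), 400), nrow = 400,
                 byrow = TRUE)
  expect_equal(ivIs(many)[["IV"]], 2 * (1 - cos(2 * pi / 24)),
               tolerance = 0.01)
  ## i.i.d. noise: IV -> 2
  set.seed(12)
  noise <- matrix(rnorm(24 * 2000), ncol = 24)
  expect_equal(ivIs(noise)[["IV"]], 2, tolerance = 0.05)
  expect_lt(ivIs(noise)[["IS"]], 0.05)
  ## degenerate input
  expect_true(all(is.na(ivIs(matrix(3, 4, 24)))))
  expect_error(ivIs(matrix(1, 1, 24)), "2 days")
})

test_that("interdaily stability lies in [0, 1] on random inputs", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rlnorm(24 * 8, 4, 1), ncol = 24)
    r <- ivIs(m)
    expect_gte(r[["IS"]], 0)
    expect_lte(r[["IS"]], 1 + 1e-12)
    expect_gte(r[["IV"]], 0)
  }
})

test_that("per-subject CR aggregation composes its parts", {
  sub <- simulateSubject(groupParams(nonwearRate = 0), nDays = 5,
                         seed = 17)
  cl <- includeSubject(markValidDays(detectNonwear(sub$series)))
  cr <- aggregateCr(cl)
  prof <- diurnalProfile(cl)
  expect_equal(cr[["M10"]], m10l5(prof)[["M10"]])
  expect_equal(cr[["DARE"]], dare(prof))
  expect_gte(cr[["RA"]], 0); expect_lte(cr[["RA"]], 1)
  expect_gte(cr[["L5"]], 0)
  expect_lte(cr[["L5"]], cr[["M10"]])
  expect_true(cr[["Acrophase"]] >= 0 && cr[["Acrophase"]] < 24)
  ## log-scale option shrinks landmark magnitudes below raw-scale ones
  crLog <- aggregateCr(cl, logScale = TRUE)
  expect_lt(crLog[["M10"]], cr[["M10"]])
})
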