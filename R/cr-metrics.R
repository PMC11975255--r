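## Circadian / diurnal rest-activity metrics: M10/L5 landmarks, relative
## amplitude, DARE, single-subject cosinor, intradaily variability and
## interdaily stability.

#' Mean diurnal profile of a subject
#'
#' Minute-of-day mean of counts over the subject's valid days, using wear
#' minutes only.  A minute slot with no wear observation on any valid day
#' (rare) is filled by circular linear interpolation so downstream window
#' searches always see a complete 1440-point profile.
#'
#' @param clean a [CleanSeries-class].
#' @return Numeric vector of length 1440.
#' @export
diurnalProfile <- function(clean) {
  cnt <- clean@counts
  cnt[!clean@wear] <- NA
  prof <- colMeans(cnt, na.rm = TRUE)
  if (anyNA(prof) || any(is.nan(prof))) {
    bad <- which(!is.finite(prof))
    if (length(bad) == length(prof))
      stop("profile is entirely missing")
    good <- which(is.finite(prof))
    ## circular interpolation: unroll to 3 periods
    xs <- c(good - MINUTES_PER_DAY, good, good + MINUTES_PER_DAY)
    ys <- rep(prof[good], 3)
    prof[bad] <- stats::approx(xs, ys, xout = bad)$y
  }
  prof
}

circularWindowMeans <- function(profile, width) {
  n <- length(profile)
  cs <- cumsum(c(0, profile, profile))
  starts <- seq_len(n)
  (cs[starts + width] - cs[starts]) / width
}

#' M10 / L5 landmarks and relative amplitude
#'
#' M10 is the maximal mean over all 600-minute circular windows of the
#' diurnal profile (the most active 10 hours); L5 the minimal mean over
#' 300-minute circular windows (the least active 5 hours).  Windows may
#' wrap midnight.  Midpoints are the window centers as clock hours.
#' RA = (M10 - L5) / (M10 + L5).  Ties resolve to the earliest window
#' start.
#'
#' @param profile length-1440 diurnal profile.
#' @return Named vector \code{M10}, \code{Mid_M10} (hours), \code{L5},
#'   \code{Mid_L5} (hours), \code{RA}.
#' @export
m10l5 <- function(profile) {
  stopifnot(length(profile) == MINUTES_PER_DAY, !anyNA(profile))
  w10 <- circularWindowMeans(profile, 600L)
  w5 <- circularWindowMeans(profile, 300L)
  i10 <- which.max(w10); i5 <- which.min(w5)
  m10 <- w10[i10]; l5 <- w5[i5]
  mid <- function(start, width) (((start - 1) + width / 2) %% 1440) / 60
  ra <- if (m10 + l5 > 0) (m10 - l5) / (m10 + l5) else NA_real_
  c(M10 = m10, Mid_M10 = mid(i10, 600), L5 = l5, Mid_L5 = mid(i5, 300),
    RA = ra)
}

#' Daytime activity ratio estimate (DARE)
#'
#' Proportion of the 24-hour activity total occurring inside the daytime
#' window (default 08:00-20:00).
#'
#' @param profile length-1440 diurnal profile.
#' @param window daytime window in clock hours, \code{c(start, end)}.
#' @return Scalar proportion in \[0, 1\].
#' @export
dare <- function(profile, window = c(8, 20)) {
  stopifnot(length(profile) == MINUTES_PER_DAY)
  total <- sum(profile)
  if (total <= 0) stop("zero total activity: DARE undefined")
  h <- minuteHours()
  inWin <- if (window[1] < window[2])
    h >= window[1] & h < window[2] else h >= window[1] | h < window[2]
  sum(profile[inWin]) / total
}

#' Single-subject cosinor fit
#'
#' Least-squares fit of \eqn{x(t) = M + \beta_c\cos(\omega t) +
#' \beta_s\sin(\omega t)} with \eqn{\omega = 2\pi/24} h, giving
#' MESOR \eqn{M}, amplitude \eqn{\sqrt{\beta_c^2 + \beta_s^2}} and
#' acrophase \eqn{\mathrm{atan2}(\beta_s, \beta_c)/\omega \bmod 24}
#' (clock time of the fitted peak).  A constant series yields amplitude 0
#' and missing acrophase.
#'
#' @param x activity values.
#' @param hours clock time of each value, in hours.
#' @return Named vector \code{MESOR}, \code{Amplitude}, \code{Acrophase}.
#' @examples
#' h <- minuteOfDayHours()
#' x <- 1000 + 500 * cos(2 * pi * (h - 14) / 24)
#' cosinorFit(x, h)
#' @export
cosinorFit <- function(x, hours) {
  keep <- is.finite(x) & is.finite(hours)
  x <- x[keep]; hours <- hours[keep]
  if (length(unique(hours)) < 3)
    stop("cosinor fit needs >= 3 distinct clock times")
  w <- 2 * pi / 24
  fit <- lm(x ~ cos(w * hours) + sin(w * hours))
  b <- coef(fit)
  amp <- sqrt(b[2]^2 + b[3]^2)
  acro <- if (amp < .Machine$double.eps^0.5 * max(1, abs(b[1])))
    NA_real_ else (atan2(b[3], b[2]) / w) %% 24
  c(MESOR = unname(b[1]), Amplitude = unname(amp), Acrophase = unname(acro))
}

#' Intradaily variability and interdaily stability
#'
#' On the concatenated hourly means \eqn{x_1, \dots, x_N} over a
#' subject's valid days, with hour-of-day means \eqn{\bar x_h}
#' (\eqn{p = 24} bins) and grand mean \eqn{\bar x}:
#' \deqn{IV = N \sum_{i=2}^N (x_i - x_{i-1})^2 /
#'   ((N-1)\sum_i (x_i - \bar x)^2)}
#' \deqn{IS = N \sum_h (\bar x_h - \bar x)^2 /
#'   (p \sum_i (x_i - \bar x)^2)}
#' IV near 2 indicates noise-like hour-to-hour fragmentation, small IV a
#' smooth rhythm; IS in \[0, 1\] measures day-to-day constancy of the
#' 24-hour pattern.
#'
#' @param hourly numeric matrix (days x 24) of hourly means, or a vector
#'   whose length is a multiple of 24 (day-major).
#' @return Named vector \code{c(IV =, IS =)}; both \code{NA} when the
#'   series has zero variance.
#' @export
ivIs <- function(hourly) {
  if (is.vector(hourly)) {
    stopifnot(length(hourly) %% 24 == 0)
    hourly <- matrix(hourly, ncol = 24, byrow = TRUE)
  }
  if (nrow(hourly) < 2)
    stop("IV/IS need >= 2 days of hourly data")
  x <- as.vector(t(hourly))
  keep <- is.finite(x)
  x <- x[keep]
  hod <- rep(seq_len(24), nrow(hourly))[keep]
  N <- length(x)
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  if (ss == 0) return(c(IV = NA_real_, IS = NA_real_))
  iv <- N * sum(diff(x)^2) / ((N - 1) * ss)
  hmeans <- tapply(x, hod, mean)
  is_ <- N * sum((hmeans - xbar)^2) / (24 * ss)
  c(IV = iv, IS = unname(is_))
}

hourlyMeans <- function(clean) {
  cnt <- clean@counts
  cnt[!clean@wear] <- NA
  t(apply(cnt, 1, function(row)
    tapply(row, rep(seq_len(24), each = 60), mean, na.rm = TRUE)))
}

#' Per-subject circadian-rhythm features
#'
#' Composes the CR metrics for one subject: M10/L5 landmarks, RA and DARE
#' on the mean diurnal profile; the cosinor fit pooled over all valid-day
#' wear minutes; IV and IS on the concatenated hourly means.  Landmarks
#' are computed on the raw count scale by default; \code{logScale = TRUE}
#' applies \eqn{\log(1 + count)} before the profile is formed.
#'
#' @param clean a [CleanSeries-class].
#' @param dareWindow daytime window for [dare()].
#' @param logScale compute landmark metrics on log(1+count).
#' @return Named numeric vector: \code{M10}, \code{Mid_M10}, \code{L5},
#'   \code{Mid_L5}, \code{RA}, \code{DARE}, \code{MESOR},
#'   \code{Amplitude}, \code{Acrophase}, \code{IV}, \code{IS}.
#' @export
aggregateCr <- function(clean, dareWindow = c(8, 20), logScale = FALSE) {
  stopifnot(is(clean, "CleanSeries"))
  cl <- clean
  if (logScale) cl@counts <- log1p(cl@counts)
  prof <- diurnalProfile(cl)
  land <- m10l5(prof)
  dr <- dare(prof, dareWindow)
  cnt <- cl@counts
  cnt[!cl@wear] <- NA
  x <- as.vector(t(cnt))
  hrs <- rep(minuteHours(), nrow(cnt))
  cf <- cosinorFit(x, hrs)
  vi <- ivIs(hourlyMeans(cl))
  c(land, DARE = dr, cf, vi)
}

#' Circadian-rhythm feature table for a cohort
#'
#' @param clean named list of [CleanSeries-class] objects.
#' @param dareWindow daytime window for [dare()].
#' @param logScale compute landmark metrics on log(1+count).
#' @return data.frame, one row per subject.
#' @export
crFeatures <- function(clean, dareWindow = c(8, 20), logScale = FALSE) {
  rows <- t(vapply(clean, aggregateCr, numeric(11L),
                   dareWindow = dareWindow, logScale = logScale))
  data.frame(subject_id = names(clean), rows, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
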