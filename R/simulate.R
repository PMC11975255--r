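## Synthetic minute-epoch actigraphy cohorts.
##
## The generator couples activity fragmentation and the diurnal rhythm: a
## two-state (sedentary/active) Markov chain runs minute by minute, with the
## active-to-sedentary probability held constant and the sedentary-to-active
## probability modulated so that the occupancy probability of the active
## state follows a logistic transform of a 24-h cosinor curve.  Counts in
## active minutes are drawn lognormal above the nonactive cut point, counts
## in sedentary minutes below it, so the generating chain states coincide
## with the active/sedentary dichotomy the fragmentation metrics use.

#' Per-group generating parameters for the synthetic cohort
#'
#' @param mesor,amplitude,acrophase cosinor parameters (counts, counts,
#'   hours in \[0, 24)) of the latent diurnal activity-rate curve; the
#'   occupancy probability of the active state follows a logistic transform
#'   of this curve, so \code{amplitude <= mesor} is required.
#' @param noiseSd additive count noise SD (counts; 0 disables).
#' @param pActiveGivenSedentary,pSedentaryGivenActive Markov transition
#'   probabilities (the SATP- and ASTP-like generating rates).
#' @param activeCountLogMean,activeCountLogSd lognormal parameters of the
#'   count excess above the nonactive cut point in active minutes.
#' @param sleepWindow numeric length-2 (start hour, end hour, may wrap
#'   midnight) during which sedentary counts are drawn near zero and the
#'   active-occupancy curve is attenuated; \code{c(0, 0)} disables.
#' @param nonwearRate expected nonwear episodes per day.
#' @param nonwearMinLen minimum nonwear episode length in minutes (>= 90,
#'   so episodes are detectable by the 90-min all-zero rule).
#' @param ageMean,ageSd,bmiMean,bmiSd,pFemale covariate distributions.
#' @param ipaqNoiseSd SD of the multiplicative (log-scale) reporting noise
#'   on the IPAQ MET-minute summary.
#' @param fragLogitSd between-subject SD, on the logit scale, of the two
#'   transition probabilities (person-level fragmentation heterogeneity).
#' @param activeLevelSd between-subject SD of the active-minute lognormal
#'   location (person-level activity-intensity heterogeneity).
#' @param rhythmLogSd between-subject log-scale SD of a common multiplier
#'   on MESOR and amplitude (rhythm-strength heterogeneity; the multiplier
#'   is shared so amplitude never exceeds MESOR).
#' @param acroSd between-subject SD of the acrophase, hours.
#' @return A validated list of class \code{"GroupParams"}.
#' @seealso [defaultGroupParams()], [simulateSubject()], [simulateCohort()]
#' @export
groupParams <- function(mesor = 1300, amplitude = 1000, acrophase = 14.5,
                        noiseSd = 0,
                        pActiveGivenSedentary = 0.09,
                        pSedentaryGivenActive = 0.27,
                        activeCountLogMean = log(3000) - 0.5,
                        activeCountLogSd = 1.0,
                        sleepWindow = c(23, 7),
                        nonwearRate = 0.15, nonwearMinLen = 120L,
                        ageMean = 54, ageSd = 8,
                        bmiMean = 28.5, bmiSd = 6, pFemale = 0.7,
                        ipaqNoiseSd = 0.4,
                        fragLogitSd = 0.25, activeLevelSd = 0.25,
                        rhythmLogSd = 0.2, acroSd = 1.5) {
  p <- list(mesor = mesor, amplitude = amplitude, acrophase = acrophase,
            noiseSd = noiseSd,
            pActiveGivenSedentary = pActiveGivenSedentary,
            pSedentaryGivenActive = pSedentaryGivenActive,
            activeCountLogMean = activeCountLogMean,
            activeCountLogSd = activeCountLogSd,
            sleepWindow = sleepWindow,
            nonwearRate = nonwearRate,
            nonwearMinLen = as.integer(nonwearMinLen),
            ageMean = ageMean, ageSd = ageSd,
            bmiMean = bmiMean, bmiSd = bmiSd, pFemale = pFemale,
            ipaqNoiseSd = ipaqNoiseSd,
            fragLogitSd = fragLogitSd, activeLevelSd = activeLevelSd,
            rhythmLogSd = rhythmLogSd, acroSd = acroSd)
  class(p) <- "GroupParams"
  validateGroupParams(p)
  p
}

validateGroupParams <- function(p) {
  pr <- c(p$pActiveGivenSedentary, p$pSedentaryGivenActive, p$pFemale)
  if (any(pr <= 0 | pr >= 1))
    stop("transition and covariate probabilities must lie in (0, 1)")
  if (p$amplitude < 0 || p$amplitude > p$mesor)
    stop("amplitude must lie in [0, mesor] (nonnegative expected rate)")
  if (p$acrophase < 0 || p$acrophase >= 24)
    stop("acrophase must lie in [0, 24)")
  if (p$nonwearMinLen < 90L)
    stop("nonwearMinLen below 90 minutes would be undetectable by the ",
         "90-minute all-zero nonwear rule")
  if (p$nonwearRate < 0) stop("nonwearRate must be nonnegative")
  het <- c(p$fragLogitSd, p$activeLevelSd, p$rhythmLogSd, p$acroSd)
  if (any(het < 0))
    stop("between-subject heterogeneity SDs must be nonnegative")
  invisible(p)
}

#' Default group parameters emulating a three-group MS cohort
#'
#' Returns generating parameters for the three study groups (RRMS-Stable,
#' RRMS-Suspected progression, PMS) chosen so that cohort-level metric
#' means fall near the reported scales: group ASTP-like transition
#' probabilities 0.27 / 0.26 / 0.30 with SATP-like 0.09 throughout, latent
#' cosinor acrophases 14.56 / 14.61 / 14.76 h, and progressively lower
#' activity-rate level and active-minute count magnitude in the PMS group
#' (lower TAC, MVPA and rhythm amplitude; higher ASTP).
#'
#' @return Named list of three [groupParams()] objects.
#' @export
defaultGroupParams <- function() {
  list(
    `RRMS-Stable` = groupParams(
      mesor = 1313, amplitude = 1000, acrophase = 14.56,
      pSedentaryGivenActive = 0.27,
      activeCountLogMean = log(3000) - 0.5,
      ageMean = 53, ageSd = 7, bmiMean = 29.4, bmiSd = 6.4, pFemale = 0.71),
    `RRMS-Suspected` = groupParams(
      mesor = 1264, amplitude = 950, acrophase = 14.61,
      pSedentaryGivenActive = 0.26,
      activeCountLogMean = log(3000) - 0.5,
      ageMean = 54, ageSd = 8, bmiMean = 28.2, bmiSd = 5.6, pFemale = 0.74),
    PMS = groupParams(
      mesor = 1120, amplitude = 850, acrophase = 14.76,
      pSedentaryGivenActive = 0.30,
      activeCountLogMean = log(2700) - 0.5,
      ageMean = 57, ageSd = 9, bmiMean = 28.0, bmiSd = 6.2, pFemale = 0.67))
}

## hour-of-day grid at minute resolution (midpoints not needed; left edges)
minuteHours <- function() (seq_len(MINUTES_PER_DAY) - 1L) / 60

inSleepWindow <- function(hours, window) {
  s <- window[1]; e <- window[2]
  if (s == e) return(rep(FALSE, length(hours)))
  if (s < e) hours >= s & hours < e else hours >= s | hours < e
}

## Active-state occupancy curve pi(t): logistic transform of the cosinor
## curve, attenuated in the sleep window, with the intercept solved so the
## daily mean occupancy equals the Markov equilibrium
## satp / (satp + astp).  Holding the active->sedentary probability fixed
## and setting p_SA(t) = astp * pi(t) / (1 - pi(t)) then makes the
## stationary empirical SATP and ASTP match the generating probabilities.
activeOccupancy <- function(params) {
  h <- minuteHours()
  satp <- params$pActiveGivenSedentary
  astp <- params$pSedentaryGivenActive
  pi0 <- satp / (satp + astp)
  k <- if (params$mesor > 0) 2 * params$amplitude / params$mesor else 0
  shape <- k * cos(2 * pi * (h - params$acrophase) / 24)
  atten <- ifelse(inSleepWindow(h, params$sleepWindow), 0.08, 1)
  f <- function(a) mean(plogis(a + shape) * atten) - pi0
  lo <- qlogis(pi0) - 12; hi <- qlogis(pi0) + 12
  a <- tryCatch(stats::uniroot(f, c(lo, hi))$root, error = function(e) NA)
  if (is.na(a)) stop("could not calibrate the occupancy curve; ",
                     "equilibrium occupancy unreachable under attenuation")
  plogis(a + shape) * atten
}

markovStatesFromOccupancy <- function(occ, astp, nDays, u) {
  nMin <- nDays * MINUTES_PER_DAY
  pSA <- pmin(astp * occ / pmax(1 - occ, 1e-9), 0.99)
  states <- logical(nMin)                # TRUE = active
  s <- u[1] < occ[1]
  states[1] <- s
  for (t in 2:nMin) {
    m <- ((t - 1L) %% MINUTES_PER_DAY) + 1L
    s <- if (s) u[t] >= astp else u[t] < pSA[m]
    states[t] <- s
  }
  states
}

#' Simulate one subject's minute-epoch count series
#'
#' Generates \code{nDays} x 1440 nonnegative integer counts from the
#' coupled Markov/cosinor model described in [groupParams()], inserts
#' nonwear episodes as all-zero runs of at least \code{nonwearMinLen}
#' minutes, and returns the ground truth needed by recovery tests.
#'
#' @param params a [groupParams()] object.
#' @param nDays number of days (default 14).
#' @param seed integer seed; fully determines the output.
#' @param subjectId identifier for the returned series.
#' @param nonactiveMax count threshold aligning generating states with the
#'   active/sedentary dichotomy (default 2000).
#' @return List with elements \code{series} (a [MinuteSeries-class]) and
#'   \code{truth} (generating parameters, the active-state and wear masks,
#'   and the subject's true mean MVPA/LIPA minutes per day).
#' @examples
#' sub <- simulateSubject(groupParams(), nDays = 2, seed = 1)
#' sub$series
#' @export
simulateSubject <- function(params, nDays = 14, seed = 1,
                            subjectId = "S1", nonactiveMax = 2000) {
  validateGroupParams(params)
  stopifnot(nDays >= 1)
  set.seed(as.integer(seed))
  nMin <- nDays * MINUTES_PER_DAY

  ## person-level heterogeneity: perturb the group parameters once per
  ## subject so cohorts show realistic between-subject spread
  nominal <- params
  eff <- params
  eff$pSedentaryGivenActive <- plogis(
    qlogis(params$pSedentaryGivenActive) + rnorm(1, 0, params$fragLogitSd))
  eff$pActiveGivenSedentary <- plogis(
    qlogis(params$pActiveGivenSedentary) + rnorm(1, 0, params$fragLogitSd))
  eff$activeCountLogMean <- params$activeCountLogMean +
    rnorm(1, 0, params$activeLevelSd)
  rhythmMult <- exp(rnorm(1, 0, params$rhythmLogSd))
  eff$mesor <- params$mesor * rhythmMult
  eff$amplitude <- params$amplitude * rhythmMult
  eff$acrophase <- (params$acrophase + rnorm(1, 0, params$acroSd)) %% 24

  occ <- activeOccupancy(eff)
  states <- markovStatesFromOccupancy(occ, eff$pSedentaryGivenActive,
                                      nDays, runif(nMin))
  params <- eff

  h <- rep(minuteHours(), nDays)
  sleep <- inSleepWindow(h, params$sleepWindow)
  counts <- numeric(nMin)
  nAct <- sum(states)
  ## active minutes: cut point + lognormal excess (heavy right tail)
  counts[states] <- nonactiveMax + 1 +
    rlnorm(nAct, params$activeCountLogMean, params$activeCountLogSd)
  ## sedentary minutes: low counts, near zero inside the sleep window
  sedMean <- ifelse(sleep[!states], 30, 400)
  sedRaw <- abs(rnorm(nMin - nAct, sedMean, sedMean))
  counts[!states] <- pmin(sedRaw, nonactiveMax)
  if (params$noiseSd > 0)
    counts <- pmax(counts + rnorm(nMin, 0, params$noiseSd), 0)

  ## nonwear: all-zero runs of >= nonwearMinLen minutes
  wearTruth <- rep(TRUE, nMin)
  nEpisodes <- stats::rpois(1, params$nonwearRate * nDays)
  if (nEpisodes > 0) {
    for (i in seq_len(nEpisodes)) {
      len <- params$nonwearMinLen +
        floor(runif(1, 0, params$nonwearMinLen))
      start <- floor(runif(1, 1, nMin - len))
      idx <- start:(start + len - 1)
      counts[idx] <- 0
      wearTruth[idx] <- FALSE
    }
  }
  counts <- round(counts)

  cm <- matrix(counts, ncol = MINUTES_PER_DAY, byrow = TRUE)
  series <- minuteSeries(subjectId, cm)
  stMat <- matrix(states, ncol = MINUTES_PER_DAY, byrow = TRUE)
  dayMin <- states & wearTruth
  excess <- counts - nonactiveMax
  trueMvpa <- sum(dayMin & excess > 4750) / nDays
  trueLipa <- sum(dayMin & excess <= 4750) / nDays
  list(series = series,
       truth = list(params = params, nominalParams = nominal,
                    states = stMat,
                    wear = matrix(wearTruth, ncol = MINUTES_PER_DAY,
                                  byrow = TRUE),
                    occupancy = occ,
                    trueMvpaMinPerDay = trueMvpa,
                    trueLipaMinPerDay = trueLipa))
}

#' Configuration of a synthetic cohort
#'
#' @param nPerGroup subjects per group (>= 1).
#' @param nDays days of wear per subject (default 14).
#' @param groupParams named list of [groupParams()] objects, one per group
#'   (default [defaultGroupParams()]).
#' @param dstEvents list of \code{list(day =, direction =)} daylight-saving
#'   events injected into every subject's series
#'   (\code{direction} is \code{"forward"} or \code{"back"}).
#' @param seed integer seed; fully determines the cohort.
#' @return Validated list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nPerGroup = 85, nDays = 14,
                         groupParams = defaultGroupParams(),
                         dstEvents = list(), seed = 1) {
  stopifnot(nPerGroup >= 1, nDays >= 1, length(groupParams) >= 1,
            !is.null(names(groupParams)))
  lapply(groupParams, validateGroupParams)
  cfg <- list(nPerGroup = as.integer(nPerGroup), nDays = as.integer(nDays),
              groupParams = groupParams, dstEvents = dstEvents,
              seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  cfg
}

ipaqCategory <- function(metMin) {
  cut(metMin, c(-Inf, 600, 3000, Inf),
      labels = c("low", "moderate", "high"), right = TRUE)
}

#' Simulate a full synthetic cohort
#'
#' Generates minute-epoch series, covariates and IPAQ summaries for
#' \code{nPerGroup} subjects in each configured group.  The IPAQ
#' MET-minute summary is derived from the subject's true MVPA and LIPA
#' minutes (4 and 2.5 METs respectively, scaled to a week) with
#' multiplicative lognormal reporting noise, then binned into the ordinal
#' low/moderate/high categories at 600 and 3000 MET-min/week.
#'
#' @param config a [cohortConfig()].
#' @return An [ActigraphyCohort-class]; per-subject generating truth is
#'   retained in the \code{truth} slot.
#' @examples
#' coh <- simulateCohort(cohortConfig(nPerGroup = 2, nDays = 3, seed = 7))
#' coh
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  groups <- names(config$groupParams)
  series <- list(); truth <- list(); rows <- list()
  idx <- 0L
  for (g in seq_along(groups)) {
    gp <- config$groupParams[[g]]
    for (i in seq_len(config$nPerGroup)) {
      idx <- idx + 1L
      sid <- sprintf("S%03d", idx)
      subSeed <- (as.numeric(config$seed) * 100003 + idx * 7919) %%
        2147483647
      sub <- simulateSubject(gp, nDays = config$nDays, seed = subSeed,
                             subjectId = sid)
      for (ev in config$dstEvents)
        sub$series <- injectDst(sub$series, ev$day, ev$direction)
      set.seed((subSeed + 13L) %% 2147483647L)
      age <- round(rnorm(1, gp$ageMean, gp$ageSd), 1)
      bmi <- round(rnorm(1, gp$bmiMean, gp$bmiSd), 1)
      sex <- if (runif(1) < gp$pFemale) "female" else "male"
      trueMet <- 7 * (4 * sub$truth$trueMvpaMinPerDay +
                      2.5 * sub$truth$trueLipaMinPerDay)
      met <- trueMet * exp(rnorm(1, 0, gp$ipaqNoiseSd))
      series[[sid]] <- sub$series
      truth[[sid]] <- sub$truth
      rows[[sid]] <- data.frame(
        subject_id = sid, group = groups[g], age = age, sex = sex,
        bmi = bmi, ipaq_met_min = met,
        ipaq_category = as.character(ipaqCategory(met)),
        stringsAsFactors = FALSE)
    }
  }
  subjects <- do.call(rbind, rows)
  rownames(subjects) <- NULL
  new("ActigraphyCohort", series = series, subjects = subjects,
      truth = truth)
}

#' Inject a daylight-saving transition into a series
#'
#' A spring-forward transition removes one clock hour: the skipped hour's
#' 60 minutes are marked missing (\code{NA}).  A fall-back transition
#' repeats one clock hour: the second copy of the repeated hour is stored
#' as a duplicate block alongside the series until [resolveDst()] averages
#' the two copies.
#'
#' @param series a [MinuteSeries-class].
#' @param day day index of the transition.
#' @param direction \code{"forward"} or \code{"back"}.
#' @param hour clock hour affected (default 2 for forward — 02:00 to 02:59
#'   skipped — and 1 for back — 01:00 to 01:59 repeated).
#' @param duplicateValues optional 60-vector for the second observed copy
#'   of the repeated hour; defaults to the recorded hour itself.
#' @return The modified series.
#' @export
injectDst <- function(series, day, direction = c("forward", "back"),
                      hour = NULL, duplicateValues = NULL) {
  direction <- match.arg(direction)
  if (day < 1 || day > nDays(series))
    stop("DST day index out of range")
  if (is.null(hour)) hour <- if (direction == "forward") 2L else 1L
  mins <- (hour * 60L + 1L):((hour + 1L) * 60L)
  if (direction == "forward") {
    series@counts[day, mins] <- NA_real_
  } else {
    vals <- if (is.null(duplicateValues)) series@counts[day, mins] else
      as.numeric(duplicateValues)
    stopifnot(length(vals) == 60L)
    series@dupBlocks <- c(series@dupBlocks,
                          list(list(day = day, minutes = mins,
                                    values = vals)))
  }
  series@dstEvents <- rbind(series@dstEvents,
                            data.frame(day = day, direction = direction))
  series
}

#' Observed minute-observations carried by one day
#'
#' Counts non-missing minutes plus any duplicate-hour observations not yet
#' resolved: 1380 for a spring-forward day, 1500 for a fall-back day,
#' 1440 otherwise.
#'
#' @param series a [MinuteSeries-class].
#' @param day day index.
#' @return Integer number of observations.
#' @export
dayObservedMinutes <- function(series, day) {
  n <- sum(!is.na(series@counts[day, ]))
  for (b in series@dupBlocks) if (b$day == day) n <- n + length(b$values)
  as.integer(n)
}

#' Simulate a pure additive cosinor signal
#'
#' Minute-level series \eqn{x(t) = M + A\cos(2\pi (t - \phi)/24) +
#' \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}, used to validate the
#' cosinor estimator under its own generating model.  With
#' \code{truncate = FALSE} (the default) values may be negative, since the
#' additive model places no floor; \code{truncate = TRUE} clips at zero and
#' rounds, yielding counts admissible in a [MinuteSeries-class].
#'
#' @param mesor,amplitude,acrophase cosinor parameters (counts, counts,
#'   hours).
#' @param nDays number of days.
#' @param noiseSd additive noise SD in counts.
#' @param seed integer seed.
#' @param truncate clip at zero and round to integer counts.
#' @return Numeric \code{nDays} x 1440 matrix.
#' @examples
#' x <- simulateCosinorSubject(1000, 500, 14, nDays = 2, noiseSd = 0)
#' cosinorFit(as.vector(t(x)), rep(minuteOfDayHours(), 2))
#' @export
simulateCosinorSubject <- function(mesor, amplitude, acrophase, nDays = 14,
                                   noiseSd = 500, seed = 1,
                                   truncate = FALSE) {
  set.seed(as.integer(seed))
  h <- rep(minuteHours(), nDays)
  x <- mesor + amplitude * cos(2 * pi * (h - acrophase) / 24)
  if (noiseSd > 0) x <- x + rnorm(length(x), 0, noiseSd)
  if (truncate) x <- round(pmax(x, 0))
  matrix(x, ncol = MINUTES_PER_DAY, byrow = TRUE)
}

#' Simulate a stationary two-state active/sedentary minute chain
#'
#' First-order Markov chain over \{sedentary, active\} with constant
#' transition probabilities, initialized from its stationary distribution.
#'
#' @param pActiveGivenSedentary sedentary-to-active transition probability.
#' @param pSedentaryGivenActive active-to-sedentary transition probability.
#' @param nMinutes chain length.
#' @param seed integer seed.
#' @return Logical vector, \code{TRUE} = active.
#' @export
simulateBinaryStates <- function(pActiveGivenSedentary,
                                 pSedentaryGivenActive,
                                 nMinutes, seed = 1) {
  stopifnot(pActiveGivenSedentary > 0, pActiveGivenSedentary < 1,
            pSedentaryGivenActive > 0, pSedentaryGivenActive < 1)
  set.seed(as.integer(seed))
  u <- runif(nMinutes)
  pi0 <- pActiveGivenSedentary /
    (pActiveGivenSedentary + pSedentaryGivenActive)
  states <- logical(nMinutes)
  s <- u[1] < pi0
  states[1] <- s
  if (nMinutes > 1) for (t in 2:nMinutes) {
    s <- if (s) u[t] >= pSedentaryGivenActive else
      u[t] < pActiveGivenSedentary
    states[t] <- s
  }
  states
}

#' Minute-of-day grid in hours
#'
#' Clock hours (0, 1/60, ..., 23 59/60) of the 1440 minute slots, as used
#' by the cosinor fit.
#'
#' @return Numeric vector of length 1440.
#' @export
minuteOfDayHours <- function() minuteHours()
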