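## Physical-activity volume, intensity, composition and fragmentation
## metrics, per day and averaged over a subject's valid days.

PA_2H_NAMES <- sprintf("TAC_%02d_%02d", seq(0, 22, 2), seq(2, 24, 2))

#' Daily volume and intensity metrics
#'
#' Computes, over the wear (non-missing, worn) minutes of one day: total
#' activity counts (TAC), total log-transformed activity counts
#' (TLAC, \eqn{\sum \log(1 + count)}), minutes in each intensity class,
#' and TAC within the twelve 2-hour bins of the day.
#'
#' @param counts length-1440 minute counts (\code{NA} = missing).
#' @param wear length-1440 logical wear flags.
#' @param cp a [CutPoints-class].
#' @return Named numeric vector: \code{TAC}, \code{TLAC},
#'   \code{nonactive}, \code{LIPA}, \code{MVPA}, \code{TAC_00_02} ...
#'   \code{TAC_22_24}.
#' @export
dailyVolume <- function(counts, wear, cp) {
  stopifnot(length(counts) == MINUTES_PER_DAY,
            length(wear) == MINUTES_PER_DAY)
  use <- wear & !is.na(counts)
  x <- counts[use]
  cls <- classifyMinute(x, cp)
  bins <- rep(seq_len(12), each = 120L)
  tac2h <- vapply(seq_len(12), function(b) {
    i <- bins == b
    sum(counts[i & use])
  }, numeric(1))
  out <- c(TAC = sum(x), TLAC = sum(log1p(x)),
           nonactive = sum(cls == "nonactive"),
           LIPA = sum(cls == "LIPA"), MVPA = sum(cls == "MVPA"),
           setNames(tac2h, PA_2H_NAMES))
  out
}

#' Activity fragmentation of a minute sequence
#'
#' Dichotomizes the wear minutes of a minute-count sequence (one day, or
#' a subject's concatenated days) into active (count above the nonactive cut)
#' versus sedentary and returns the two transition probabilities:
#' ASTP = (active-to-sedentary transitions) / (active minutes) and
#' SATP = (sedentary-to-active transitions) / (sedentary minutes).
#' Transitions are counted only between adjacent wear minutes, so nonwear
#' gaps break bouts without contributing transitions; the final bout of
#' the sequence contributes minutes but no transition (censoring).
#'
#' @param counts minute counts (\code{NA} = missing).
#' @param wear logical wear flags, same length.
#' @param cp a [CutPoints-class].
#' @return Named vector \code{c(SATP =, ASTP =)}; a probability is
#'   \code{NA} when its source state never occurs.
#' @export
fragmentation <- function(counts, wear, cp) {
  use <- wear & !is.na(counts)
  active <- counts > nonactiveMax(cp)
  idx <- which(use)
  nAct <- sum(active[idx]); nSed <- length(idx) - nAct
  adj <- idx[-length(idx)][diff(idx) == 1L]   # wear minutes whose
  nxt <- adj + 1L                              # successor is also wear
  as_ <- sum(active[adj] & !active[nxt])
  sa <- sum(!active[adj] & active[nxt])
  c(SATP = if (nSed > 0) sa / nSed else NA_real_,
    ASTP = if (nAct > 0) as_ / nAct else NA_real_)
}

#' Per-subject physical-activity features
#'
#' Averages the daily metrics of [dailyVolume()] and [fragmentation()]
#' over the subject's valid days and forms the composition ratios
#' MVPA/LIPA, MVPA/nonactive and LIPA/nonactive from the averaged
#' minutes.
#'
#' @param clean a [CleanSeries-class].
#' @param cp a [CutPoints-class] (default reference 2000/6750).
#' @return Named numeric vector of PA features (Table-style naming:
#'   \code{TAC}, \code{TLAC}, \code{nonactive}, \code{MVPA}, \code{LIPA},
#'   \code{SATP}, \code{ASTP}, \code{MVPA_LIPA}, \code{MVPA_nonactive},
#'   \code{LIPA_nonactive}, \code{TAC_00_02} ... \code{TAC_22_24}).
#' @export
aggregatePa <- function(clean, cp = cutPoints()) {
  stopifnot(is(clean, "CleanSeries"))
  daily <- vapply(seq_len(clean@nValid), function(d)
    dailyVolume(clean@counts[d, ], clean@wear[d, ], cp),
    numeric(5L + 12L))
  frag <- vapply(seq_len(clean@nValid), function(d)
    fragmentation(clean@counts[d, ], clean@wear[d, ], cp), numeric(2))
  avg <- rowMeans(daily)
  fr <- rowMeans(frag, na.rm = TRUE)
  fr[is.nan(fr)] <- NA_real_
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  c(avg[c("TAC", "TLAC", "nonactive", "MVPA", "LIPA")],
    fr,
    MVPA_LIPA = ratio(avg[["MVPA"]], avg[["LIPA"]]),
    MVPA_nonactive = ratio(avg[["MVPA"]], avg[["nonactive"]]),
    LIPA_nonactive = ratio(avg[["LIPA"]], avg[["nonactive"]]),
    avg[PA_2H_NAMES])
}

#' Physical-activity feature table for a cohort
#'
#' @param clean named list of [CleanSeries-class] objects.
#' @param cp a [CutPoints-class].
#' @return data.frame, one row per subject (column \code{subject_id}
#'   first).
#' @export
paFeatures <- function(clean, cp = cutPoints()) {
  rows <- t(vapply(clean, aggregatePa, numeric(22L), cp = cp))
  data.frame(subject_id = names(clean), rows, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
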