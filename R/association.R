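## Group comparisons and covariate-adjusted logistic models.

groupContrast <- function(records, contrast = c("PMS_vs_RRMS",
                                                "Susp_vs_Stable")) {
  contrast <- match.arg(contrast)
  g <- records$group
  if (contrast == "PMS_vs_RRMS") {
    y <- ifelse(g == "PMS", 1L, 0L)
  } else {
    y <- ifelse(g == "RRMS-Suspected", 1L,
                ifelse(g == "RRMS-Stable", 0L, NA_integer_))
  }
  y
}

#' Descriptive group comparison of metrics
#'
#' Continuous metrics are compared between the combined RRMS group
#' (Stable plus Suspected progression) and the PMS group with a Welch
#' two-sample t test; categorical covariates with a Pearson chi-squared
#' test.  Group means (SD) per original group are reported alongside.
#'
#' @param features data.frame with \code{subject_id} and numeric metric
#'   columns.
#' @param records subject table with \code{subject_id} and \code{group}.
#' @param varEqual use the pooled-variance t test instead of Welch.
#' @return data.frame, one row per metric, with per-group mean (SD)
#'   columns and the p value.
#' @export
groupCompare <- function(features, records, varEqual = FALSE) {
  m <- match(features$subject_id, records$subject_id)
  if (anyNA(m)) stop("every subject needs a covariate record")
  grp <- records$group[m]
  y <- ifelse(grp == "PMS", "PMS", "RRMS")
  metrics <- setdiff(names(features), "subject_id")
  groups <- sort(unique(grp))
  rows <- lapply(metrics, function(v) {
    x <- features[[v]]
    ok <- is.finite(x)
    if (length(unique(x[ok])) < 2 || min(table(y[ok])) < 2)
      stop("degenerate metric '", v, "': comparison undefined")
    tt <- t.test(x[ok & y == "RRMS"], x[ok & y == "PMS"],
                 var.equal = varEqual)
    stats <- vapply(groups, function(g) {
      xi <- x[ok & grp == g]
      c(mean(xi), sd(xi))
    }, numeric(2))
    row <- data.frame(metric = v, stringsAsFactors = FALSE)
    for (g in groups) {
      row[[paste0("mean_", g)]] <- stats[1, g]
      row[[paste0("sd_", g)]] <- stats[2, g]
    }
    row$p <- tt$p.value
    row
  })
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p, "BH")
  out
}

#' Covariate-adjusted logistic model for one predictor
#'
#' Maximum-likelihood logistic regression of a binary group contrast on
#' one metric, optionally adjusted for age, sex and BMI, with Wald 95%
#' confidence bounds.  Perfect or quasi-perfect separation is flagged.
#'
#' @param outcome binary 0/1 vector (\code{NA} rows dropped).
#' @param predictor numeric metric vector.
#' @param covariates optional data.frame of adjustment covariates (e.g.
#'   \code{age}, \code{sex}, \code{bmi}).
#' @param scaleBySd divide the predictor by its sample SD before entry.
#' @param name predictor label in the output.
#' @return One-row data.frame: \code{predictor}, \code{estimate}
#'   (log-odds per predictor unit), \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{separation}, \code{scaling_note}.
#' @export
fitLogistic <- function(outcome, predictor, covariates = NULL,
                        scaleBySd = FALSE, name = "x") {
  df <- data.frame(.y = outcome, .x = predictor)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  ## degenerate covariates (single observed level) carry no information
  keep <- vapply(df, function(col) length(unique(col)) > 1, logical(1))
  keep[c(".y", ".x")] <- TRUE
  df <- df[, keep, drop = FALSE]
  if (length(unique(df$.y)) < 2)
    stop("outcome must contain both classes")
  if (length(unique(df$.x)) < 2)
    stop("constant predictor: model undefined")
  note <- "native scale"
  if (scaleBySd) {
    df$.x <- df$.x / sd(df$.x)
    note <- "predictor divided by 1 SD"
  }
  fit <- suppressWarnings(
    glm(.y ~ ., data = df, family = binomial()))
  sep <- !fit$converged || any(abs(coef(fit)) > 50)
  co <- summary(fit)$coefficients[".x", ]
  est <- co[["Estimate"]]; se <- co[["Std. Error"]]
  data.frame(predictor = name, estimate = est,
             ci_low = est - qnorm(0.975) * se,
             ci_high = est + qnorm(0.975) * se,
             p = co[["Pr(>|z|)"]], separation = sep,
             scaling_note = note, stringsAsFactors = FALSE)
}

#' Per-metric adjusted association models
#'
#' Fits [fitLogistic()] for every metric column against a group contrast,
#' adjusted for age, sex and BMI.  TAC and TLAC (daily or 2-hour) are
#' divided by their sample SD before entry; other metrics enter on their
#' native scale.  A Benjamini-Hochberg column accompanies the unadjusted
#' p values.
#'
#' @param features data.frame with \code{subject_id} and metric columns.
#' @param records subject table (\code{subject_id}, \code{group},
#'   \code{age}, \code{sex}, \code{bmi}).
#' @param contrast \code{"PMS_vs_RRMS"} (combined RRMS as reference) or
#'   \code{"Susp_vs_Stable"}.
#' @param sdScaled character vector of metric names to scale by 1 SD
#'   (default: TAC, TLAC and the 2-hour TAC bins).
#' @return data.frame, one row per metric.
#' @export
associationModels <- function(features, records,
                              contrast = "PMS_vs_RRMS",
                              sdScaled = NULL) {
  m <- match(features$subject_id, records$subject_id)
  if (anyNA(m)) stop("every subject needs a covariate record")
  rec <- records[m, , drop = FALSE]
  y <- groupContrast(rec, contrast)
  covs <- data.frame(age = rec$age, sex = factor(rec$sex),
                     bmi = rec$bmi)
  metrics <- setdiff(names(features), "subject_id")
  if (is.null(sdScaled))
    sdScaled <- c("TAC", "TLAC", grep("^TAC_", metrics, value = TRUE))
  sdScaled <- intersect(sdScaled, metrics)
  rows <- lapply(metrics, function(v)
    fitLogistic(y, features[[v]], covs,
                scaleBySd = v %in% sdScaled, name = v))
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p, "BH")
  out$contrast <- contrast
  out
}

#' M10-window sensitivity analysis
#'
#' Recomputes the physical-activity metrics restricted to each subject's
#' most active 10 hours (the M10 window of the mean diurnal profile,
#' circular), accounting for differences in sleep timing and duration:
#' minutes outside the window are masked as nonwear before the PA metrics
#' are recomputed.
#'
#' @param clean named list of [CleanSeries-class] objects.
#' @param cp a [CutPoints-class].
#' @return data.frame of windowed PA features, one row per subject.
#' @export
m10Sensitivity <- function(clean, cp = cutPoints()) {
  windowed <- lapply(clean, function(cl) {
    prof <- diurnalProfile(cl)
    w <- circularWindowMeans(prof, 600L)
    start <- which.max(w)
    idx <- ((start - 1L) + 0:599) %% MINUTES_PER_DAY + 1L
    mask <- rep(FALSE, MINUTES_PER_DAY)
    mask[idx] <- TRUE
    cl@wear <- sweep(cl@wear, 2, mask, "&")
    cl
  })
  paFeatures(windowed, cp)
}
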