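## End-to-end orchestration: simulate/read -> preprocess -> cut points ->
## PA + CR metrics -> fPCA -> JIVE -> association models, with flat CSV
## and JSON intermediates.

#' Pipeline run configuration
#'
#' @param simulation a [cohortConfig()] to simulate from, or \code{NULL}
#'   when reading from files.
#' @param countsCsv,covariatesCsv input paths used when
#'   \code{simulation} is \code{NULL}.
#' @param cutpoints list: \code{nonactive_max}, \code{mvpa_min},
#'   \code{calibrate} (logical; when \code{TRUE} the grid search of
#'   [calibrateCutPoints()] replaces the fixed pair).
#' @param fpca list: \code{K}, \code{binWidth}.
#' @param jive list: \code{ranks} (\code{list(joint =, individual =)}),
#'   \code{select} (permutation rank selection), \code{nPerm},
#'   \code{seed}.
#' @param dareWindow daytime window for [dare()].
#' @param contrasts association contrasts to fit.
#' @param m10Sensitivity rerun the PA metrics inside each subject's M10
#'   window.
#' @param seed master seed.
#' @return List of class \code{"RunConfig"}.
#' @export
pipelineConfig <- function(simulation = cohortConfig(),
                           countsCsv = NULL, covariatesCsv = NULL,
                           cutpoints = list(nonactive_max = 2000,
                                            mvpa_min = 6750,
                                            calibrate = FALSE),
                           fpca = list(K = 5L, binWidth = 10L),
                           jive = list(ranks = list(
                                         joint = 1L,
                                         individual = c(PA = 4L, CR = 3L)),
                                       select = FALSE, nPerm = 100L,
                                       seed = 1L),
                           dareWindow = c(8, 20),
                           contrasts = c("PMS_vs_RRMS", "Susp_vs_Stable"),
                           m10Sensitivity = FALSE,
                           seed = 1L) {
  cfg <- list(simulation = simulation, countsCsv = countsCsv,
              covariatesCsv = covariatesCsv, cutpoints = cutpoints,
              fpca = fpca, jive = jive, dareWindow = dareWindow,
              contrasts = contrasts, m10Sensitivity = m10Sensitivity,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

writeStage <- function(obj, outDir, file) {
  if (is.null(outDir)) return(invisible(NULL))
  path <- file.path(outDir, file)
  if (grepl("\\.csv$", file)) write.csv(obj, path, row.names = FALSE)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and (optionally) writes flat-file
#' intermediates plus a markdown report to \code{outDir}.  Fully
#' deterministic given the configuration seed.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (\code{NULL} = in-memory only).
#' @return List with elements \code{cohort}, \code{clean},
#'   \code{exclusions}, \code{cutpoints}, \code{pa}, \code{cr},
#'   \code{fpca}, \code{jive}, \code{jiveScores}, \code{descriptives},
#'   \code{models}, and \code{counts} (per-stage subject accounting).
#' @examples
#' cfg <- pipelineConfig(simulation = cohortConfig(nPerGroup = 3,
#'                                                 nDays = 4, seed = 2))
#' \donttest{res <- runPipeline(cfg)}
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  ## stage 1: input
  if (!is.null(config$simulation)) {
    cohort <- simulateCohort(config$simulation)
    records <- subjectTable(cohort)
  } else {
    series <- readMinuteCsv(config$countsCsv)
    records <- readCovariatesCsv(config$covariatesCsv)
    cohort <- new("ActigraphyCohort", series = series,
                  subjects = records[match(names(series),
                                           records$subject_id), ,
                                     drop = FALSE],
                  truth = list())
    records <- subjectTable(cohort)
  }
  nIn <- length(cohortSeries(cohort))

  ## stage 2: preprocessing + inclusion
  pre <- preprocessCohort(cohort)
  clean <- pre$clean
  if (!length(clean))
    stop("empty cohort after preprocessing: no subject met the ",
         "3-valid-day inclusion rule")
  records <- records[records$subject_id %in% names(clean), , drop = FALSE]
  writeStage(pre$exclusions, outDir, "exclusions.csv")

  ## stage 3: cut points
  if (isTRUE(config$cutpoints$calibrate)) {
    cal <- calibrateCutPoints(clean, records)
    cp <- cal$cutpoints
    writeStage(cal$grid, outDir, "calibration_grid.csv")
  } else {
    cal <- NULL
    cp <- cutPoints(config$cutpoints$nonactive_max,
                    config$cutpoints$mvpa_min)
  }

  ## stage 4: features
  pa <- paFeatures(clean, cp)
  cr <- crFeatures(clean, config$dareWindow)
  writeStage(pa, outDir, "pa_features.csv")

  ## stage 5: fPCA scores appended to the CR features
  profs <- profileMatrix(clean)
  fp <- fitFpca(profs, K = config$fpca$K, binWidth = config$fpca$binWidth)
  sc <- fpcaScores(fp)
  colnames(sc) <- sprintf("fPC%d", seq_len(ncol(sc)))
  cr <- cbind(cr, as.data.frame(sc, row.names = NULL))
  writeStage(cr, outDir, "cr_features.csv")
  if (!is.null(outDir)) writeFpcaJson(fp, file.path(outDir, "fpca.json"))

  ## stage 6: JIVE
  blocks <- list(featureBlock(pa, "PA"), featureBlock(cr, "CR"))
  if (isTRUE(config$jive$select)) {
    ranks <- selectJiveRanks(blocks, nPerm = config$jive$nPerm,
                             seed = config$jive$seed)
  } else ranks <- config$jive$ranks
  jm <- fitJive(blocks, jointRank = ranks$joint,
                individualRanks = ranks$individual, maxIter = 5000L)
  jsc <- exportJiveScores(jm)
  writeStage(jsc, outDir, "jive_scores.csv")
  writeStage(jiveLoadingReport(jm), outDir, "jive_loadings.csv")

  ## stage 7: association surface
  allFeatures <- merge(pa, cr, by = "subject_id")
  desc <- groupCompare(allFeatures, records)
  writeStage(desc, outDir, "descriptives.csv")
  models <- list()
  for (ctr in config$contrasts) {
    models[[paste0("metrics_", ctr)]] <-
      associationModels(allFeatures, records, contrast = ctr)
    models[[paste0("jive_", ctr)]] <-
      associationModels(jsc, records, contrast = ctr)
  }
  for (nm in names(models)) writeStage(models[[nm]], outDir,
                                       paste0(nm, ".csv"))
  m10 <- NULL
  if (isTRUE(config$m10Sensitivity)) {
    m10 <- m10Sensitivity(clean, cp)
    writeStage(m10, outDir, "pa_features_m10.csv")
  }

  countsLog <- data.frame(stage = c("input", "included"),
                          n = c(nIn, length(clean)))
  writeStage(countsLog, outDir, "subject_counts.csv")
  if (!is.null(outDir)) {
    cfgOut <- config
    cfgOut$simulation <- if (is.null(config$simulation)) NULL else
      config$simulation[c("nPerGroup", "nDays", "seed")]
    jsonlite::write_json(unclass(cfgOut),
                         file.path(outDir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    writeReport(desc, jm, pre, file.path(outDir, "report.md"))
  }

  list(cohort = cohort, clean = clean, exclusions = pre$exclusions,
       cutpoints = cp, calibration = cal, pa = pa, cr = cr, fpca = fp,
       jive = jm, jiveScores = jsc, descriptives = desc, models = models,
       m10 = m10, counts = countsLog)
}

writeReport <- function(desc, jm, pre, path) {
  lines <- c("# Actigraphy pipeline report", "",
             sprintf("- Subjects in: %d; included: %d; excluded: %d",
                     nrow(pre$log), sum(pre$log$included),
                     sum(!pre$log$included)),
             "", "## Group descriptives (first metrics)", "")
  hd <- utils::capture.output(print(head(desc, 12), digits = 3))
  vd <- varDecomposition(jm)
  lines <- c(lines, "```", hd, "```", "", "## JIVE variance decomposition",
             "", "```",
             utils::capture.output(print(round(vd, 3))), "```")
  writeLines(lines, path)
}
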