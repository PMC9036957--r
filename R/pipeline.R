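#' Pipeline configuration
#'
#' Bundles everything a reproducible run needs: the cohort design (preset
#' name or explicit [groupSpec()] list), the grouping factor and its
#' positive class, the parameter combinations for the logistic models, the
#' acquisition scheme, fit options, the mandatory seed and an optional
#' output directory.  When an output directory is given, the configuration
#' is serialized into it (config.yaml) alongside all result tables, so any
#' run can be recreated from its output.
#'
#' @param preset "subtype" or "grade" (ignored when \code{specs} given).
#' @param specs optional explicit list of [groupSpec()] objects.
#' @param nScale group-size multiplier passed to [cohortPreset()].
#' @param positiveLabel class treated as positive in ROC analyses; defaults
#'   to "SCC" for the subtype design and "high" for the grade design.
#' @param combinations list of feature vectors for [logisticCombine()];
#'   default: D+beta, D+mu, beta+mu, D+beta+mu.
#' @param scheme an [AcquisitionScheme-class]; default [cervicalProtocol()].
#' @param fitControl a [frocFitControl()] list.
#' @param seed integer seed, mandatory for any stochastic stage.
#' @param outputDir optional directory for serialized results.
#' @return List of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(preset = c("grade", "subtype"), specs = NULL,
                           nScale = 1, positiveLabel = NULL,
                           combinations = list(
                             c("mean_d", "mean_beta"),
                             c("mean_d", "mean_mu"),
                             c("mean_beta", "mean_mu"),
                             c("mean_d", "mean_beta", "mean_mu")),
                           scheme = cervicalProtocol(),
                           fitControl = frocFitControl(),
                           seed, outputDir = NULL) {
  preset <- match.arg(preset)
  if (missing(seed) || !is.finite(seed)) {
    stop("a seed is mandatory for any stochastic pipeline stage")
  }
  if (is.null(specs)) specs <- cohortPreset(preset, nScale = nScale)
  labels <- vapply(specs, `[[`, "", "label")
  if (is.null(positiveLabel)) {
    positiveLabel <- if ("high" %in% labels) "high"
                     else if ("SCC" %in% labels) "SCC" else labels[1L]
  }
  if (!positiveLabel %in% labels) {
    stop("positiveLabel must be one of the group labels")
  }
  structure(list(preset = preset, specs = specs, nScale = nScale,
                 positiveLabel = positiveLabel, combinations = combinations,
                 scheme = scheme, fitControl = fitControl,
                 seed = as.integer(seed), outputDir = outputDir),
            class = "PipelineConfig")
}

serializeConfig <- function(config, dir) {
  cfg <- list(
    preset = config$preset, nScale = config$nScale,
    positiveLabel = config$positiveLabel,
    combinations = lapply(config$combinations, as.list),
    b_values = config$scheme@bValues,
    delta_small_ms = config$scheme@deltaSmall,
    delta_big_ms = config$scheme@deltaBig,
    gamma = config$scheme@gamma,
    seed = config$seed,
    groups = lapply(config$specs, function(g) g[names(g) != "class"]))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
}

comboName <- function(f) {
  paste(sub("mean_", "", f), collapse = "+")
}

#' Run the cohort-level simulation study
#'
#' End-to-end mirror of a VOI-mean biomarker analysis on synthetic data:
#' sample a cohort from the configured group specifications, compare the
#' four parameters between groups (Mann--Whitney, Bonferroni), run ROC
#' analyses per parameter, fit the logistic combinations, and compare each
#' combination against ADC with the Hanley--McNeil and McNemar tests.
#'
#' @param config a [pipelineConfig()]; \code{config$seed} drives all
#'   randomness, so a fixed config reproduces its tables byte for byte.
#' @param cohort optional pre-built cohort data.frame (e.g. from
#'   [runImagePipeline()]); when supplied the sampling stage is skipped.
#' @return List: \code{cohort}, \code{comparisons} (per-parameter group
#'   statistics), \code{rocUnivariate} and \code{rocCombined} (sensitivity,
#'   specificity, accuracy, AUC with CI per predictor), \code{pairedVsAdc}
#'   (Hanley--McNeil and McNemar p-values of each combination against ADC),
#'   \code{rocObjects}, and \code{log} (per-stage notes).
#' @examples
#' res <- runSimulationStudy(pipelineConfig("grade", seed = 7))
#' res$rocCombined
#' @export
runSimulationStudy <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  logLines <- character()
  note <- function(...) {
    logLines <<- c(logLines, sprintf(...))
  }
  by <- "group"
  if (is.null(cohort)) {
    cohort <- sampleCohort(config$specs, seed = config$seed)
    note("sampled cohort: %d subjects in %d groups", nrow(cohort),
         length(config$specs))
  } else {
    note("using supplied cohort: %d subjects", nrow(cohort))
  }
  pos <- config$positiveLabel
  params <- c("mean_adc", "mean_beta", "mean_d", "mean_mu")

  comparisons <- compareGroups(cohort, by = by, params = params)
  note("group comparison: %d parameters, Bonferroni m = %d", length(params),
       length(params))

  rocTable <- function(name, roc) {
    data.frame(predictor = name, cutoff = roc@cutoff,
               sensitivity = roc@sensitivity, specificity = roc@specificity,
               accuracy = roc@accuracy, auc = roc@auc, auc_ci_low = roc@ciLow,
               auc_ci_high = roc@ciHigh, stringsAsFactors = FALSE)
  }

  rocs <- list()
  uniRows <- list()
  for (pn in params) {
    r <- rocAnalysis(cohort[[pn]], cohort[[by]], positiveLabel = pos)
    rocs[[pn]] <- r
    uniRows[[pn]] <- rocTable(sub("mean_", "", pn), r)
  }
  rocUnivariate <- do.call(rbind, uniRows)

  combRows <- list()
  paired <- list()
  adcRoc <- rocs[["mean_adc"]]
  for (f in config$combinations) {
    nm <- comboName(f)
    cm <- logisticCombine(cohort, f, outcome = by, positiveLabel = pos)
    rocs[[nm]] <- cm@roc
    combRows[[nm]] <- rocTable(nm, cm@roc)
    if (cm@separated) note("combination %s: separation flagged", nm)
    ha <- compareAuc(cm@roc, adcRoc, paired = TRUE)
    mc <- mcnemarTest(rocCorrect(cm@roc), rocCorrect(adcRoc))
    paired[[nm]] <- data.frame(
      combination = nm, auc = cm@roc@auc, auc_adc = adcRoc@auc,
      hanley_mcneil_z = ha$z, hanley_mcneil_p = ha$p, auc_cor = ha$r,
      mcnemar_p = mc$p, stringsAsFactors = FALSE)
  }
  rocCombined <- rbind(rocTable("adc", adcRoc), do.call(rbind, combRows))
  pairedVsAdc <- do.call(rbind, paired)
  rownames(rocUnivariate) <- rownames(rocCombined) <-
    rownames(pairedVsAdc) <- NULL

  out <- list(cohort = cohort, comparisons = comparisons,
              rocUnivariate = rocUnivariate, rocCombined = rocCombined,
              pairedVsAdc = pairedVsAdc, rocObjects = rocs, log = logLines)

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    serializeConfig(config, config$outputDir)
    writeCohortTable(cohort, file.path(config$outputDir, "cohort.csv"))
    utils::write.csv(comparisons,
                     file.path(config$outputDir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(rocUnivariate,
                     file.path(config$outputDir, "roc_univariate.csv"),
                     row.names = FALSE)
    utils::write.csv(rocCombined,
                     file.path(config$outputDir, "roc_combined.csv"),
                     row.names = FALSE)
    utils::write.csv(pairedVsAdc,
                     file.path(config$outputDir, "paired_vs_adc.csv"),
                     row.names = FALSE)
    writeLines(logLines, file.path(config$outputDir, "run.log"))
  }
  out
}

#' Run the image-level pipeline
#'
#' Fits parameter maps for each subject's 4D DWI series, extracts VOI
#' summaries, and assembles the cohort table consumed by the statistics
#' stage of [runSimulationStudy()].  Per-subject failures (e.g. an empty
#' mask) are logged and skipped; the pipeline continues.
#'
#' @param subjects data.frame with one row per subject: \code{subject_id},
#'   \code{dwi} and \code{bval} and \code{mask} file paths (or, for
#'   in-memory use, list-columns \code{volume} and \code{maskArray}), plus
#'   any label columns to carry through (e.g. \code{group}).
#' @param scheme an [AcquisitionScheme-class] used when volumes are given
#'   in memory; ignored for file input (the sidecar defines the b-values).
#' @param fitControl a [frocFitControl()] list.
#' @param fitMode "voxel" (default) fits every masked voxel and averages the
#'   parameters; "voi" averages the decay signal over the VOI first and fits
#'   once per subject.
#' @return List: \code{cohort} (per-subject VOI means with labels),
#'   \code{maps} (per-subject [ParameterMapSet-class]; empty for
#'   \code{fitMode = "voi"}), \code{log}.
#' @export
runImagePipeline <- function(subjects, scheme = cervicalProtocol(),
                             fitControl = frocFitControl(),
                             fitMode = c("voxel", "voi")) {
  fitMode <- match.arg(fitMode)
  stopifnot(is.data.frame(subjects), "subject_id" %in% names(subjects))
  labelCols <- setdiff(names(subjects),
                       c("subject_id", "dwi", "bval", "mask", "volume",
                         "maskArray"))
  rows <- list()
  maps <- list()
  logLines <- character()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    res <- tryCatch({
      if ("volume" %in% names(subjects)) {
        vol <- subjects$volume[[i]]
        msk <- subjects$maskArray[[i]]
        sch <- scheme
      } else {
        rd <- readDwiSeries(subjects$dwi[i], subjects$bval[i],
                            deltaSmall = scheme@deltaSmall,
                            deltaBig = scheme@deltaBig)
        vol <- rd$volume
        sch <- rd$scheme
        msk <- readMask(subjects$mask[i])
      }
      if (fitMode == "voi") {
        if (!any(msk)) stop("empty mask")
        nb <- dim(vol)[4L]
        nv <- prod(dim(vol)[1:3])
        idx <- which(array(as.logical(msk), dim = dim(vol)[1:3]))
        meanSig <- vapply(seq_len(nb), function(j) {
          mean(vol[idx + (j - 1L) * nv])
        }, 0)
        ff <- fitFroc(meanSig, sch, fitControl)
        af <- fitAdcTwoPoint(meanSig, sch)
        list(maps = NULL,
             summary = data.frame(subject_id = as.character(sid),
                                  mean_adc = af@adc,
                                  mean_beta = ff@params@beta,
                                  mean_d = ff@params@d,
                                  mean_mu = ff@params@mu,
                                  n_voxels = length(idx),
                                  stringsAsFactors = FALSE))
      } else {
        pm <- suppressMessages(fitMap(vol, msk, sch, fitControl))
        vs <- voiSummary(pm, subjectId = sid)
        list(maps = pm, summary = vs)
      }
    }, error = function(e) e, warning = function(w) w)
    if (inherits(res, "condition")) {
      logLines <- c(logLines,
                    sprintf("subject %s skipped: %s", sid,
                            conditionMessage(res)))
      next
    }
    if (!is.null(res$maps)) maps[[sid]] <- res$maps
    row <- res$summary
    for (lc in labelCols) row[[lc]] <- subjects[[lc]][i]
    rows[[sid]] <- row
  }
  if (length(logLines)) warning(paste(logLines, collapse = "; "))
  cohort <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(cohort)) rownames(cohort) <- NULL
  list(cohort = cohort, maps = maps, log = logLines)
}
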