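# End-to-end driver: simulate -> features -> nfhas -> search -> train ->
# evaluate, with every artifact written to disk and a manifest tying the
# outputs to the configuration hash and seed.

#' Pipeline configuration
#'
#' Bundles the per-stage settings of [runPipeline()]. All seeds used by
#' the stages are derived from the single `seed` via fixed substreams, so
#' one integer reproduces the whole run.
#'
#' @param nPatients synthetic cohort size.
#' @param seed master seed.
#' @param profiles,recovery,demographics generator settings, see
#'   [syntheticConfig()].
#' @param candidates architecture candidates for the search (list of
#'   hidden-width vectors).
#' @param nRepeats,trainFraction Monte-Carlo cross-validation settings.
#' @param pca apply PCA pre-processing inside search and final training.
#' @param searchMaxEpochs,finalMaxEpochs LM epoch budgets.
#' @param stagingMethod,thresholds severity staging, see
#'   [stageSeverity()].
#' @param nBins error-histogram bins.
#' @param alpha significance level of the paired tables.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(nPatients = 200L, seed = 1L,
                           profiles = severityProfiles(),
                           recovery = recoveryModelSpec(),
                           demographics = NULL,
                           candidates = enumerateArchitectures(17L, 2L),
                           nRepeats = 10L, trainFraction = 0.7, pca = FALSE,
                           searchMaxEpochs = 100L, finalMaxEpochs = 300L,
                           stagingMethod = "threshold",
                           thresholds = c(80, 60, 40, 20),
                           nBins = 20L, alpha = 0.05) {
  cfg <- list(
    nPatients = as.integer(nPatients), seed = as.integer(seed),
    profiles = profiles, recovery = recovery, demographics = demographics,
    candidates = candidates, nRepeats = as.integer(nRepeats),
    trainFraction = trainFraction, pca = pca,
    searchMaxEpochs = as.integer(searchMaxEpochs),
    finalMaxEpochs = as.integer(finalMaxEpochs),
    stagingMethod = stagingMethod, thresholds = thresholds,
    nBins = as.integer(nBins), alpha = alpha
  )
  structure(cfg, class = "PipelineConfig")
}

.configHash <- function(config) {
  flat <- list(
    nPatients = config$nPatients, seed = config$seed,
    recovery = config$recovery[c("coefficients", "intercept", "nonlinearity",
                                 "noise_sd", "group_proportions")],
    candidates = vapply(config$candidates, paste, character(1), collapse = "x"),
    nRepeats = config$nRepeats, trainFraction = config$trainFraction,
    pca = config$pca, searchMaxEpochs = config$searchMaxEpochs,
    finalMaxEpochs = config$finalMaxEpochs,
    stagingMethod = config$stagingMethod, thresholds = config$thresholds,
    nBins = config$nBins, alpha = config$alpha
  )
  textHash(jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA))
}

.needArtifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact %s: run stage '%s' first",
                 basename(path), stage), call. = FALSE)
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in their fixed order, reading any
#' prerequisite not produced in this call from `outDir` (and failing with
#' a message naming the stage to run first when it is absent):
#'
#' * `simulate` — generate the synthetic cohort and write its CSVs.
#' * `features` — scaled-MAD outlier exclusion, raw and z-scored
#'   18-predictor tables, NFHAS-difference targets.
#' * `nfhas` — NFHAS score and severity type per patient and time point.
#' * `search` — Monte-Carlo cross-validation over the candidate
#'   architectures.
#' * `train` — final 70/30 split and LM training of the selected
#'   architecture; serialized model and predictions.
#' * `evaluate` — held-out regression R, quadrant percentages, error
#'   histogram and per-quadrant paired tables.
#'
#' @param config a [pipelineConfig()].
#' @param outDir artifact directory.
#' @param stages subset of the six stage names, any order (executed in
#'   pipeline order).
#' @return named list of file paths written, invisibly; the run manifest
#'   is `manifest.json`.
#' @export
runPipeline <- function(config, outDir,
                        stages = c("simulate", "features", "nfhas",
                                   "search", "train", "evaluate")) {
  stopifnot(inherits(config, "PipelineConfig"))
  allStages <- c("simulate", "features", "nfhas", "search", "train", "evaluate")
  stages <- allStages[allStages %in% match.arg(stages, allStages, several.ok = TRUE)]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  cohort <- NULL
  filtered <- NULL
  rawFeat <- NULL
  target <- NULL
  best <- NULL

  loadCohort <- function() {
    if (is.null(cohort)) {
      .needArtifact(file.path(outDir, "cohort_baseline.csv"), "simulate")
      cohort <<- readCohortCSV(outDir)
    }
    cohort
  }
  loadFeatures <- function() {
    if (is.null(rawFeat)) {
      path <- .needArtifact(file.path(outDir, "features_raw.csv"), "features")
      tab <- utils::read.csv(path, stringsAsFactors = FALSE)
      rawFeat <<- as.matrix(tab[, featureNames()])
      rownames(rawFeat) <<- tab$patient_id
      target <<- stats::setNames(tab$target, tab$patient_id)
    }
    rawFeat
  }

  if ("simulate" %in% stages) {
    sc <- syntheticConfig(
      nPatients = config$nPatients, seed = config$seed,
      profiles = config$profiles, recovery = config$recovery
    )
    if (!is.null(config$demographics)) sc$demographics <- config$demographics
    cohort <- generateCohort(sc)
    writeCohortCSV(cohort, outDir)
    files <- c(files, file.path(outDir, c(
      "cohort_baseline.csv", "cohort_followup.csv", "cohort_truth.json"
    )))
  }

  if ("features" %in% stages) {
    filtered <- filterOutlierPatients(loadCohort())
    bl <- baselineRecords(filtered)
    fu <- followupRecords(filtered)
    rawFeat <- rawFeatures(bl)
    target <- buildTarget(bl, fu)
    rawTab <- data.frame(patient_id = rownames(rawFeat), rawFeat,
                         target = unname(target),
                         stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.csv(rawTab, file.path(outDir, "features_raw.csv"),
                     row.names = FALSE)
    zfit <- zscoreFitMatrix(rawFeat)
    zTab <- data.frame(patient_id = rownames(rawFeat), zfit$values,
                       target = unname(target),
                       stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.csv(zTab, file.path(outDir, "features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(center = as.list(zfit$center), scale = as.list(zfit$scale),
           excluded = as.list(attr(filtered, "excluded"))),
      file.path(outDir, "zscore_params.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    files <- c(files, file.path(outDir, c(
      "features_raw.csv", "features.csv", "zscore_params.json"
    )))
  }

  if ("nfhas" %in% stages) {
    co <- loadCohort()
    cd <- SummarizedExperiment::colData(co)
    scores <- nfhasScores(co)
    types <- stageSeverity(scores, method = config$stagingMethod,
                           thresholds = config$thresholds)
    tab <- data.frame(
      patient_id = cd$patient_id, time_point = cd$time_point,
      nfhas = as.numeric(scores), severity_type = types,
      stringsAsFactors = FALSE
    )
    tab <- tab[order(tab$patient_id, tab$time_point), ]
    utils::write.csv(tab, file.path(outDir, "nfhas_scores.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(outDir, "nfhas_scores.csv"))
  }

  if ("search" %in% stages) {
    loadFeatures()
    search <- searchArchitectures(
      rawFeat, target, candidates = config$candidates,
      nRepeats = config$nRepeats, trainFraction = config$trainFraction,
      seed = seedStream(config$seed, 4L), pca = config$pca,
      maxEpochs = config$searchMaxEpochs
    )
    best <- search$best
    utils::write.csv(search$report, file.path(outDir, "search_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(hidden = search$best, pca = config$pca),
      file.path(outDir, "selected_architecture.json"),
      digits = NA, pretty = TRUE
    )
    files <- c(files, file.path(outDir, c(
      "search_report.csv", "selected_architecture.json"
    )))
  }

  if ("train" %in% stages) {
    loadFeatures()
    if (is.null(best)) {
      path <- .needArtifact(file.path(outDir, "selected_architecture.json"),
                            "search")
      sel <- jsonlite::read_json(path, simplifyVector = TRUE)
      best <- as.integer(unlist(sel$hidden))
    }
    n <- nrow(rawFeat)
    idx <- withSeed(seedStream(config$seed, 5L),
                    sample.int(n, round(config$trainFraction * n)))
    zfit <- zscoreFitMatrix(rawFeat[idx, , drop = FALSE])
    zTr <- zfit$values
    zVa <- applyZscore(rawFeat[-idx, , drop = FALSE], zfit$center, zfit$scale)
    rotation <- NULL
    if (config$pca) {
      pc <- pcaTransform(zTr)
      zTr <- pc$scores
      zVa <- zVa %*% pc$rotation
      rotation <- pc$rotation
    }
    model <- netModel(ncol(zTr), best, seed = seedStream(config$seed, 6L))
    fit <- trainLM(model, zTr, target[idx], maxEpochs = config$finalMaxEpochs)
    saveNetModel(fit$model, file.path(outDir, "model.json"), extras = list(
      center = as.list(zfit$center), scale = as.list(zfit$scale),
      pca = config$pca,
      rotation = if (is.null(rotation)) NULL else as.numeric(rotation),
      final_train_mse = utils::tail(fit$history, 1),
      epochs = fit$epochs
    ))
    preds <- data.frame(
      patient_id = c(rownames(rawFeat)[idx], rownames(rawFeat)[-idx]),
      split = rep(c("train", "validation"), c(length(idx), n - length(idx))),
      actual = c(unname(target[idx]), unname(target[-idx])),
      predicted = c(forwardPass(fit$model, zTr), forwardPass(fit$model, zVa)),
      stringsAsFactors = FALSE
    )
    preds <- preds[order(preds$split, preds$patient_id), ]
    utils::write.csv(preds, file.path(outDir, "predictions.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(outDir, c("model.json", "predictions.csv")))
  }

  if ("evaluate" %in% stages) {
    path <- .needArtifact(file.path(outDir, "predictions.csv"), "train")
    preds <- utils::read.csv(path, stringsAsFactors = FALSE)
    val <- preds[preds$split == "validation", ]
    if (is.null(filtered)) filtered <- filterOutlierPatients(loadCohort())
    report <- evaluatePredictions(
      stats::setNames(val$predicted, val$patient_id),
      stats::setNames(val$actual, val$patient_id),
      cohort = filtered, nBins = config$nBins, alpha = config$alpha
    )
    jsonlite::write_json(
      list(
        r = report@r, slope = report@slope, intercept = report@intercept,
        mse = report@mse, n = report@n,
        quadrants = report@quadrants, histogram = report@histogram
      ),
      file.path(outDir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    files <- c(files, file.path(outDir, "evaluation.json"))
    for (q in names(report@tables)) {
      for (fam in names(report@tables[[q]])) {
        fn <- sprintf("table_%s_%s.csv", gsub("-", "m", gsub(" ", "", q)), fam)
        utils::write.csv(report@tables[[q]][[fam]], file.path(outDir, fn),
                         row.names = FALSE)
        files <- c(files, file.path(outDir, fn))
      }
    }
  }

  manifest <- list(
    package = "romnet",
    version = as.character(utils::packageVersion("romnet")),
    seed = config$seed,
    config_hash = .configHash(config),
    stages = stages,
    files = sort(basename(files))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, file.path(outDir, "manifest.json")))
}
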