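# Configuration and the end-to-end experiment.

#' Default pipeline configuration
#'
#' Nested list with every tunable of the pipeline. The defaults are the
#' desk-scale study conditions: 10 subjects per group x 40 trials on a
#' 2,000-vertex surface with the planted parietal 300-350 ms attenuation
#' delta = 0.5, 40x40x16 input volumes and the scaled classifier
#' (channels 8/16/32, fc width 32). Set `gridSize = 120`,
#' `convChannels = c(64, 128, 256)`, `fcWidth = 512`,
#' `nVertices = 15002`, `nPerGroup = 49`, `nTrials = 500`,
#' `batchSize = 128` for the full-scale configuration.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    outDir = NULL,
    synth = list(nVertices = 2000L, nRegions = 8L, nPerGroup = 10L,
                 nTrials = 40L, fsHz = 400, tStartMs = -1200, tEndMs = 800,
                 roiRegion = 2L, windowMs = c(300, 350), delta = 0.5,
                 noiseSd = 0.5, subjectSd = 0.2, trialSd = 0.1,
                 scoreName = "MMSE", scoreRho = 0.26, scoreMean = 27,
                 scoreSd = 2),
    inverse = list(enabled = FALSE, nChannels = 32L, snr = 3,
                   depthExponent = 0.5),
    volumize = list(gridSize = 40L, mode = "3d", knn = 4L),
    cnn = list(convChannels = c(8L, 16L, 32L), fcWidth = 32L,
               batchSize = 16L, maxEpochs = 100L, patience = 10L,
               lr = NULL, weightDecay = 1e-5, reserveFraction = 0.2,
               nFolds = 3L),
    explain = list(gamma = 0.25, epsilon = 1e-9,
                   methods = c("lrp", "ggcam")),
    analyze = list(correlations = TRUE)
  )
}

checkKnownKeys <- function(cfg, template, path = "") {
  bad <- setdiff(names(cfg), names(template))
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste0(path, bad, collapse = ", "), call. = FALSE)
  for (nm in names(cfg))
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])))
      checkKnownKeys(as.list(cfg[[nm]]), template[[nm]],
                     paste0(path, nm, "$"))
  invisible(TRUE)
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys, and merges it over
#' [defaultPipelineConfig()]. The configuration round-trips losslessly
#' through [writePipelineConfig()].
#'
#' @param path YAML file path.
#' @return full configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  template <- defaultPipelineConfig()
  checkKnownKeys(cfg, template)
  modifyList(template, cfg)
}

#' @rdname readPipelineConfig
#' @param config a configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

configHash <- function(config) {
  s <- utf8ToInt(paste(utils::capture.output(utils::str(config)),
                       collapse = "\n"))
  h <- 0
  for (b in s) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the end-to-end experiment
#'
#' Simulates the cohort, (optionally) round-trips trials through the
#' forward model and the wMNE inverse, builds the input volumes, runs the
#' leave-one-subject-out pretraining / fine-tuning protocol, computes LRP
#' and guided-GradCAM heatmaps for every fold's evaluation samples,
#' aggregates them over correctly/incorrectly classified patient samples,
#' scores localization of the planted effect, and computes the cohort
#' group and correlation statistics. All artifacts (report JSON, CSV
#' tables, aggregate heatmaps) are written to `outDir` when given; the
#' run is reproducible from the configuration and seed.
#'
#' @param config a configuration list (see [defaultPipelineConfig()]) or a
#'   YAML path.
#' @param seed optional seed overriding `config$seed`.
#' @param outDir optional output directory overriding `config$outDir`.
#' @return the experiment report (list), invisibly.
#' @export
runExperiment <- function(config = defaultPipelineConfig(), seed = NULL,
                          outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  checkKnownKeys(config, defaultPipelineConfig())
  config <- modifyList(defaultPipelineConfig(), config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(outDir)) config$outDir <- outDir
  sy <- config$synth
  seed0 <- as.integer(config$seed)

  surface <- makeSphereSurface(sy$nVertices, sy$nRegions, seed = seed0)
  spec <- effectSpec(roiRegion = sy$roiRegion, windowMs = sy$windowMs,
                     delta = sy$delta, noiseSd = sy$noiseSd,
                     subjectSd = sy$subjectSd, trialSd = sy$trialSd)
  cohort <- simulateCohort(surface, spec, sy$nPerGroup, sy$nTrials,
                           sy$fsHz, sy$tStartMs, sy$tEndMs, seed = seed0)
  cohort <- simulateClinicalScores(cohort, sy$scoreRho, sy$scoreName,
                                   sy$scoreMean, sy$scoreSd,
                                   seed = seed0 + 1L)
  map <- mollweideMap(surface, config$volumize$gridSize,
                      config$volumize$knn)
  transform <- NULL
  if (isTRUE(config$inverse$enabled)) {
    lf <- makeLeadField(surface, config$inverse$nChannels, seed = seed0)
    K <- wmneKernel(lf, depthExponent = config$inverse$depthExponent,
                    snr = config$inverse$snr)$kernel
    G <- gainMatrix(lf)
    transform <- function(E) K %*% (G %*% E)
  }
  volumes <- cohortVolumes(cohort, map, config$volumize$mode,
                           transform = transform)

  arch <- archConfig(config$volumize$mode,
                     inputDim = c(config$volumize$gridSize,
                                  config$volumize$gridSize,
                                  if (config$volumize$mode == "3d") 16L
                                  else 1L),
                     convChannels = config$cnn$convChannels,
                     fcWidth = config$cnn$fcWidth)
  cfg <- trainConfig(batchSize = config$cnn$batchSize,
                     maxEpochs = config$cnn$maxEpochs,
                     patience = config$cnn$patience, lr = config$cnn$lr,
                     weightDecay = config$cnn$weightDecay, seed = seed0)
  loso <- runLoso(volumes, arch, cfg,
                  reserveFraction = config$cnn$reserveFraction,
                  nFolds = config$cnn$nFolds)

  methods <- config$explain$methods
  agg <- list()
  loc <- list()
  peaks <- list()
  plantedMask <- plantedMaskVolume(map, spec, volumeWindows(volumes))
  roiMask <- roiGridMask(map, spec@roiRegion)
  for (m in methods) {
    sums <- list(correct = NULL, incorrect = NULL)
    ns <- c(correct = 0L, incorrect = 0L)
    for (fold in loso$folds) {
      rel <- switch(m,
        lrp = lrp(fold$model, fold$evalVolumes,
                  gamma = config$explain$gamma,
                  epsilon = config$explain$epsilon),
        ggcam = guidedGradCam(fold$model, fold$evalVolumes),
        gbp = guidedBackprop(fold$model, fold$evalVolumes),
        gradcam = gradCam(fold$model, fold$evalVolumes),
        stop("unknown explain method: ", m))
      for (cc in c(correct = TRUE, incorrect = FALSE)) {
        key <- if (cc) "correct" else "incorrect"
        a <- aggregateHeatmaps(rel, fold$metrics$predicted,
                               group = "patient", correct = cc)
        if (a$n > 0) {
          sums[[key]] <- if (is.null(sums[[key]])) a$mean * a$n
                         else sums[[key]] + a$mean * a$n
          ns[[key]] <- ns[[key]] + a$n
        }
      }
    }
    agg[[m]] <- list(
      correct = if (ns[["correct"]] > 0) sums$correct / ns[["correct"]],
      incorrect = if (ns[["incorrect"]] > 0)
        sums$incorrect / ns[["incorrect"]],
      n = ns)
    if (ns[["correct"]] > 0) {
      loc[[m]] <- localizationScore(agg[[m]]$correct, plantedMask)
      if (config$volumize$mode == "3d")
        peaks[[m]] <- roiTimeCourse(agg[[m]]$correct, roiMask,
                                    volumeWindows(volumes))$peakWindow
    }
  }

  meta <- cohortMeta(cohort)
  stats <- groupStatsTable(meta, c("aS", sy$scoreName))
  correlations <- NULL
  if (isTRUE(config$analyze$correlations)) {
    roiCd <- roiMeanCurrentDensity(cohort, spec@roiRegion, spec@windowMs)
    ct <- pearsonOneTailed(roiCd, meta[[sy$scoreName]], "positive")
    correlations <- data.frame(score = sy$scoreName, rho = ct$rho,
                               p = ct$p, n = ct$n)
  }

  report <- list(
    configHash = configHash(config), seed = seed0,
    nSubjects = nrow(meta), nVolumes = nSamples(volumes),
    volumeDim = dim(volumeArray(volumes))[1:3],
    lr = loso$lr,
    reserveControls = loso$reserveControls,
    foldMetrics = lapply(loso$folds, function(f)
      c(subject = f$subject,
        f$metrics[c("accuracy", "precision", "recall", "auroc")])),
    meanMetrics = as.list(loso$meanMetrics),
    localization = loc,
    peakWindows = peaks,
    groupStats = stats,
    correlations = correlations,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", null = "null")
    write.csv(stats, file.path(config$outDir, "group_stats.csv"),
              row.names = FALSE)
    if (!is.null(correlations))
      write.csv(correlations, file.path(config$outDir, "correlations.csv"),
                row.names = FALSE)
    write.csv(meta, file.path(config$outDir, "cohort_meta.csv"),
              row.names = FALSE)
    saveRDS(agg, file.path(config$outDir, "aggregate_heatmaps.rds"))
  }
  invisible(report)
}

cliUsage <- function() {
  paste(
    "usage: cortexplain <command> [--config FILE] [--seed N] [--out DIR]",
    "                   [--log-level LEVEL]",
    "commands: simulate | volumize | train | explain | analyze | run | report",
    sep = "\n")
}

parseCliArgs <- function(argv) {
  out <- list(flags = list(), command = NULL)
  if (!length(argv)) return(out)
  out$command <- argv[1]
  i <- 2L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--") || i == length(argv)) return(NULL)
    out$flags[[sub("^--", "", a)]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' In-process implementation of the shell interface (a thin Rscript wrapper
#' ships in `inst/scripts/cortexplain`). Subcommands: `simulate` (write a
#' cohort container), `volumize` (cohort to volumes), `train` (volumes to
#' LOSO results), `explain` (results to heatmaps), `analyze` (stats
#' tables), `run` (the full experiment), `report` (print a report
#' summary). Flags: `--config`, `--seed`, `--out`, `--log-level`.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 success, 1 failure, 2 usage error).
#' @export
pipelineCli <- function(argv = character()) {
  p <- parseCliArgs(argv)
  cmds <- c("simulate", "volumize", "train", "explain", "analyze", "run",
            "report")
  if (is.null(p) || is.null(p$command) || !(p$command %in% cmds)) {
    message(cliUsage())
    return(2L)
  }
  config <- tryCatch({
    if (!is.null(p$flags$config)) readPipelineConfig(p$flags$config)
    else defaultPipelineConfig()
  }, error = function(e) e)
  if (inherits(config, "error")) {
    message("configuration error: ", conditionMessage(config))
    return(2L)
  }
  if (!is.null(p$flags$seed)) config$seed <- as.integer(p$flags$seed)
  outDir <- if (!is.null(p$flags$out)) p$flags$out
            else if (!is.null(config$outDir)) config$outDir else "."
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  status <- tryCatch({
    sy <- config$synth
    switch(p$command,
      simulate = {
        surface <- makeSphereSurface(sy$nVertices, sy$nRegions,
                                     config$seed)
        spec <- effectSpec(roiRegion = sy$roiRegion,
                           windowMs = sy$windowMs, delta = sy$delta,
                           noiseSd = sy$noiseSd, subjectSd = sy$subjectSd,
                           trialSd = sy$trialSd)
        cohort <- simulateCohort(surface, spec, sy$nPerGroup, sy$nTrials,
                                 sy$fsHz, sy$tStartMs, sy$tEndMs,
                                 seed = config$seed)
        cohort <- simulateClinicalScores(cohort, sy$scoreRho, sy$scoreName,
                                         sy$scoreMean, sy$scoreSd,
                                         seed = config$seed + 1L)
        writeCohort(cohort, file.path(outDir, "cohort.rds"))
      },
      volumize = {
        cohort <- readCohort(file.path(outDir, "cohort.rds"))
        map <- mollweideMap(cohortSurface(cohort), config$volumize$gridSize,
                            config$volumize$knn)
        saveRDS(cohortVolumes(cohort, map, config$volumize$mode),
                file.path(outDir, "volumes.rds"))
      },
      train = {
        volumes <- readRDS(file.path(outDir, "volumes.rds"))
        arch <- archConfig(config$volumize$mode,
                           c(config$volumize$gridSize,
                             config$volumize$gridSize,
                             if (config$volumize$mode == "3d") 16L else 1L),
                           config$cnn$convChannels, config$cnn$fcWidth)
        cfg <- trainConfig(batchSize = config$cnn$batchSize,
                           maxEpochs = config$cnn$maxEpochs,
                           patience = config$cnn$patience,
                           lr = config$cnn$lr,
                           weightDecay = config$cnn$weightDecay,
                           seed = config$seed)
        loso <- runLoso(volumes, arch, cfg, config$cnn$reserveFraction,
                        config$cnn$nFolds)
        saveRDS(loso, file.path(outDir, "loso.rds"))
        jsonlite::write_json(as.list(loso$meanMetrics),
                             file.path(outDir, "metrics.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      explain = {
        loso <- readRDS(file.path(outDir, "loso.rds"))
        heat <- lapply(loso$folds, function(f)
          list(subject = f$subject,
               lrp = lrp(f$model, f$evalVolumes, config$explain$gamma,
                         config$explain$epsilon),
               ggcam = guidedGradCam(f$model, f$evalVolumes)))
        saveRDS(heat, file.path(outDir, "heatmaps.rds"))
      },
      analyze = {
        cohort <- readCohort(file.path(outDir, "cohort.rds"))
        stats <- groupStatsTable(cohortMeta(cohort),
                                 c("aS", sy$scoreName))
        write.csv(stats, file.path(outDir, "group_stats.csv"),
                  row.names = FALSE)
      },
      run = {
        runExperiment(config, outDir = outDir)
      },
      report = {
        rp <- jsonlite::read_json(file.path(outDir, "report.json"))
        cat(jsonlite::toJSON(rp$meanMetrics, auto_unbox = TRUE,
                             pretty = TRUE), "\n")
      })
    0L
  }, error = function(e) {
    message("error [", p$command, "]: ", conditionMessage(e))
    1L
  })
  status
}
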