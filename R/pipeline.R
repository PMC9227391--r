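# Unified run configuration and staged pipeline: simulate -> augment ->
# train -> evaluate -> identify -> scan, each stage writing its artifact
# plus a manifest (config, seed, version) so a run can be reproduced.

.runConfigDefaults <- function() {
  list(
    seed = 1L,
    outDir = "nmrmix-run",
    logLevel = "INFO",
    simulator = list(nCompounds = 24L, multipletsPerCompound = c(2L, 8L),
                     ppmRange = c(0.5, 9.5), gamma = 0.0015,
                     jRange = c(2, 12), spectrometerFreq = 400,
                     gridPoints = 16384L, gridFrom = 11, gridTo = -1),
    augmentation = list(nPairs = 22000L, ratioRange = c(0.2, 1.0),
                        componentsRange = c(2L, 5L), noiseSigma = 0.005,
                        positiveFraction = 0.5,
                        splitSizes = c(18000L, 2000L, 2000L),
                        solventMask = FALSE),
    model = list(nConvLayers = 6L, nKernels = 32L, kernelSize = 5L,
                 poolSize = 2L, denseUnits = 100L, dropoutRate = 0.2,
                 learningRate = 1e-4, epochs = 100L, batchSize = 32L),
    identification = list(threshold = 0.5, mixture = NULL),
    evaluation = list(maxShift = 0.052, shiftStep = 0.003))
}

# recursive merge that rejects keys absent from the defaults
.mergeConfig <- function(base, upd, path = "") {
  for (key in names(upd)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key '", full, "'; valid keys here: ",
           paste(names(base), collapse = ", "))
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(upd[[key]]))
        stop("configuration key '", full, "' must be a section")
      base[[key]] <- .mergeConfig(base[[key]], upd[[key]], full)
    } else {
      base[[key]] <- upd[[key]]
    }
  }
  base
}

#' Fully-defaulted run configuration
#'
#' The defaults reproduce the reference pipeline: a 24-compound library
#' on a 16,384-point grid, 22,000 augmented pairs split
#' 18,000/2,000/2,000, a depth-6 model with learning rate 1e-4 trained
#' for 100 epochs, and a 0.5 identification threshold.
#'
#' @param ... named overrides, e.g. `model = list(epochs = 20)`
#' @return a nested list of class `runConfig`
#' @export
runConfig <- function(...) {
  upd <- list(...)
  structure(.mergeConfig(.runConfigDefaults(), upd), class = "runConfig")
}

#' Load a run configuration from YAML/JSON with overrides
#'
#' Precedence: built-in defaults, then the file, then `overrides`.
#' Unknown keys are rejected with the list of valid keys.
#'
#' @param path YAML (or JSON) configuration file, or `NULL`
#' @param overrides named list applied last
#' @return a `runConfig`
#' @export
loadRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .runConfigDefaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such configuration file: '", path, "'")
    fromFile <- yaml::read_yaml(path)
    if (!is.null(fromFile)) cfg <- .mergeConfig(cfg, fromFile)
  }
  if (length(overrides)) cfg <- .mergeConfig(cfg, overrides)
  structure(cfg, class = "runConfig")
}

.log <- function(config, level, ...) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3)
  if (levels[[level]] >= levels[[config$logLevel %||% "INFO"]])
    message(sprintf("[%s] %s", level, sprintf(...)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

.writeManifest <- function(dir, stage, config) {
  jsonlite::write_json(
    list(stage = stage, config = unclass(config),
         seed = config$seed,
         package = as.character(packageVersion("nmrmix")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, paste0(stage, "-manifest.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

.requireArtifact <- function(path, stage, neededBy) {
  if (!file.exists(path))
    stop("stage '", neededBy, "' needs the output of stage '", stage,
         "'; run '", stage, "' first (missing: ", path, ")")
}

#' Run the pipeline
#'
#' Executes the requested stages in order, each reading the previous
#' stage's artifact from `outDir` and writing its own plus a manifest.
#' Stages: `simulate` (synthetic library), `augment` (pair recipes +
#' split), `train`, `evaluate` (test-partition metrics), `identify`
#' (screen a mixture; needs `identification$mixture`, a spectrum file
#' path, or uses a freshly augmented synthetic mixture when `NULL`),
#' `scan` (translation-invariance scan).
#'
#' @param config a `runConfig`
#' @param stages subset of
#'   `c("simulate", "augment", "train", "evaluate", "identify", "scan")`
#' @param verbose print per-epoch training progress
#' @return invisibly, a list of the artifacts produced
#' @export
runPipeline <- function(config = runConfig(),
                        stages = c("simulate", "augment", "train",
                                   "evaluate"),
                        verbose = FALSE) {
  stages <- match.arg(stages, c("simulate", "augment", "train", "evaluate",
                                "identify", "scan"), several.ok = TRUE)
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  libDir <- file.path(out, "library")
  pairsFile <- file.path(out, "pairs.json")
  modelDir <- file.path(out, "model")

  simCfg <- function() {
    s <- config$simulator
    simulatorConfig(nCompounds = s$nCompounds,
                    multipletsPerCompound = s$multipletsPerCompound,
                    ppmRange = s$ppmRange, gamma = s$gamma,
                    jRange = s$jRange, spectrometerFreq = s$spectrometerFreq,
                    grid = seq(s$gridFrom, s$gridTo,
                               length.out = s$gridPoints),
                    seed = .substream(config$seed, 0, 10L))
  }
  augCfg <- function() {
    a <- config$augmentation
    augmentationConfig(nPairs = a$nPairs, ratioRange = a$ratioRange,
                       componentsRange = a$componentsRange,
                       noiseSigma = a$noiseSigma,
                       positiveFraction = a$positiveFraction,
                       splitSizes = a$splitSizes,
                       maskWindows = if (isTRUE(a$solventMask))
                         solventWindows() else NULL,
                       seed = .substream(config$seed, 0, 11L))
  }
  rebuildPairs <- function(lib) splitPairSet(buildPairSet(lib, augCfg()))

  if ("simulate" %in% stages) {
    .log(config, "INFO", "simulate: generating %d synthetic compounds",
         config$simulator$nCompounds)
    lib <- generateLibrary(simCfg())
    writeLibrary(lib, libDir)
    .writeManifest(out, "simulate", config)
    artifacts$library <- libDir
  }
  if ("augment" %in% stages) {
    .requireArtifact(libDir, "simulate", "augment")
    lib <- loadLibrary(libDir)
    .log(config, "INFO", "augment: %d pairs", config$augmentation$nPairs)
    ps <- rebuildPairs(lib)
    jsonlite::write_json(
      list(nPairs = length(ps), labels = pairLabels(ps),
           targets = pairTargets(ps),
           partition = as.character(pairPartition(ps)),
           composition = lapply(pairComposition(ps), function(d)
             list(index = d$index, ratio = d$ratio)),
           noiseSeeds = ps@noiseSeeds, config = ps@config),
      pairsFile, auto_unbox = TRUE, digits = NA, null = "null")
    .writeManifest(out, "augment", config)
    artifacts$pairs <- pairsFile
  }
  if ("train" %in% stages) {
    .requireArtifact(pairsFile, "augment", "train")
    lib <- loadLibrary(libDir)
    ps <- rebuildPairs(lib)           # bit-identical to the saved recipe
    m <- config$model
    mc <- modelConfig(nConvLayers = m$nConvLayers, nKernels = m$nKernels,
                      kernelSize = m$kernelSize, poolSize = m$poolSize,
                      denseUnits = m$denseUnits, dropoutRate = m$dropoutRate,
                      learningRate = m$learningRate, epochs = m$epochs,
                      batchSize = m$batchSize,
                      seed = .substream(config$seed, 0, 12L))
    .log(config, "INFO", "train: %d epochs, lr %g", m$epochs, m$learningRate)
    model <- buildPairCNN(mc, length(ppmAxis(lib)))
    model <- trainPairCNN(model, ps, verbose = verbose)
    saveModel(model, modelDir)
    .writeManifest(out, "train", config)
    artifacts$model <- modelDir
  }
  if ("evaluate" %in% stages) {
    .requireArtifact(file.path(modelDir, "weights.rds"), "train", "evaluate")
    lib <- loadLibrary(libDir)
    model <- loadModel(modelDir)
    ev <- evaluatePairSet(model, rebuildPairs(lib), "test",
                          config$identification$threshold)
    jsonlite::write_json(
      list(counts = unclass(ev$counts), metrics = unclass(ev$metrics)),
      file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
    .log(config, "INFO", "evaluate: ACC %.4f TPR %.4f FPR %.4f",
         ev$metrics$ACC, ev$metrics$TPR, ev$metrics$FPR)
    .writeManifest(out, "evaluate", config)
    artifacts$metrics <- file.path(out, "metrics.json")
  }
  if ("identify" %in% stages) {
    .requireArtifact(file.path(modelDir, "weights.rds"), "train", "identify")
    lib <- loadLibrary(libDir)
    model <- loadModel(modelDir)
    mixPath <- config$identification$mixture
    mix <- if (is.null(mixPath)) {
      p <- makePair(lib, 1L, TRUE, augCfg(),
                    seed = .substream(config$seed, 0, 13L))
      p$mixture
    } else readSpectrum(mixPath, format = .guessFormat(mixPath))
    res <- identifyCompounds(model, lib, mix,
                             threshold = config$identification$threshold,
                             maskWindows = if (isTRUE(config$augmentation$solventMask))
                               solventWindows() else NULL)
    writeScreenResult(res, file.path(out, "identification.csv"))
    .writeManifest(out, "identify", config)
    artifacts$identification <- file.path(out, "identification.csv")
  }
  if ("scan" %in% stages) {
    .requireArtifact(file.path(modelDir, "weights.rds"), "train", "scan")
    lib <- loadLibrary(libDir)
    model <- loadModel(modelDir)
    offs <- shiftOffsetGrid(config$evaluation$maxShift,
                            config$evaluation$shiftStep)
    pairs <- buildInvariancePairs(lib, augCfg(),
                                  seed = .substream(config$seed, 0, 14L))
    tab <- do.call(rbind, lapply(seq_along(pairs), function(i) {
      sc <- invarianceScan(model, pairs[[i]]$pure, pairs[[i]]$mixture, offs)
      data.frame(pair = i, mixture = pairs[[i]]$mixtureId,
                 component = pairs[[i]]$componentIndex,
                 offset = sc$offsets, probability = sc$probabilities)
    }))
    utils::write.csv(tab, file.path(out, "shift-scan.csv"), row.names = FALSE)
    .writeManifest(out, "scan", config)
    artifacts$scan <- file.path(out, "shift-scan.csv")
  }
  invisible(artifacts)
}

.guessFormat <- function(path) {
  if (dir.exists(path)) "bruker"
  else if (grepl("\\.(dx|jdx|jcamp)$", path, ignore.case = TRUE)) "jcamp"
  else "table"
}
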