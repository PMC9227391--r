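# Evaluation harness: confusion counts, ACC/TPR/FPR, hyperparameter
# scans, and the chemical-shift translation-invariance experiment.

#' Confusion counts at a threshold
#'
#' A prediction is positive when its probability is strictly greater
#' than the threshold; counts always sum to the number of samples.
#'
#' @param probabilities numeric predictions in [0, 1]
#' @param labels 0/1 reference labels
#' @param threshold decision threshold
#' @return list(TP, TN, FP, FN) of class `confusionCounts`
#' @export
confusionCounts <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- probabilities > threshold
  pos <- labels == 1
  structure(list(TP = sum(pred & pos), TN = sum(!pred & !pos),
                 FP = sum(pred & !pos), FN = sum(!pred & pos)),
            class = "confusionCounts")
}

#' Accuracy, sensitivity and false positive rate
#'
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, `TPR = TP / (TP + FN)`,
#' `FPR = FP / (TN + FP)`.  Undefined denominators raise an error
#' rather than returning a silent 0.
#'
#' @param counts a `confusionCounts` list (or any list with TP/TN/FP/FN)
#' @return list(ACC, TPR, FPR) of class `metricsReport`
#' @examples
#' classificationMetrics(confusionCounts(c(.9, .2), c(1, 0)))
#' @export
classificationMetrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be non-negative")
  n <- TP + TN + FP + FN
  if (n == 0) stop("no samples: ACC is undefined")
  if (TP + FN == 0) stop("no positive samples: TPR is undefined")
  if (TN + FP == 0) stop("no negative samples: FPR is undefined")
  structure(list(ACC = (TP + TN) / n, TPR = TP / (TP + FN),
                 FPR = FP / (TN + FP)),
            class = "metricsReport")
}

#' Evaluate a trained model on a pair-set partition
#'
#' Predicts every pair of the partition and reports confusion counts and
#' metrics at the given threshold.
#'
#' @param model a trained [PairCNN-class]
#' @param pairset a [SpectralPairSet-class]
#' @param partition `"train"`, `"val"`, `"test"` or `NULL` for all pairs
#' @param threshold decision threshold
#' @return list with `counts`, `metrics` and `probabilities`
#' @export
evaluatePairSet <- function(model, pairset, partition = "test",
                            threshold = 0.5) {
  dat <- realizePairs(pairset, partition)
  if (!length(dat$labels)) stop("the requested partition is empty")
  probs <- predictPairs(model, dat$pure, dat$mixture)
  counts <- confusionCounts(probs, dat$labels, threshold)
  list(counts = counts, metrics = classificationMetrics(counts),
       probabilities = probs)
}

#' Scan training hyperparameters on a fixed split
#'
#' Trains one model per configuration on the same train/val partitions
#' (and the same data realisation) and tabulates validation accuracy;
#' the row with maximal validation accuracy is flagged best.
#'
#' @param pairset a split [SpectralPairSet-class]
#' @param configs list of [modelConfig()] objects
#' @param verbose print progress
#' @return data.frame(name, epochs, depth, learningRate, valACC, best)
#' @export
hyperparameterScan <- function(pairset, configs, verbose = FALSE) {
  if (!length(configs)) stop("the configuration grid is empty")
  tr <- realizePairs(pairset, "train")
  va <- realizePairs(pairset, "val")
  L <- nrow(tr$pure)
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    if (verbose)
      message(sprintf("config %d/%d: depth %d, lr %g, epochs %d",
                      i, length(configs), cfg$nConvLayers,
                      cfg$learningRate, cfg$epochs))
    model <- buildPairCNN(cfg, L)
    model <- trainPairCNN(model, tr, validation = va)
    probs <- predictPairs(model, va$pure, va$mixture)
    acc <- classificationMetrics(confusionCounts(probs, va$labels))$ACC
    data.frame(name = sprintf("M%d", i), epochs = cfg$epochs,
               depth = cfg$nConvLayers, learningRate = cfg$learningRate,
               valACC = acc)
  })
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.max(out$valACC)
  out
}

# --- chemical-shift invariance --------------------------------------------

#' Translate a spectrum along the ppm axis
#'
#' Peaks move by `delta` ppm (positive = towards higher ppm); the
#' intensity is re-interpolated on the fixed grid and vacated edges are
#' filled with 0.
#'
#' @param spectrum an [NMRSpectrum-class]
#' @param delta shift in ppm; |delta| must be smaller than the ppm span
#' @return the shifted [NMRSpectrum-class] on the same grid
#' @export
shiftSpectrum <- function(spectrum, delta) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  span <- abs(max(spectrum@ppm) - min(spectrum@ppm))
  if (abs(delta) >= span) stop("|delta| must be smaller than the ppm span")
  if (delta == 0) return(spectrum)
  o <- order(spectrum@ppm)
  # value at x after shifting by delta is the old value at x - delta
  y <- approx(spectrum@ppm[o] + delta, spectrum@intensity[o],
              xout = spectrum@ppm, method = "linear", rule = 1)$y
  y[is.na(y)] <- 0
  NMRSpectrum(spectrum@ppm, y, name = spectrum@name, meta = spectrum@meta)
}

#' Symmetric grid of chemical-shift offsets
#'
#' `{-k*step, ..., 0, ..., +k*step}` with `k = floor(maxShift / step)`;
#' the defaults (+-0.052 ppm in 0.003 ppm steps) yield 35 offsets.
#'
#' @param maxShift largest |offset| in ppm
#' @param step offset increment in ppm (> 0)
#' @return numeric vector of offsets, symmetric about and including 0
#' @export
shiftOffsetGrid <- function(maxShift = 0.052, step = 0.003) {
  if (step <= 0) stop("step must be positive")
  k <- floor(maxShift / step)
  (-k:k) * step
}

#' Scan a trained model over chemical-shift variations of one pair
#'
#' Only the mixture spectrum is shifted (the component spectrum stays
#' fixed); one probability is predicted per offset.  `passWindow` is the
#' widest symmetric contiguous offset interval around 0 on which every
#' probability exceeds 0.5 (width 0 when the unshifted pair itself
#' fails).
#'
#' @param model a trained [PairCNN-class]
#' @param pure component [NMRSpectrum-class]
#' @param mixture mixture [NMRSpectrum-class]
#' @param offsets offsets from [shiftOffsetGrid()]
#' @return list(offsets, probabilities, passWindow)
#' @export
invarianceScan <- function(model, pure, mixture,
                           offsets = shiftOffsetGrid()) {
  stopifnot(is(model, "PairCNN"))
  L <- length(mixture@ppm)
  mshift <- vapply(offsets, function(d)
    intensities(shiftSpectrum(mixture, d)), numeric(L))
  probs <- predictPairs(model,
                        matrix(intensities(pure), L, length(offsets)),
                        mshift)
  step <- if (length(offsets) > 1) min(diff(sort(unique(offsets)))) else 1
  kmax <- round(max(abs(offsets)) / step)
  k <- -1
  for (j in 0:kmax) {
    inWin <- abs(offsets) <= j * step + step / 2
    if (all(probs[inWin] > 0.5)) k <- j else break
  }
  passWindow <- if (k < 0) c(0, 0) else c(-k * step, k * step)
  list(offsets = offsets, probabilities = probs, passWindow = passWindow)
}

#' Build the base pairs for the invariance experiment
#'
#' Generates 8 augmented mixtures with 2, 2, 3, 3, 4, 4, 5 and 5
#' components (noise per config) and pairs each mixture with each of its
#' components: 28 base pairs, all labelled 1; crossed with the default
#' 35-offset grid they define 980 varied pairs.
#'
#' @param library an [NMRLibrary-class] with at least 5 entries
#' @param config an [augmentationConfig()] (noise level, ratios, mask)
#' @param seed integer seed
#' @return list of pairs, each `list(pure, mixture, mixtureId, componentIndex)`
#' @export
buildInvariancePairs <- function(library, config = augmentationConfig(),
                                 seed = 1) {
  if (length(library) < 5) stop("library must have at least 5 entries")
  counts <- c(2, 2, 3, 3, 4, 4, 5, 5)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  pairs <- list()
  for (m in seq_along(counts)) {
    set.seed(.substream(seed, m, 3L))
    idx <- sample(seq_len(length(library)), counts[m])
    ratios <- runif(counts[m], config$ratioRange[1], config$ratioRange[2])
    mix <- superpose(library@entries[idx], ratios,
                     noiseSigma = config$noiseSigma,
                     seed = .substream(seed, m, 4L),
                     name = sprintf("invariance_mixture_%d", m))
    y <- .maskIntensity(mix@intensity, library@grid, config$maskWindows)
    mix <- normalizeMax(NMRSpectrum(library@grid, y, name = mix@name))
    for (ci in idx)
      pairs[[length(pairs) + 1]] <-
        list(pure = library@entries[[ci]], mixture = mix,
             mixtureId = m, componentIndex = ci)
  }
  pairs
}

#' Summary statistics of observed chemical-shift deviations
#'
#' Mean, standard deviation (sample, n-1, by default), the interval
#' `mean +- 1.5 * sd` and the fraction of deviations it covers.
#'
#' @param deviations per-peak ppm deviations (mixture peak minus
#'   component peak), non-empty
#' @param sample use the n-1 (sample) standard deviation; `FALSE` for
#'   the population form
#' @return list(deviations, mean, sd, interval, coverage)
#' @export
shiftVariationStats <- function(deviations, sample = TRUE) {
  if (!length(deviations)) stop("deviations must be non-empty")
  m <- mean(deviations)
  s <- if (length(deviations) == 1) 0
       else if (sample) sd(deviations)
       else sqrt(mean((deviations - m)^2))
  interval <- c(m - 1.5 * s, m + 1.5 * s)
  list(deviations = deviations, mean = m, sd = s, interval = interval,
       coverage = mean(deviations >= interval[1] & deviations <= interval[2]))
}

#' Per-peak chemical-shift deviations between a component and a mixture
#'
#' For every local maximum of the component spectrum above
#' `minHeight`, finds the nearest local maximum of the mixture within
#' `maxDist` ppm and records the ppm deviation; peaks inside the
#' excluded windows (solvent/active-hydrogen regions) are skipped.
#' Intended for real spectra where shifts actually vary.
#'
#' @param pure,mixture [NMRSpectrum-class] objects on one grid
#' @param maxDist matching radius in ppm
#' @param minHeight minimum relative peak height considered
#' @param exclude list of ppm windows to skip (default [solventWindows()])
#' @return numeric vector of deviations (ppm), possibly empty
#' @export
peakDeviations <- function(pure, mixture, maxDist = 0.03, minHeight = 0.05,
                           exclude = solventWindows()) {
  findPeaks <- function(s) {
    y <- s@intensity / max(s@intensity)
    n <- length(y)
    i <- which(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] >= y[-c(1, 2)]) + 1
    i <- i[y[i] >= minHeight]
    ppm <- s@ppm[i]
    if (length(exclude))
      for (w in exclude) {
        keep <- !(ppm >= min(w) & ppm <= max(w))
        i <- i[keep]; ppm <- ppm[keep]
      }
    ppm
  }
  pp <- findPeaks(pure)
  pm <- findPeaks(mixture)
  if (!length(pp) || !length(pm)) return(numeric())
  dev <- vapply(pp, function(p) {
    d <- pm - p
    d[which.min(abs(d))]
  }, numeric(1))
  dev[abs(dev) <= maxDist]
}
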