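# Metrics, shift operations and the invariance machinery.

test_that("confusion counts follow the strict-threshold definition", {
  cc <- confusionCounts(c(0.9, 0.2, 0.6, 0.4), c(1, 0, 0, 1), 0.5)
  expect_equal(unclass(cc), list(TP = 1L, TN = 1L, FP = 1L, FN = 1L),
               ignore_attr = TRUE)
  # perfect predictions
  cc2 <- confusionCounts(c(0.99, 0.01), c(1, 0))
  expect_equal(cc2$FP + cc2$FN, 0)
  # conservation
  set.seed(2)
  p <- runif(50); y <- rbinom(50, 1, 0.5)
  cc3 <- confusionCounts(p, y, 0.3)
  expect_equal(cc3$TP + cc3$TN + cc3$FP + cc3$FN, 50)
  expect_error(confusionCounts(c(0.1), c(1, 0)), "equal length")
})

test_that("ACC/TPR/FPR arithmetic matches the defining ratios", {
  m <- classificationMetrics(list(TP = 997, FN = 3, TN = 999, FP = 1))
  expect_equal(m$ACC, 0.9980)
  expect_equal(m$TPR, 0.9970)
  expect_equal(m$FPR, 0.0010)
  all10 <- classificationMetrics(confusionCounts(rep(c(0.9, 0.1), 5),
                                                 rep(c(1, 0), 5)))
  expect_equal(unclass(all10), list(ACC = 1, TPR = 1, FPR = 0),
               ignore_attr = TRUE)
  expect_error(classificationMetrics(list(TP = 0, FN = 0, TN = 5, FP = 5)),
               "TPR is undefined")
  expect_error(classificationMetrics(list(TP = 5, FN = 5, TN = 0, FP = 0)),
               "FPR is undefined")
})

test_that("metrics of confusion counts agree with exhaustive enumeration", {
  # all 2^4 prediction patterns over 4 samples with labels 1,1,0,0
  labels <- c(1, 1, 0, 0)
  for (mask in 0:15) {
    pred <- as.integer(intToBits(mask))[1:4]
    probs <- ifelse(pred == 1, 0.9, 0.1)
    cc <- confusionCounts(probs, labels, 0.5)
    # brute-force counting
    TP <- sum(pred == 1 & labels == 1); TN <- sum(pred == 0 & labels == 0)
    FP <- sum(pred == 1 & labels == 0); FN <- sum(pred == 0 & labels == 1)
    expect_equal(unclass(cc), list(TP = TP, TN = TN, FP = FP, FN = FN),
                 ignore_attr = TRUE)
    m <- classificationMetrics(cc)
    expect_equal(m$ACC, (TP + TN) / 4)
    expect_equal(m$TPR, TP / (TP + FN))
    expect_equal(m$FPR, FP / (TN + FP))
  }
})

test_that("raising the threshold never increases TPR or FPR", {
  set.seed(33)
  p <- runif(200); y <- rbinom(200, 1, 0.5)
  thr <- seq(0.05, 0.95, by = 0.05)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    m <- classificationMetrics(confusionCounts(p, y, thr[i]))
    tpr[i] <- m$TPR; fpr[i] <- m$FPR
  }
  expect_true(all(diff(tpr) <= 1e-12))
  expect_true(all(diff(fpr) <= 1e-12))
})

test_that("spectra translate along ppm by interpolation with zero fill", {
  grid <- testGrid(256)
  step <- abs(diff(grid)[1])
  y <- numeric(256); y[100] <- 1
  s <- NMRSpectrum(grid, y, name = "impulse")
  expect_identical(intensities(shiftSpectrum(s, 0)), y)
  # +3 grid steps towards higher ppm = 3 indices earlier on a
  # descending axis
  sh <- shiftSpectrum(s, 3 * step)
  expect_equal(which.max(intensities(sh)), 97)
  expect_equal(max(intensities(sh)), 1, tolerance = 1e-6)
  # shift there and back recovers the original away from the edges
  back <- shiftSpectrum(shiftSpectrum(s, 5 * step), -5 * step)
  expect_equal(intensities(back)[20:230], y[20:230], tolerance = 1e-6)
  expect_error(shiftSpectrum(s, 100), "span")
})

test_that("the offset grid is symmetric, zero-centred and sized as stated", {
  offs <- shiftOffsetGrid()
  expect_length(offs, 35)                 # +-0.052 ppm in 0.003 steps
  expect_equal(offs, sort(offs))
  expect_true(0 %in% offs)
  expect_equal(offs, -rev(offs))
  expect_equal(max(offs), 0.051)
  expect_equal(shiftOffsetGrid(0.052, 0.06), 0)   # step > max -> {0}
  expect_error(shiftOffsetGrid(0.05, 0), "positive")
})

test_that("shift-variation statistics implement mean +- 1.5 sd coverage", {
  z <- shiftVariationStats(rep(0, 5))
  expect_equal(z$mean, 0); expect_equal(z$sd, 0); expect_equal(z$coverage, 1)
  s <- shiftVariationStats(c(-0.01, 0.01))
  expect_equal(s$mean, 0)
  expect_equal(s$sd, 0.01414, tolerance = 1e-3)
  expect_equal(s$interval, c(-0.0212, 0.0212), tolerance = 1e-2)
  expect_equal(s$coverage, 1)
  # population variant is smaller
  expect_lt(shiftVariationStats(c(-0.01, 0.01), sample = FALSE)$sd, s$sd)
  expect_error(shiftVariationStats(numeric()), "non-empty")
})

test_that("peak deviations are measured to the nearest matching maximum", {
  grid <- testGrid(4096)
  pure <- NMRSpectrum(grid, lorentzianLine(5, 0.01, 1, grid), "p")
  mixt <- NMRSpectrum(grid, lorentzianLine(5.012, 0.01, 1, grid) +
                        lorentzianLine(8, 0.01, 0.7, grid), "m")
  dev <- peakDeviations(pure, mixt)
  expect_length(dev, 1)
  # agreement up to the grid spacing (~0.003 ppm)
  expect_equal(dev, 0.012, tolerance = 0.25)
})

test_that("the invariance pair builder emits 8 mixtures and 28 base pairs", {
  lib <- toyLibrary()
  pairs <- buildInvariancePairs(lib, toyAugConfig(), seed = 2)
  expect_length(pairs, 28)
  expect_equal(length(unique(vapply(pairs, `[[`, 0, "mixtureId"))), 8)
  counts <- table(vapply(pairs, `[[`, 0, "mixtureId"))
  expect_equal(sort(as.integer(counts)), c(2, 2, 3, 3, 4, 4, 5, 5))
  # every pair is mixture-with-own-component: an implicit label of 1
  expect_length(shiftOffsetGrid(), 35)
  expect_equal(28 * 35, 980)
})

test_that("invariance scans are consistent with plain prediction at offset 0", {
  fix <- toyTrainedModel()
  pair <- makePair(fix$library, 6, TRUE, toyAugConfig(), seed = 55)
  offs <- shiftOffsetGrid(0.01, 0.005)
  sc <- invarianceScan(fix$model, pair$pure, pair$mixture, offs)
  expect_length(sc$probabilities, length(offs))
  expect_equal(sc$probabilities[offs == 0],
               predictPair(fix$model, pair$pure, pair$mixture),
               tolerance = 1e-6)
  expect_equal(sc$passWindow, -rev(sc$passWindow))
  if (sc$probabilities[offs == 0] > 0.5)
    expect_true(sc$passWindow[1] <= 0 && sc$passWindow[2] >= 0)
})

test_that("evaluatePairSet composes prediction, counting and metrics", {
  fix <- toyTrainedModel()
  ev <- evaluatePairSet(fix$model, fix$pairs, "val")
  dat <- realizePairs(fix$pairs, "val")
  probs <- predictPairs(fix$model, dat$pure, dat$mixture)
  expect_equal(ev$probabilities, probs)
  expect_equal(ev$metrics,
               classificationMetrics(confusionCounts(probs, dat$labels)))
})

test_that("the hyperparameter scan tabulates one row per configuration", {
  lib <- toyLibrary()
  ps <- splitPairSet(buildPairSet(lib, toyAugConfig(nPairs = 120, seed = 19)))
  configs <- list(
    modelConfig(nConvLayers = 3, epochs = 1, learningRate = 1e-3, seed = 1),
    modelConfig(nConvLayers = 3, epochs = 1, learningRate = 1e-4, seed = 1),
    modelConfig(nConvLayers = 4, epochs = 1, learningRate = 1e-4, seed = 1))
  tab <- hyperparameterScan(ps, configs)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$name, c("M1", "M2", "M3"))
  expect_equal(tab$depth, c(3, 3, 4))
  expect_equal(sum(tab$best), 1)
  expect_equal(which(tab$best), which.max(tab$valACC))
})
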