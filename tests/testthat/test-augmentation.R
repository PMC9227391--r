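# Pair augmentation: superposition, labelling, balance, splitting.

test_that("superposition is the exact ratio-weighted sum when noiseless", {
  grid <- seq(5, 1, length.out = 5)
  a <- NMRSpectrum(grid, c(1, 0, 2, 0, 1), name = "a")
  b <- NMRSpectrum(grid, c(0, 2, 2, 0, 0), name = "b")
  # identity
  expect_equal(intensities(superpose(list(a), 1.0, 0)), intensities(a))
  # hand-computed pointwise average
  s <- superpose(list(a, b), c(0.5, 0.5), 0)
  expect_equal(intensities(s), c(0.5, 1, 2, 0, 0.5))
  # additivity: superpose(A u B) = superpose(A) + superpose(B)
  c2 <- NMRSpectrum(grid, runif(5), name = "c")
  all3 <- superpose(list(a, b, c2), c(0.3, 0.6, 0.9), 0)
  expect_equal(intensities(all3),
               intensities(superpose(list(a, b), c(0.3, 0.6), 0)) +
                 0.9 * intensities(c2))
  expect_error(superpose(list(a, b), 1.0, 0), "equal length")
})

test_that("the additive noise model has the configured amplitude", {
  grid <- defaultGrid()          # 16,384 points
  zero <- NMRSpectrum(grid, numeric(length(grid)) + 1e-12)
  s <- superpose(list(zero), 1.0, noiseSigma = 0.01, seed = 42)
  expect_equal(sd(intensities(s)), 0.01, tolerance = 0.2)
  # deterministic given the seed
  s2 <- superpose(list(zero), 1.0, noiseSigma = 0.01, seed = 42)
  expect_identical(intensities(s), intensities(s2))
})

test_that("pairs honour the positive/negative contract and ratio range", {
  lib <- toyLibrary()
  cfg <- toyAugConfig()
  pos <- makePair(lib, 3, TRUE, cfg, seed = 1)
  expect_equal(pos$label, 1L)
  expect_true(3 %in% pos$composition$index)
  neg <- makePair(lib, 3, FALSE, cfg, seed = 2)
  expect_equal(neg$label, 0L)
  expect_false(3 %in% neg$composition$index)
  for (s in 1:20) {
    p <- makePair(lib, 1 + s %% 8, s %% 2 == 0, cfg, seed = s)
    expect_true(all(p$composition$ratio >= 0.2 & p$composition$ratio <= 1.0))
    expect_false(anyDuplicated(p$composition$index) > 0)
    k <- nrow(p$composition)
    expect_true(k >= 2 && k <= 3)
  }
  expect_error(makePair(toyLibrary(3), 1, TRUE, cfg), "library too small")
})

test_that("pair sets have exact size, balance, label soundness and determinism", {
  lib <- toyLibrary()
  cfg <- augmentationConfig(nPairs = 10, componentsRange = c(2, 3),
                            splitSizes = c(8, 1, 1), seed = 3)
  ps <- buildPairSet(lib, cfg)
  expect_length(ps, 10)
  expect_equal(sum(pairLabels(ps) == 1), 5)
  # label soundness, exhaustively
  comp <- pairComposition(ps)
  for (i in seq_len(10))
    expect_equal(pairLabels(ps)[i] == 1L,
                 pairTargets(ps)[i] %in% comp[[i]]$index)
  # determinism
  ps2 <- buildPairSet(lib, cfg)
  expect_identical(pairTargets(ps2), pairTargets(ps))
  expect_identical(pairComposition(ps2), comp)
})

test_that("every library entry appears as the pure side", {
  lib <- toyLibrary()
  ps <- buildPairSet(lib, toyAugConfig(nPairs = 80))
  expect_setequal(unique(pairTargets(ps)), seq_len(8))
})

test_that("mixing ratios are uniform on the configured range", {
  lib <- toyLibrary()
  ps <- buildPairSet(lib, augmentationConfig(
    nPairs = 5000, componentsRange = c(2, 3),
    splitSizes = c(5000, 0, 0), seed = 9))
  ratios <- unlist(lapply(pairComposition(ps), function(d) d$ratio))
  expect_gt(length(ratios), 10000)
  ks <- suppressWarnings(stats::ks.test(ratios, "punif", 0.2, 1.0))
  expect_gt(ks$p.value, 0.01)
})

test_that("splitting partitions the set into the stated disjoint sizes", {
  lib <- toyLibrary()
  cfg <- augmentationConfig(nPairs = 10, componentsRange = c(2, 3),
                            splitSizes = c(8, 1, 1), seed = 3)
  ps <- splitPairSet(buildPairSet(lib, cfg))
  expect_equal(as.integer(table(pairPartition(ps))[c("train", "val", "test")]),
               c(8L, 1L, 1L))
  expect_false(anyNA(pairPartition(ps)))
  expect_error(splitPairSet(buildPairSet(lib, cfg), sizes = c(9, 1, 1)),
               "sum")
})

test_that("noiseless realisation equals the normalised weighted sum exactly", {
  lib <- toyLibrary()
  cfg <- augmentationConfig(nPairs = 6, componentsRange = c(2, 3),
                            noiseSigma = 0, splitSizes = c(6, 0, 0),
                            seed = 21)
  ps <- buildPairSet(lib, cfg)
  dat <- realizePairs(ps)
  m <- intensities(lib)
  for (i in 1:6) {
    comp <- pairComposition(ps)[[i]]
    y <- as.vector(m[, comp$index, drop = FALSE] %*% comp$ratio)
    expect_equal(dat$mixture[, i], y / max(y), tolerance = 1e-12)
    expect_equal(dat$pure[, i], unname(m[, pairTargets(ps)[i]]))
  }
  expect_identical(dat$labels, pairLabels(ps))
})

test_that("solvent mask windows are zeroed in realised spectra", {
  lib <- toyLibrary()     # toy singlets at 1.5..8.5 ppm
  cfg <- augmentationConfig(nPairs = 4, componentsRange = c(2, 3),
                            splitSizes = c(4, 0, 0),
                            maskWindows = solventWindows(), seed = 2)
  dat <- realizePairs(buildPairSet(lib, cfg))
  g <- ppmAxis(lib)
  inMask <- (g >= 2.45 & g <= 2.55) | (g >= 3.28 & g <= 3.38)
  expect_true(all(dat$mixture[inMask, ] == 0))
  expect_true(all(dat$pure[inMask, ] == 0))
})
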