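# Shared fixtures, all built in code at test time.

# short descending grid for fast tests
testGrid <- function(n = 512, from = 11, to = -1) {
  seq(from, to, length.out = n)
}

# 8 well-separated single-singlet compounds: a linearly separable toy
# world in which a correctly trained classifier can be near-perfect
toyLibrary <- function(n = 8, grid = testGrid(512), gamma = 0.05) {
  entries <- lapply(seq_len(n), function(i) {
    y <- lorentzianLine(center = 0.5 + i, gamma = gamma, amplitude = 1, grid)
    normalizeMax(NMRSpectrum(grid, y, name = sprintf("toy_%02d", i)))
  })
  NMRLibrary(entries)
}

toyAugConfig <- function(nPairs = 240, seed = 11) {
  augmentationConfig(nPairs = nPairs, componentsRange = c(2, 3),
                     splitSizes = c(nPairs - 60, 30, 30), seed = seed)
}

# one trained toy model per session, reused across test files
.fixtureCache <- new.env(parent = emptyenv())

toyTrainedModel <- function() {
  if (!is.null(.fixtureCache$toy)) return(.fixtureCache$toy)
  lib <- toyLibrary()
  ps <- splitPairSet(buildPairSet(lib, toyAugConfig()))
  model <- buildPairCNN(modelConfig(learningRate = 1e-3, epochs = 30,
                                    seed = 7),
                        length(ppmAxis(lib)))
  model <- trainPairCNN(model, ps)
  .fixtureCache$toy <- list(library = lib, pairs = ps, model = model)
  .fixtureCache$toy
}
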