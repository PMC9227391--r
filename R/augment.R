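# Data augmentation: labelled spectral pairs built by superposing
# randomly sampled library spectra at random ratios with additive
# Gaussian noise.  NMR signals are additive, so a ratio-weighted sum of
# pure spectra is a faithful surrogate for a real mixture spectrum.

#' Solvent exclusion windows
#'
#' Default ppm windows zeroed when solvent masking is enabled: the
#' DMSO-d6 residual signal around 2.50 ppm and HDO around 3.33 ppm,
#' which carry no compound-specific information.
#'
#' @return list of (low, high) ppm intervals
#' @export
solventWindows <- function() {
  list(c(2.45, 2.55), c(3.28, 3.38))
}

#' Configuration for pair augmentation
#'
#' Defaults follow the reference protocol: 22,000 pairs, mixing ratios
#' uniform on 0.2-1.0, 2-5 components per augmented mixture, additive
#' Gaussian noise of sd 0.005 relative to unit-max spectra, a balanced
#' 50/50 label split, and an 18,000/2,000/2,000 train/val/test split.
#'
#' @param nPairs total number of pairs
#' @param ratioRange (low, high) mixing-ratio range, 0 < low <= high
#' @param componentsRange (min, max) components per mixture, min >= 2
#' @param noiseSigma sd of the additive Gaussian noise
#' @param positiveFraction fraction of label-1 pairs, in (0, 1)
#' @param splitSizes (train, val, test) counts summing to `nPairs`
#' @param maskWindows list of ppm intervals zeroed in every realised
#'   spectrum, or `NULL` (default; appropriate for synthetic libraries).
#'   Use [solventWindows()] for DMSO-d6/HDO masking of real data.
#' @param seed master seed; per-pair substreams are derived from it so
#'   realisation is order-independent
#' @return a list of class `augmentationConfig`
#' @export
augmentationConfig <- function(nPairs = 22000, ratioRange = c(0.2, 1.0),
                               componentsRange = c(2, 5), noiseSigma = 0.005,
                               positiveFraction = 0.5,
                               splitSizes = c(18000, 2000, 2000),
                               maskWindows = NULL, seed = 1) {
  if (ratioRange[1] <= 0 || ratioRange[1] > ratioRange[2])
    stop("ratioRange must satisfy 0 < low <= high")
  if (componentsRange[1] < 2) stop("componentsRange minimum must be >= 2")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (positiveFraction <= 0 || positiveFraction >= 1)
    stop("positiveFraction must be in (0, 1)")
  if (sum(splitSizes) != nPairs)
    stop("splitSizes must sum to nPairs (", sum(splitSizes), " != ", nPairs, ")")
  structure(list(nPairs = as.integer(nPairs), ratioRange = as.numeric(ratioRange),
                 componentsRange = as.integer(componentsRange),
                 noiseSigma = noiseSigma, positiveFraction = positiveFraction,
                 splitSizes = as.integer(splitSizes),
                 maskWindows = maskWindows, seed = as.integer(seed)),
            class = "augmentationConfig")
}

# deterministic per-pair substream seeds below 2^31
.substream <- function(master, i, salt = 0L) {
  as.integer((as.numeric(master) + 97 * as.numeric(i) + 1000003 * salt) %%
               2147483647)
}

#' Superpose spectra at given ratios with additive noise
#'
#' Pointwise `sum(ratio_k * intensity_k)` plus i.i.d. zero-mean Gaussian
#' noise of sd `noiseSigma`; exactly linear when `noiseSigma = 0`.
#' Deterministic given `seed`.
#'
#' @param components list of [NMRSpectrum-class] on a shared grid
#' @param ratios positive weights, one per component
#' @param noiseSigma noise sd
#' @param seed integer seed for the noise draw
#' @param name name of the resulting spectrum
#' @return an [NMRSpectrum-class] (not renormalized)
#' @export
superpose <- function(components, ratios, noiseSigma = 0, seed = 1,
                      name = "mixture") {
  if (length(components) != length(ratios))
    stop("components and ratios must have equal length")
  if (!length(components)) stop("at least one component is required")
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  grid <- components[[1]]@ppm
  for (s in components)
    if (length(s@ppm) != length(grid) || max(abs(s@ppm - grid)) > 1e-9)
      stop("all components must share one ppm grid")
  y <- numeric(length(grid))
  for (k in seq_along(components))
    y <- y + ratios[k] * components[[k]]@intensity
  if (noiseSigma > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    y <- y + rnorm(length(y), 0, noiseSigma)
  }
  NMRSpectrum(grid, y, name = name)
}

.maskIntensity <- function(y, grid, windows) {
  if (is.null(windows)) return(y)
  for (w in windows) y[grid >= min(w) & grid <= max(w)] <- 0
  y
}

# draw one pair recipe (composition + ratios) from a per-pair substream
.drawComposition <- function(nLib, targetIndex, positive, config, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k <- sample(config$componentsRange[1]:config$componentsRange[2], 1)
  others <- setdiff(seq_len(nLib), targetIndex)
  idx <- if (positive) c(targetIndex, sample(others, k - 1))
         else sample(others, k)
  data.frame(index = idx,
             ratio = runif(k, config$ratioRange[1], config$ratioRange[2]))
}

#' Build a single labelled spectral pair
#'
#' A positive pair mixes the target compound with `k - 1` other distinct
#' library entries; a negative pair mixes `k` distinct entries none of
#' which is the target (`k` drawn from `componentsRange`, ratios i.i.d.
#' uniform on `ratioRange`).  Noise is added to the mixture, the mixture
#' is re-max-normalized, and the composition is recorded.
#'
#' @param library an [NMRLibrary-class]
#' @param targetIndex library index of the "pure" side
#' @param positive logical label
#' @param config an [augmentationConfig()]
#' @param seed integer substream seed
#' @return list with elements `pure`, `mixture` ([NMRSpectrum-class]),
#'   `label` (0/1) and `composition` (data.frame index, ratio)
#' @export
makePair <- function(library, targetIndex, positive,
                     config = augmentationConfig(), seed = 1) {
  n <- length(library)
  if (targetIndex < 1 || targetIndex > n) stop("targetIndex out of range")
  if (n < config$componentsRange[2] + 1)
    stop("library too small: need at least componentsRange max + 1 = ",
         config$componentsRange[2] + 1, " entries")
  comp <- .drawComposition(n, targetIndex, positive, config, seed)
  mix <- superpose(library@entries[comp$index], comp$ratio,
                   noiseSigma = config$noiseSigma, seed = .substream(seed, 1))
  y <- .maskIntensity(mix@intensity, library@grid, config$maskWindows)
  mix <- normalizeMax(NMRSpectrum(library@grid, y, name = "augmented_mixture"))
  pure <- library@entries[[targetIndex]]
  pure <- NMRSpectrum(library@grid,
                      .maskIntensity(pure@intensity, library@grid,
                                     config$maskWindows),
                      name = pure@name, meta = pure@meta)
  list(pure = pure, mixture = mix, label = as.integer(positive),
       composition = comp)
}

#' Build an augmented spectral-pair set
#'
#' Generates exactly `nPairs` pair recipes with exactly
#' `round(positiveFraction * nPairs)` positives; target compounds are
#' cycled over the whole library (shuffled) so every entry appears as
#' the pure side.  Deterministic given `config$seed`; pairs are realised
#' lazily by [realizePairs()].
#'
#' @param library an [NMRLibrary-class]
#' @param config an [augmentationConfig()]
#' @return a [SpectralPairSet-class] (unsplit; see [splitPairSet()])
#' @export
buildPairSet <- function(library, config = augmentationConfig()) {
  n <- config$nPairs
  nLib <- length(library)
  if (nLib < config$componentsRange[2] + 1)
    stop("library too small: need at least componentsRange max + 1 = ",
         config$componentsRange[2] + 1, " entries")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.substream(config$seed, 0, 1L))
  nPos <- as.integer(round(config$positiveFraction * n))
  labels <- sample(rep(c(1L, 0L), c(nPos, n - nPos)))
  targets <- sample(rep(seq_len(nLib), length.out = n))
  .Random.seed_restore(old)

  comps <- vector("list", n)
  for (i in seq_len(n))
    comps[[i]] <- .drawComposition(nLib, targets[i], labels[i] == 1L, config,
                                   .substream(config$seed, i))
  new("SpectralPairSet", library = library, targets = targets,
      labels = labels, composition = comps,
      noiseSeeds = vapply(seq_len(n), function(i)
        .substream(.substream(config$seed, i), 1), integer(1)),
      partition = factor(rep(NA_character_, n),
                         levels = c("train", "val", "test")),
      config = unclass(config))
}

#' Randomly partition a pair set into train/val/test
#'
#' Uniformly random disjoint partition of the stated sizes,
#' deterministic given `seed`.
#'
#' @param pairset a [SpectralPairSet-class]
#' @param sizes (train, val, test) counts summing to `length(pairset)`
#' @param seed integer seed (defaults to a substream of the set's seed)
#' @return the pair set with its partition slot filled
#' @export
splitPairSet <- function(pairset, sizes = pairset@config$splitSizes,
                         seed = .substream(pairset@config$seed, 0, 2L)) {
  n <- length(pairset)
  if (sum(sizes) != n)
    stop("split sizes must sum to the number of pairs (",
         sum(sizes), " != ", n, ")")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tag <- sample(rep(c("train", "val", "test"), sizes))
  pairset@partition <- factor(tag, levels = c("train", "val", "test"))
  pairset
}

#' Realise pair spectra as matrices
#'
#' Materialises the selected pairs: the pure side is the (masked)
#' library entry, the mixture side is the ratio-weighted superposition
#' plus the pair's noise draw, masked and re-max-normalized.  Columns
#' are pairs, rows are grid points.
#'
#' @param pairset a [SpectralPairSet-class]
#' @param which indices of pairs to realise (default all), or a partition
#'   name (`"train"`, `"val"`, `"test"`)
#' @return list with `pure` and `mixture` matrices (grid x pairs),
#'   `labels`, and `indices` (the realised pair indices)
#' @export
realizePairs <- function(pairset, which = NULL) {
  idx <- if (is.null(which)) seq_len(length(pairset))
         else if (is.character(which)) {
           stopifnot(which %in% levels(pairset@partition))
           base::which(pairset@partition == which)
         } else as.integer(which)
  lib <- pairset@library
  grid <- lib@grid
  cfg <- pairset@config
  rawm <- intensities(lib)
  libm <- rawm
  if (!is.null(cfg$maskWindows))
    for (w in cfg$maskWindows) libm[grid >= min(w) & grid <= max(w), ] <- 0
  L <- length(grid)
  pure <- matrix(0, L, length(idx))
  mixt <- matrix(0, L, length(idx))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (j in seq_along(idx)) {
    i <- idx[j]
    comp <- pairset@composition[[i]]
    y <- as.vector(rawm[, comp$index, drop = FALSE] %*% comp$ratio)
    if (cfg$noiseSigma > 0) {
      set.seed(pairset@noiseSeeds[i])
      y <- y + rnorm(L, 0, cfg$noiseSigma)
    }
    y <- .maskIntensity(y, grid, cfg$maskWindows)
    m <- max(y)
    if (m <= 0) stop("degenerate mixture in pair ", i)
    mixt[, j] <- y / m
    pure[, j] <- libm[, pairset@targets[i]]
  }
  list(pure = pure, mixture = mixt,
       labels = pairset@labels[idx], indices = idx)
}
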