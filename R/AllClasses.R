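#' @title Core S4 classes
#' @name nmrmix-classes
#' @description S4 containers for spectra, spectral libraries, augmented
#'   spectral-pair sets, the trained two-branch network and screening
#'   results.
NULL

.uniformGridOK <- function(ppm, rtol = 1e-9) {
  if (length(ppm) < 2) return(FALSE)
  d <- diff(ppm)
  if (any(d == 0)) return(FALSE)
  if (any(sign(d) != sign(d[1]))) return(FALSE)
  step <- mean(d)
  all(abs(d - step) <= rtol * max(abs(step), 1e-300))
}

#' NMRSpectrum: a 1D NMR spectrum on a uniform ppm grid
#'
#' Holds a chemical-shift axis (ppm, uniformly spaced, stored in either
#' direction but written high-to-low by the package's own writers), the
#' matching intensity vector, a name and free-form metadata (e.g.
#' spectrometer frequency in MHz, source file).
#'
#' @slot ppm numeric, monotone uniform chemical-shift axis (ppm)
#' @slot intensity numeric, same length as `ppm`, finite
#' @slot name character(1) compound/sample identifier
#' @slot meta list of free-form annotations
#' @exportClass NMRSpectrum
setClass("NMRSpectrum",
  representation(ppm = "numeric", intensity = "numeric",
                 name = "character", meta = "list"),
  prototype(name = "", meta = list()))

setValidity("NMRSpectrum", function(object) {
  msg <- character()
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm axis and intensities differ in length")
  if (length(object@ppm) < 2)
    msg <- c(msg, "a spectrum needs at least 2 points")
  else if (!.uniformGridOK(object@ppm))
    msg <- c(msg, "ppm axis must be monotone with uniform spacing (rel. tol 1e-9)")
  if (anyNA(object@intensity) || any(!is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (length(object@name) != 1L)
    msg <- c(msg, "name must be a single string")
  if (length(msg)) msg else TRUE
})

#' NMRLibrary: an ordered collection of pure-compound spectra
#'
#' All entries share one ppm grid and have unique names; this is the
#' spectral database screened against mixture spectra.
#'
#' @slot grid numeric shared ppm axis
#' @slot entries list of [NMRSpectrum-class] objects on `grid`
#' @exportClass NMRLibrary
setClass("NMRLibrary",
  representation(grid = "numeric", entries = "list"))

setValidity("NMRLibrary", function(object) {
  msg <- character()
  if (length(object@entries)) {
    ok <- vapply(object@entries, function(s)
      is(s, "NMRSpectrum") && length(s@ppm) == length(object@grid) &&
        max(abs(s@ppm - object@grid)) <= 1e-9, logical(1))
    if (!all(ok))
      msg <- c(msg, "all entries must be NMRSpectrum objects on the shared grid")
    nm <- vapply(object@entries, function(s) s@name, character(1))
    if (anyDuplicated(nm))
      msg <- c(msg, "entry names must be unique")
  }
  if (length(object@grid) >= 2 && !.uniformGridOK(object@grid))
    msg <- c(msg, "grid must be monotone with uniform spacing")
  if (length(msg)) msg else TRUE
})

#' SpectralPairSet: an augmented set of labelled spectral pairs
#'
#' Stores the *recipe* for every pair (target library entry, mixture
#' composition with ratios, noise substream seed, label, partition tag)
#' together with the source library; pair spectra are realised on demand
#' by [realizePairs()], bit-reproducibly.  This keeps paper-scale sets
#' (22,000 pairs on a 16,384-point grid) lightweight.
#'
#' @slot library the source [NMRLibrary-class]
#' @slot targets integer, library index of the "pure" side of each pair
#' @slot labels integer 0/1, 1 iff the target is in the composition
#' @slot composition list of data.frames (index, ratio) actually mixed
#' @slot noiseSeeds integer, per-pair noise substream seed
#' @slot partition factor with levels train/val/test (or NA if unsplit)
#' @slot config the augmentation configuration list
#' @exportClass SpectralPairSet
setClass("SpectralPairSet",
  representation(library = "NMRLibrary", targets = "integer",
                 labels = "integer", composition = "list",
                 noiseSeeds = "integer", partition = "factor",
                 config = "list"))

setValidity("SpectralPairSet", function(object) {
  n <- length(object@targets)
  msg <- character()
  if (length(object@labels) != n || length(object@composition) != n ||
      length(object@noiseSeeds) != n || length(object@partition) != n)
    msg <- c(msg, "per-pair slots must have equal length")
  if (n && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (n) {
    member <- vapply(seq_len(n), function(i)
      object@targets[i] %in% object@composition[[i]]$index, logical(1))
    if (!all((object@labels == 1L) == member))
      msg <- c(msg, "label must equal membership of the target in the composition")
  }
  if (length(msg)) msg else TRUE
})

#' PairCNN: the two-branch convolutional spectral-pair classifier
#'
#' Two subnetworks with the same architecture but independently trained
#' weights embed the pure-compound and mixture spectra; the concatenated
#' features pass through a dense head with a sigmoid output giving the
#' probability that the mixture contains the compound.
#'
#' @slot weights named list of weight matrices (see [buildPairCNN()])
#' @slot config model configuration list ([modelConfig()])
#' @slot inputLength integer, number of grid points each branch expects
#' @slot trained logical
#' @slot history data.frame of per-epoch loss/accuracy (train and validation)
#' @exportClass PairCNN
setClass("PairCNN",
  representation(weights = "list", config = "list",
                 inputLength = "integer", trained = "logical",
                 history = "data.frame"))

#' ScreenResult: outcome of screening a library against a mixture
#'
#' @slot table data.frame with one row per library entry: index, name,
#'   probability, candidate flag (probability strictly above threshold)
#' @slot threshold numeric decision threshold
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(table = "data.frame", threshold = "numeric"))
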