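# Accessor and show methods for the S4 classes.

#' Create an NMRSpectrum
#'
#' @param ppm uniform monotone chemical-shift axis in ppm
#' @param intensity intensity values, same length as `ppm`
#' @param name identifier
#' @param meta list of annotations
#' @return an [NMRSpectrum-class]
#' @examples
#' s <- NMRSpectrum(seq(10, 0, length.out = 64), rep(1, 64), "flat")
#' ppmAxis(s)[1:3]
#' @export
NMRSpectrum <- function(ppm, intensity, name = "", meta = list()) {
  new("NMRSpectrum", ppm = as.numeric(ppm), intensity = as.numeric(intensity),
      name = as.character(name), meta = meta)
}

#' Create an NMRLibrary from spectra sharing one grid
#'
#' @param entries list of [NMRSpectrum-class] objects on a common grid
#' @return an [NMRLibrary-class]
#' @export
NMRLibrary <- function(entries) {
  if (!length(entries)) return(new("NMRLibrary", grid = numeric(), entries = list()))
  new("NMRLibrary", grid = entries[[1]]@ppm, entries = entries)
}

#' @describeIn NMRSpectrum ppm axis of a spectrum
#' @param x object
#' @export
setMethod("ppmAxis", "NMRSpectrum", function(x) x@ppm)
#' @export
setMethod("ppmAxis", "NMRLibrary", function(x) x@grid)
#' @export
setMethod("intensities", "NMRSpectrum", function(x) x@intensity)

#' @describeIn NMRLibrary intensity matrix, one column per entry
#' @param x object
#' @export
setMethod("intensities", "NMRLibrary", function(x) {
  m <- vapply(x@entries, function(s) s@intensity,
              numeric(length(x@grid)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(x@grid))
  colnames(m) <- names(x)
  m
})

#' @export
setMethod("spectrumName", "NMRSpectrum", function(x) x@name)
#' @export
setMethod("spectrumMeta", "NMRSpectrum", function(x) x@meta)

#' @export
setMethod("length", "NMRSpectrum", function(x) length(x@ppm))
#' @export
setMethod("length", "NMRLibrary", function(x) length(x@entries))
#' @export
setMethod("names", "NMRLibrary", function(x)
  vapply(x@entries, function(s) s@name, character(1)))

#' @export
setMethod("[[", "NMRLibrary", function(x, i) {
  if (is.character(i)) {
    j <- match(i, names(x))
    if (is.na(j)) stop("no library entry named '", i, "'")
    i <- j
  }
  x@entries[[i]]
})

setMethod("show", "NMRSpectrum", function(object) {
  cat(sprintf("NMRSpectrum '%s': %d points, %.3f..%.3f ppm, max %.4g\n",
              object@name, length(object@ppm),
              min(object@ppm), max(object@ppm), max(object@intensity)))
})

setMethod("show", "NMRLibrary", function(object) {
  cat(sprintf("NMRLibrary: %d entries on a %d-point grid (%.2f..%.2f ppm)\n",
              length(object@entries), length(object@grid),
              min(object@grid), max(object@grid)))
  if (length(object@entries))
    cat("  entries:", paste(utils::head(names(object), 6), collapse = ", "),
        if (length(object@entries) > 6) "..." else "", "\n")
})

#' @export
setMethod("length", "SpectralPairSet", function(x) length(x@targets))
#' @export
setMethod("pairLabels", "SpectralPairSet", function(x) x@labels)
#' @export
setMethod("pairTargets", "SpectralPairSet", function(x) x@targets)
#' @export
setMethod("pairComposition", "SpectralPairSet", function(x) x@composition)
#' @export
setMethod("pairPartition", "SpectralPairSet", function(x) x@partition)

setMethod("show", "SpectralPairSet", function(object) {
  n <- length(object@targets)
  cat(sprintf("SpectralPairSet: %d pairs (%d positive) over %d library entries\n",
              n, sum(object@labels == 1L), length(object@library)))
  if (!all(is.na(object@partition)))
    print(table(object@partition))
})

#' @export
setMethod("trainingHistory", "PairCNN", function(x) x@history)
#' @export
setMethod("modelWeights", "PairCNN", function(x) x@weights)

setMethod("show", "PairCNN", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("PairCNN: two branches of %d conv(%d kernels, size %d)",
                     " + maxpool(%d) blocks,\n  dense(%d) head, input length %d, %s\n"),
              cfg$nConvLayers, cfg$nKernels, cfg$kernelSize, cfg$poolSize,
              cfg$denseUnits, object@inputLength,
              if (object@trained) "trained" else "untrained"))
  if (object@trained && nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  final epoch: loss %.4f acc %.4f val_loss %.4f val_acc %.4f\n",
                last$loss, last$accuracy, last$val_loss, last$val_accuracy))
  }
})

#' @export
setMethod("screenTable", "ScreenResult", function(x) x@table)

#' @describeIn ScreenResult candidate rows (probability strictly above the
#'   threshold), ranked by descending probability, ties broken by index
#' @param x object
#' @export
setMethod("candidates", "ScreenResult", function(x) {
  tab <- x@table[x@table$candidate, , drop = FALSE]
  tab[order(-tab$probability, tab$index), , drop = FALSE]
})

setMethod("show", "ScreenResult", function(object) {
  cand <- candidates(object)
  cat(sprintf("ScreenResult: %d library entries, threshold %.2f, %d candidates\n",
              nrow(object@table), object@threshold, nrow(cand)))
  if (nrow(cand)) {
    for (i in seq_len(nrow(cand)))
      cat(sprintf("  %2d. %-24s p = %.4f\n", i, cand$name[i], cand$probability[i]))
  }
})
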