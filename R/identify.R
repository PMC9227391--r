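# Database screening: pair the mixture spectrum with every library
# entry, predict inclusion probabilities, threshold and rank.

#' Identify candidate components of a mixture
#'
#' Forms one spectral pair per library entry (entry, mixture), predicts
#' all inclusion probabilities with the trained model and reports the
#' entries whose probability is strictly greater than the threshold,
#' ranked by descending probability (ties broken by library index).
#' The mixture is preprocessed exactly like training data: resampled to
#' the library grid if needed, solvent-masked with the model's training
#' mask windows and max-normalized.
#'
#' @param model a trained [PairCNN-class]
#' @param library an [NMRLibrary-class] (non-empty, grid length matching
#'   the model input)
#' @param mixture an [NMRSpectrum-class]
#' @param threshold decision threshold in [0, 1] (default 0.5)
#' @param maskWindows ppm windows zeroed in both mixture and library
#'   spectra before prediction (default none; use [solventWindows()]
#'   for real DMSO-d6 data); must match what training used
#' @return a [ScreenResult-class]
#' @examples
#' \dontrun{
#' res <- identifyCompounds(model, lib, mix)
#' candidates(res)
#' }
#' @export
identifyCompounds <- function(model, library, mixture, threshold = 0.5,
                              maskWindows = NULL) {
  stopifnot(is(model, "PairCNN"), is(library, "NMRLibrary"),
            is(mixture, "NMRSpectrum"))
  if (!length(library)) stop("the spectral library is empty")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (length(library@grid) != model@inputLength)
    stop("library grid has ", length(library@grid),
         " points but the model expects ", model@inputLength)
  if (length(mixture@ppm) != length(library@grid) ||
      max(abs(mixture@ppm - library@grid)) > 1e-9)
    mixture <- resampleSpectrum(mixture, library@grid)
  grid <- library@grid
  ym <- .maskIntensity(mixture@intensity, grid, maskWindows)
  mmax <- max(ym)
  if (mmax <= 0) stop("mixture spectrum has no positive intensity")
  ym <- ym / mmax
  libm <- intensities(library)
  if (!is.null(maskWindows))
    for (w in maskWindows) libm[grid >= min(w) & grid <= max(w), ] <- 0
  n <- length(library)
  probs <- predictPairs(model, libm,
                        matrix(ym, length(grid), n))
  tab <- data.frame(index = seq_len(n), name = names(library),
                    probability = probs,
                    candidate = probs > threshold,
                    stringsAsFactors = FALSE)
  new("ScreenResult", table = tab, threshold = threshold)
}

#' Write a screening result to CSV (+ JSON summary)
#'
#' @param result a [ScreenResult-class]
#' @param path CSV output file; a `.json` summary is written alongside
#' @return `path`, invisibly
#' @export
writeScreenResult <- function(result, path) {
  utils::write.csv(screenTable(result), path, row.names = FALSE)
  cand <- candidates(result)
  jsonlite::write_json(
    list(threshold = result@threshold,
         nCandidates = nrow(cand),
         candidates = cand$name,
         probabilities = cand$probability),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
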