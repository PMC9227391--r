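# R-facing surface of the two-branch convolutional spectral-pair
# classifier.  The numerical core (im2col+GEMM convolutions, max-pooling,
# dense head, Adam, backprop) lives in src/paircnn.cpp.

#' Model configuration
#'
#' Defaults are the optimised architecture: 6 convolutional layers of 32
#' kernels of size 5 (ReLU, "same" padding, stride 1), each followed by
#' a non-overlapping max pool of size/stride 2; the concatenated,
#' flattened branch features feed dense(100, ReLU) -> dropout(0.2) ->
#' dense(1, sigmoid).  Binary cross-entropy loss, Adam optimiser with
#' learning rate 1e-4, 100 epochs, batch size 32.
#'
#' @param nConvLayers conv+pool blocks per branch
#' @param nKernels kernels per conv layer
#' @param kernelSize kernel length
#' @param poolSize max-pool window = stride (non-overlapping)
#' @param denseUnits hidden units of the first dense layer
#' @param dropoutRate dropout after the first dense layer, in [0, 1)
#' @param learningRate Adam learning rate
#' @param epochs training epochs (fixed; no early stopping)
#' @param batchSize minibatch size
#' @param seed controls weight initialisation, dropout and shuffling
#' @return a list of class `modelConfig`
#' @export
modelConfig <- function(nConvLayers = 6, nKernels = 32, kernelSize = 5,
                        poolSize = 2, denseUnits = 100, dropoutRate = 0.2,
                        learningRate = 1e-4, epochs = 100, batchSize = 32,
                        seed = 1) {
  counts <- c(nConvLayers, nKernels, kernelSize, poolSize, denseUnits,
              epochs, batchSize)
  if (any(counts < 1)) stop("all architecture/training counts must be >= 1")
  if (dropoutRate < 0 || dropoutRate >= 1) stop("dropoutRate must be in [0, 1)")
  if (learningRate <= 0) stop("learningRate must be positive")
  structure(list(nConvLayers = as.integer(nConvLayers),
                 nKernels = as.integer(nKernels),
                 kernelSize = as.integer(kernelSize),
                 poolSize = as.integer(poolSize),
                 denseUnits = as.integer(denseUnits),
                 dropoutRate = dropoutRate, learningRate = learningRate,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 seed = as.integer(seed)),
            class = "modelConfig")
}

#' 1D convolution (cross-correlation) with optional ReLU
#'
#' The same kernel the model uses, exposed directly: per output channel
#' the input is cross-correlated with the kernel (no flipping), the bias
#' added and ReLU applied.  `"same"` padding zero-pads so the output
#' length equals the input length; `"valid"` yields length
#' `L - kernelSize + 1`.
#'
#' @param x numeric vector (single channel) or channels-by-length matrix
#' @param kernels numeric vector (one kernel, one channel), a
#'   kernels-by-size matrix (single channel) or an array
#'   (nOut, channels, size)
#' @param bias per-output-channel bias (recycled)
#' @param padding `"same"` or `"valid"`
#' @param activation `"relu"` or `"linear"`
#' @return vector (single output channel) or nOut-by-Lout matrix
#' @examples
#' conv1d(c(1, 2, 3), c(1, 1), padding = "valid")  # 3 5
#' @export
conv1d <- function(x, kernels, bias = 0, padding = c("same", "valid"),
                   activation = c("relu", "linear")) {
  padding <- match.arg(padding)
  activation <- match.arg(activation)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.vector(kernels)) kernels <- array(kernels, c(1, 1, length(kernels)))
  else if (is.matrix(kernels))
    kernels <- array(kernels, c(nrow(kernels), 1, ncol(kernels)))
  nOut <- dim(kernels)[1]
  ks <- dim(kernels)[3]
  if (padding == "valid" && ncol(x) < ks)
    stop("input length (", ncol(x), ") is shorter than the kernel (", ks, ")")
  bias <- rep_len(as.numeric(bias), nOut)
  out <- cpp_conv1d(x, kernels, bias, padding == "same",
                    activation == "relu")
  if (nOut == 1) drop(out) else out
}

#' 1D max pooling
#'
#' Maximum over non-overlapping windows (when `stride == size`); any
#' trailing remainder shorter than the window is dropped.
#'
#' @param x numeric vector or channels-by-length matrix
#' @param size window length
#' @param stride window step (defaults to `size`)
#' @return pooled vector/matrix
#' @examples
#' maxpool1d(c(1, 3, 2, 5), 2)  # 3 5
#' @export
maxpool1d <- function(x, size, stride = size) {
  if (size < 1 || stride < 1) stop("size and stride must be >= 1")
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) < size) stop("input shorter than the pooling window")
  out <- cpp_maxpool1d(x, as.integer(size), as.integer(stride))
  if (vec) drop(out) else out
}

# minimal admissible input length for a given depth (each pool needs at
# least `poolSize` points)
.minInputLength <- function(config) config$poolSize^config$nConvLayers

#' Build an untrained two-branch pair classifier
#'
#' Initialises two subnetworks with the same architecture but
#' independent Glorot-uniform weights (they are never tied), plus the
#' dense head.  Deterministic given `config$seed`.
#'
#' @param config a [modelConfig()]
#' @param inputLength number of grid points of each input spectrum; must
#'   survive `nConvLayers` poolings
#' @return an untrained [PairCNN-class]
#' @export
buildPairCNN <- function(config = modelConfig(), inputLength) {
  stopifnot(inherits(config, "modelConfig"))
  inputLength <- as.integer(inputLength)
  if (inputLength < .minInputLength(config))
    stop("inputLength ", inputLength, " too short for ", config$nConvLayers,
         " pooling layers; minimal admissible length is ",
         .minInputLength(config))
  if (inputLength %% .minInputLength(config) != 0)
    stop("inputLength must be a multiple of poolSize^nConvLayers (",
         .minInputLength(config), ") so every pooling stage divides evenly")
  w <- cpp_init_weights(unclass(config), inputLength, config$seed)
  new("PairCNN", weights = w, config = unclass(config),
      inputLength = inputLength, trained = FALSE,
      history = data.frame())
}

#' Number of trainable parameters
#'
#' @param model a [PairCNN-class]
#' @return integer parameter count
#' @export
countParameters <- function(model) {
  sum(vapply(model@weights, length, numeric(1)))
}

.asPairMatrices <- function(x, inputLength, which = NULL) {
  if (is(x, "SpectralPairSet")) return(realizePairs(x, which))
  stopifnot(is.list(x), all(c("pure", "mixture", "labels") %in% names(x)))
  x
}

#' Train the pair classifier
#'
#' Runs exactly `config$epochs` epochs of minibatch Adam on binary
#' cross-entropy and records per-epoch training and validation loss and
#' accuracy.  Reproducible given the model seed (statistically across
#' BLAS builds, bit-exactly within one).
#'
#' @param model an untrained (or previously trained) [PairCNN-class]
#' @param pairs a [SpectralPairSet-class] (its `train`/`val` partitions
#'   are used when present, otherwise all pairs train) or a list with
#'   `pure`, `mixture` (grid x pairs matrices) and `labels`
#' @param validation optional validation pairs in the same forms
#' @param bestEpoch keep the weights of the epoch with the highest
#'   validation accuracy instead of the final ones (off by default;
#'   needs validation data).  Mirrors selecting the best model of a
#'   scan by validation accuracy.
#' @param verbose print per-epoch progress
#' @return the trained [PairCNN-class] with filled history
#' @export
trainPairCNN <- function(model, pairs, validation = NULL,
                         bestEpoch = FALSE, verbose = FALSE) {
  stopifnot(is(model, "PairCNN"))
  if (is(pairs, "SpectralPairSet") && !all(is.na(pairs@partition))) {
    tr <- realizePairs(pairs, "train")
    if (is.null(validation)) validation <- realizePairs(pairs, "val")
  } else tr <- .asPairMatrices(pairs)
  va <- if (is.null(validation))
    list(pure = matrix(0, nrow(tr$pure), 0),
         mixture = matrix(0, nrow(tr$pure), 0), labels = integer())
  else .asPairMatrices(validation)
  if (nrow(tr$pure) != model@inputLength)
    stop("pair length ", nrow(tr$pure), " does not match the model input length ",
         model@inputLength)
  if (length(unique(tr$labels)) < 2)
    stop("training data must contain both classes")
  if (bestEpoch && !ncol(va$pure))
    stop("bestEpoch selection needs validation data")
  fit <- cpp_train(model@weights, model@config,
                   tr$pure, tr$mixture, as.numeric(tr$labels),
                   va$pure, va$mixture, as.numeric(va$labels),
                   model@config$seed, verbose, bestEpoch)
  h <- as.data.frame(fit$history)
  names(h) <- c("loss", "accuracy", "val_loss", "val_accuracy")
  h$epoch <- seq_len(nrow(h))
  if (!is.na(fit$bestEpoch)) attr(h, "bestEpoch") <- fit$bestEpoch
  model@weights <- fit$weights
  model@trained <- TRUE
  model@history <- h
  model
}

#' Predict inclusion probabilities for spectral pairs
#'
#' @param model a [PairCNN-class]
#' @param pure,mixture grid-by-n matrices (or single spectra /
#'   [NMRSpectrum-class] objects) on the model's input grid length
#' @return numeric vector of probabilities in [0, 1], one per pair
#' @export
predictPairs <- function(model, pure, mixture) {
  asMat <- function(z) {
    if (is(z, "NMRSpectrum")) z <- intensities(z)
    if (is.vector(z)) z <- matrix(z, ncol = 1)
    z
  }
  pure <- asMat(pure); mixture <- asMat(mixture)
  if (nrow(pure) != model@inputLength || nrow(mixture) != model@inputLength)
    stop("spectra have ", nrow(pure), " points but the model expects ",
         model@inputLength)
  if (ncol(pure) != ncol(mixture))
    stop("pure and mixture must pair up column by column")
  as.numeric(cpp_predict(model@weights, model@config, pure, mixture))
}

#' @rdname predictPairs
#' @export
predictPair <- function(model, pure, mixture) {
  predictPairs(model, pure, mixture)[1]
}

#' Save / load a trained model
#'
#' The checkpoint is a directory holding the weights (RDS) and a JSON
#' sidecar with the configuration and input length.
#'
#' @param model a [PairCNN-class]
#' @param path checkpoint directory
#' @return `path` (save) or a [PairCNN-class] (load)
#' @export
saveModel <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model@weights, file.path(path, "weights.rds"))
  jsonlite::write_json(
    list(config = model@config, inputLength = model@inputLength,
         trained = model@trained),
    file.path(path, "model.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(model@history, file.path(path, "history.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  side <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
  hist <- file.path(path, "history.csv")
  new("PairCNN", weights = readRDS(file.path(path, "weights.rds")),
      config = side$config, inputLength = as.integer(side$inputLength),
      trained = isTRUE(side$trained),
      history = if (file.exists(hist)) utils::read.csv(hist) else data.frame())
}
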