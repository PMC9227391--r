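# The two-branch convolutional classifier: primitives against
# brute-force oracles, architecture contracts, training behaviour.

# plain double-loop cross-correlation oracle (no flipping), double
# precision
convOracle <- function(x, kernels, bias, same = TRUE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  nOut <- dim(kernels)[1]; C <- dim(kernels)[2]; ks <- dim(kernels)[3]
  L <- ncol(x)
  pad <- if (same) (ks - 1) %/% 2 else 0
  Lo <- if (same) L else L - ks + 1
  out <- matrix(0, nOut, Lo)
  for (o in seq_len(nOut))
    for (p in seq_len(Lo)) {
      acc <- bias[o]
      for (c in seq_len(C))
        for (t in seq_len(ks)) {
          j <- p + t - 1 - pad
          if (j >= 1 && j <= L) acc <- acc + kernels[o, c, t] * x[c, j]
        }
      out[o, p] <- max(acc, 0)
    }
  out
}

poolOracle <- function(x, size, stride) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  nw <- (ncol(x) - size) %/% stride + 1
  out <- matrix(0, nrow(x), nw)
  for (j in seq_len(nw))
    out[, j] <- apply(x[, ((j - 1) * stride + 1):((j - 1) * stride + size),
                        drop = FALSE], 1, max)
  out
}

test_that("conv1d reproduces hand examples and the ReLU clamp", {
  expect_equal(conv1d(c(1, 2, 3), c(1, 1), padding = "valid"), c(3, 5))
  # identity kernel passes non-negative input through
  x <- c(0, 1, 2, 0.5)
  expect_equal(conv1d(x, 1, padding = "valid"), x)
  # ReLU clamps negatives
  expect_equal(conv1d(c(-1, -2), 1, padding = "valid"), c(0, 0))
  expect_error(conv1d(c(1, 2), c(1, 1, 1), padding = "valid"), "shorter")
})

test_that("conv1d agrees with a brute-force cross-correlation oracle", {
  set.seed(101)
  for (rep in 1:20) {
    C <- sample(1:3, 1); L <- sample(5:20, 1)
    nOut <- sample(1:4, 1); ks <- sample(c(1, 3, 5), 1)
    if (L < ks) next
    x <- matrix(rnorm(C * L), C, L)
    kern <- array(rnorm(nOut * C * ks), c(nOut, C, ks))
    bias <- rnorm(nOut)
    for (same in c(TRUE, FALSE)) {
      got <- conv1d(x, kern, bias, padding = if (same) "same" else "valid")
      if (is.vector(got)) got <- matrix(got, nrow = 1)
      expect_equal(got, convOracle(x, kern, bias, same), tolerance = 1e-5)
    }
  }
})

test_that("maxpool1d matches the windowed-max oracle and drops remainders", {
  expect_equal(maxpool1d(c(1, 3, 2, 5), 2), c(3, 5))
  expect_equal(maxpool1d(rep(7, 6), 2), rep(7, 3))
  expect_length(maxpool1d(1:5, 2), 2)       # trailing remainder dropped
  set.seed(7)
  for (rep in 1:10) {
    C <- sample(1:3, 1); L <- sample(4:17, 1); size <- sample(2:3, 1)
    x <- matrix(rnorm(C * L), C, L)
    expect_equal(maxpool1d(x, size), poolOracle(x, size, size),
                 tolerance = 1e-6)
  }
  expect_error(maxpool1d(1:4, 0), ">= 1")
})

test_that("the built architecture has the stated shape and parameter count", {
  cfg <- modelConfig()
  m <- buildPairCNN(cfg, 4096)
  nm <- names(modelWeights(m))
  # 6 conv layers per branch, weights + biases, two branches, 2-dense head
  expect_equal(sum(grepl("^branch1_conv\\d+_W$", nm)), 6)
  expect_equal(sum(grepl("^branch2_conv\\d+_W$", nm)), 6)
  expect_length(nm, 2 * 6 * 2 + 4)

  # closed-form parameter count computed independently from shapes
  convPars <- function(cin, cout, ks) cout * cin * ks + cout
  perBranch <- convPars(1, 32, 5) + 5 * convPars(32, 32, 5)
  flat <- 2 * 32 * (4096 / 2^6)
  expected <- 2 * perBranch + (flat * 100 + 100) + (100 + 1)
  expect_equal(countParameters(m), expected)

  # too-short input reports the minimal admissible length
  expect_error(buildPairCNN(cfg, 32), "minimal admissible length is 64")
})

test_that("forward passes give probabilities, deterministically, and the
           branches are not weight-tied", {
  m <- buildPairCNN(modelConfig(seed = 3), 256)
  set.seed(1)
  pure <- matrix(abs(rnorm(256 * 5)), 256, 5)
  mixt <- matrix(abs(rnorm(256 * 5)), 256, 5)
  p <- predictPairs(m, pure, mixt)
  expect_true(all(p > 0 & p < 1))
  expect_identical(predictPairs(m, pure, mixt), p)
  # swapping the branch inputs changes the output: branches are untied
  expect_gt(max(abs(predictPairs(m, mixt, pure) - p)), 0)
  w <- modelWeights(m)
  expect_gt(max(abs(w$branch1_conv1_W - w$branch2_conv1_W)), 0)
})

test_that("training separates a separable toy world and logs full history", {
  fix <- toyTrainedModel()
  model <- fix$model
  h <- trainingHistory(model)
  expect_equal(nrow(h), 30)
  expect_true(all(c("loss", "accuracy", "val_loss", "val_accuracy") %in%
                    names(h)))
  expect_false(anyNA(h$val_loss))
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_gte(h$accuracy[nrow(h)], 0.95)
  # the two trained subnetworks have diverged from each other
  w <- modelWeights(model)
  expect_gt(max(abs(w$branch1_conv3_W - w$branch2_conv3_W)), 0)
})

test_that("prediction varies smoothly under small ppm shifts of the mixture", {
  fix <- toyTrainedModel()
  pair <- makePair(fix$library, 4, TRUE, toyAugConfig(), seed = 77)
  offs <- shiftOffsetGrid(0.02, 0.005)
  sc <- invarianceScan(fix$model, pair$pure, pair$mixture, offs)
  expect_lt(max(abs(diff(sc$probabilities))), 0.5)
})

test_that("degenerate training inputs are rejected", {
  lib <- toyLibrary()
  ps <- buildPairSet(lib, toyAugConfig(nPairs = 20))
  dat <- realizePairs(ps)
  onlyPos <- which(dat$labels == 1)
  m <- buildPairCNN(modelConfig(epochs = 1), 512)
  expect_error(
    trainPairCNN(m, list(pure = dat$pure[, onlyPos],
                         mixture = dat$mixture[, onlyPos],
                         labels = dat$labels[onlyPos])),
    "both classes")
  expect_error(trainPairCNN(m, list(pure = dat$pure[1:100, ],
                                    mixture = dat$mixture[1:100, ],
                                    labels = dat$labels)),
               "input length")
})

test_that("model checkpoints round-trip through save/load", {
  fix <- toyTrainedModel()
  dir <- withr::local_tempdir()
  saveModel(fix$model, dir)
  back <- loadModel(dir)
  dat <- realizePairs(fix$pairs, "test")
  expect_equal(predictPairs(back, dat$pure, dat$mixture),
               predictPairs(fix$model, dat$pure, dat$mixture))
})
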