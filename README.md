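# nmrmix

Identifies the components of a small-molecule mixture from its 1D ¹H NMR
spectrum by screening a library of pure-compound spectra with a
two-branch (pseudo-Siamese) convolutional network.  Intended for
spectroscopists and metabolomics/flavor analysts who have a panel of
standards measured once and want to ask, for any new mixture spectrum,
"which of my standards are in here?" — robustly against peak overlap and
small chemical-shift variations, without peak picking or alignment.

## Method

Every query is a *spectral pair* (Dᵢ, x): the library spectrum of
compound i and the mixture spectrum, both on one uniform ppm grid,
max-normalized.  A network with two convolutional branches — same
architecture, independently trained weights, because pure and mixture
spectra are drawn from different distributions — embeds the two spectra;
the concatenated features pass through a dense head ending in a sigmoid
that outputs P(i ∈ x).  Screening a library of N standards forms the N
pairs (D₁, x) … (D_N, x) and reports entries with probability above a
threshold (default 0.5), ranked.

Each branch: 6 × [conv1d(32 kernels, size 5, ReLU) → max-pool(2)];
head: dense(100, ReLU) → dropout(0.2) → dense(1, sigmoid); binary
cross-entropy, Adam, learning rate 1e-4.  Training pairs are
synthesised from the library itself by superposition — NMR signals are
additive — of 2–5 compounds at ratios uniform on 0.2–1.0 with additive
Gaussian noise (positive pairs contain the target, negative pairs do
not), 22,000 pairs split 18,000/2,000/2,000 at the default settings.
Performance is reported as ACC = (TP+TN)/n, TPR = TP/(TP+FN),
FPR = FP/(TN+FP), and a translation-invariance harness measures the
widest window of artificial chemical-shift offsets of the mixture over
which a true component is still recognised.

The convolution/pooling/backprop/Adam core is implemented in the
package (RcppArmadillo, single precision, im2col + BLAS GEMM); no
external deep-learning runtime is required.

## Worked example

Fully synthetic, seconds to run (a deliberately easy toy library):

```r
library(nmrmix)

grid <- seq(11, -1, length.out = 512)
lib <- NMRLibrary(lapply(1:8, function(i)
  normalizeMax(NMRSpectrum(grid,
    lorentzianLine(0.5 + i, gamma = 0.05, amplitude = 1, grid),
    name = sprintf("toy_%02d", i)))))

cfg <- augmentationConfig(nPairs = 240, componentsRange = c(2, 3),
                          splitSizes = c(180, 30, 30), seed = 11)
pairs <- splitPairSet(buildPairSet(lib, cfg))
model <- trainPairCNN(buildPairCNN(modelConfig(learningRate = 1e-3,
                                               epochs = 30, seed = 7), 512),
                      pairs)

mix <- normalizeMax(superpose(list(lib[[2]], lib[[5]]), c(0.8, 0.6),
                              noiseSigma = 0.005, seed = 404))
identifyCompounds(model, lib, mix)
#> ScreenResult: 8 library entries, threshold 0.50, 2 candidates
#>    1. toy_05                   p = 0.9906
#>    2. toy_02                   p = 0.9904
```

The two compounds actually mixed — numbers 2 and 5 — are the two
candidates above the 0.5 threshold; the remaining six entries score low
probabilities.  `evaluatePairSet(model, pairs, "test")` returns the
confusion counts and ACC/TPR/FPR of the held-out pairs, and
`invarianceScan(model, pure, mixture)` returns one inclusion probability
per chemical-shift offset together with the tolerated window.

Real data enter through `readSpectrum()` (Bruker processed-1D
directories, JCAMP-DX, two-column text) and `loadLibrary()` /
`writeLibrary()`; `inst/cli/nmrmix` wraps the staged pipeline
(simulate → augment → train → evaluate → identify → scan) for shell use.

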