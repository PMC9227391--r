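# Synthetic pure-compound 1H NMR spectra: random first-order multiplets
# (singlet/doublet/triplet/quartet) with Lorentzian lines, emulating
# small-molecule standards on a 400 MHz instrument.

#' Default ppm grid
#'
#' 16,384 points spanning 11 to -1 ppm (high-to-low, NMR display
#' convention), covering the usual 1H window in DMSO-d6/TMS work.
#'
#' @param n number of points
#' @param from,to ppm limits (first and last grid value)
#' @return numeric ppm axis
#' @export
defaultGrid <- function(n = 16384, from = 11, to = -1) {
  seq(from, to, length.out = n)
}

#' Configuration for the synthetic-library simulator
#'
#' Defaults emulate a panel of 24 small-molecule standards measured at
#' 400 MHz: 2-8 first-order multiplets per compound with centers on
#' 0.5-9.5 ppm, scalar couplings of 2-12 Hz and a Lorentzian half-width
#' at half-maximum of 0.0015 ppm (~0.6 Hz at 400 MHz).  On coarse grids
#' choose `gamma` of at least about twice the grid spacing so the
#' lineshape is sampled.
#'
#' @param nCompounds number of library entries
#' @param multipletsPerCompound integer range (min, max)
#' @param ppmRange range multiplet centers are drawn from
#' @param gamma Lorentzian HWHM in ppm
#' @param jRange scalar coupling range in Hz
#' @param spectrometerFreq spectrometer frequency in MHz
#' @param grid ppm axis the spectra are evaluated on
#' @param seed integer seed; the library is a pure function of the config
#' @return a list of class `simulatorConfig`
#' @export
simulatorConfig <- function(nCompounds = 24, multipletsPerCompound = c(2, 8),
                            ppmRange = c(0.5, 9.5), gamma = 0.0015,
                            jRange = c(2, 12), spectrometerFreq = 400,
                            grid = defaultGrid(), seed = 1) {
  if (nCompounds < 1) stop("nCompounds must be at least 1")
  if (gamma <= 0) stop("gamma must be positive")
  if (any(jRange < 0)) stop("jRange must be non-negative")
  if (spectrometerFreq <= 0) stop("spectrometerFreq must be positive")
  if (min(ppmRange) < min(grid) || max(ppmRange) > max(grid))
    stop("ppmRange must lie within the grid")
  structure(list(nCompounds = as.integer(nCompounds),
                 multipletsPerCompound = as.integer(multipletsPerCompound),
                 ppmRange = as.numeric(ppmRange), gamma = gamma,
                 jRange = as.numeric(jRange),
                 spectrometerFreq = spectrometerFreq,
                 grid = as.numeric(grid), seed = as.integer(seed)),
            class = "simulatorConfig")
}

#' Lorentzian line evaluated on a grid
#'
#' `amplitude * gamma^2 / ((x - center)^2 + gamma^2)`: the natural
#' liquid-state NMR lineshape, peak height `amplitude`, HWHM `gamma`,
#' area `amplitude * pi * gamma`.
#'
#' @param center peak position in ppm
#' @param gamma half-width at half-maximum in ppm (> 0)
#' @param amplitude peak height
#' @param grid ppm axis
#' @return intensity vector on `grid`
#' @export
lorentzianLine <- function(center, gamma, amplitude, grid) {
  if (gamma <= 0) stop("gamma must be positive")
  amplitude * gamma^2 / ((grid - center)^2 + gamma^2)
}

#' First-order multiplet (s/d/t/q) as a sum of Lorentzian lines
#'
#' Lines are split by `J / freq` ppm with binomial relative heights
#' (1; 1:1; 1:2:1; 1:3:3:1), the tallest line scaled to `amplitude`.
#'
#' @param center multiplet center in ppm
#' @param pattern one of `"s"`, `"d"`, `"t"`, `"q"`
#' @param J scalar coupling in Hz
#' @param freq spectrometer frequency in MHz
#' @param grid ppm axis
#' @param gamma Lorentzian HWHM in ppm
#' @param amplitude height of the tallest line
#' @return intensity vector on `grid`
#' @export
generateMultiplet <- function(center, pattern = c("s", "d", "t", "q"),
                              J = 7, freq = 400, grid,
                              gamma = 0.0015, amplitude = 1) {
  pattern <- match.arg(pattern)
  nl <- match(pattern, c("s", "d", "t", "q"))
  coef <- choose(nl - 1, 0:(nl - 1))
  sep <- J / freq                       # line separation in ppm
  offs <- (seq_len(nl) - (nl + 1) / 2) * sep
  y <- numeric(length(grid))
  for (i in seq_len(nl))
    y <- y + lorentzianLine(center + offs[i], gamma,
                            amplitude * coef[i] / max(coef), grid)
  y
}

#' Generate a synthetic pure-compound spectral library
#'
#' Each compound is a random number of multiplets with random centers,
#' patterns, couplings and heights drawn from the config ranges; each
#' spectrum is max-normalized.  Deterministic given `config$seed`.
#'
#' @param config a [simulatorConfig()]
#' @return an [NMRLibrary-class]
#' @examples
#' lib <- generateLibrary(simulatorConfig(nCompounds = 4,
#'   grid = defaultGrid(2048), gamma = 0.01, seed = 7))
#' length(lib)
#' @export
generateLibrary <- function(config = simulatorConfig()) {
  stopifnot(inherits(config, "simulatorConfig"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  entries <- lapply(seq_len(config$nCompounds), function(i) {
    m <- sample(config$multipletsPerCompound[1]:config$multipletsPerCompound[2], 1)
    y <- numeric(length(config$grid))
    for (k in seq_len(m)) {
      y <- y + generateMultiplet(
        center = runif(1, config$ppmRange[1], config$ppmRange[2]),
        pattern = sample(c("s", "d", "t", "q"), 1),
        J = runif(1, config$jRange[1], config$jRange[2]),
        freq = config$spectrometerFreq,
        grid = config$grid, gamma = config$gamma,
        amplitude = runif(1, 0.2, 1))
    }
    normalizeMax(NMRSpectrum(config$grid, y,
                             name = sprintf("compound_%02d", i),
                             meta = list(synthetic = TRUE,
                                         freq = config$spectrometerFreq)))
  })
  NMRLibrary(entries)
}

# save/restore the global RNG state so generators are pure functions of
# their seed without clobbering the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
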