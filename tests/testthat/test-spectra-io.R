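# Reading, resampling, normalisation and library persistence.

test_that("two-column table spectra parse verbatim", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.0\t0.0", "2.0\t5.0", "3.0\t0.0"), f)
  s <- readSpectrum(f, "table")
  expect_s4_class(s, "NMRSpectrum")
  expect_length(s, 3)
  # axis normalised to descending on ingest
  expect_equal(ppmAxis(s), c(3, 2, 1))
  expect_equal(intensities(s), c(0, 5, 0))
})

test_that("degenerate and malformed inputs raise read errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  file.create(f)
  expect_error(readSpectrum(f, "table"), "empty")
  expect_error(readSpectrum(file.path(tempdir(), "no-such-file.txt"), "table"),
               "no such file")
  writeLines(c("0 0", "1 1", "5 0"), f)   # non-uniform grid
  expect_error(readSpectrum(f, "table"), "uniform")
})

test_that("write/read round-trips are the identity within 1e-9", {
  grid <- testGrid(128)
  s <- NMRSpectrum(grid, runif(128), name = "roundtrip",
                   meta = list(freq = 400))
  for (fmt in c("table", "jcamp")) {
    f <- withr::local_tempfile(fileext = ".dx")
    writeSpectrum(s, f, fmt)
    r <- readSpectrum(f, fmt)
    expect_equal(ppmAxis(r), ppmAxis(s), tolerance = 1e-9)
    expect_equal(intensities(r), intensities(s), tolerance = 1e-9)
  }
})

test_that("Bruker processed-1D directories are read with a reconstructed axis", {
  dir <- withr::local_tempdir()
  si <- 64L; offset <- 12.0; swp <- 4800; sf <- 400; ncproc <- -2L
  writeLines(c("##TITLE= Processing parameters",
               sprintf("##$SI= %d", si),
               sprintf("##$OFFSET= %g", offset),
               sprintf("##$SW_p= %g", swp),
               sprintf("##$SF= %g", sf),
               "##$BYTORDP= 0",
               sprintf("##$NC_proc= %d", ncproc),
               "##$DTYPP= 0",
               "##END="),
             file.path(dir, "procs"))
  raw <- as.integer(round(seq(-1000, 1000, length.out = si)))
  writeBin(raw, file.path(dir, "1r"), size = 4, endian = "little")
  s <- readSpectrum(dir, "bruker")
  expect_length(s, si)
  expect_equal(intensities(s), raw * 2^ncproc)
  expect_equal(ppmAxis(s)[1], offset)
  expect_equal(diff(ppmAxis(s))[1], -(swp / sf) / si)
  expect_equal(spectrumMeta(s)$freq, sf)
})

test_that("resampling interpolates linearly and zero-fills outside", {
  s <- NMRSpectrum(c(0, 1), c(0, 2), name = "ramp")
  r <- resampleSpectrum(s, seq(0, 2, by = 0.5))
  expect_equal(intensities(r), c(0, 1, 2, 0, 0))   # 0.5 -> 1.0; 1.5, 2 -> 0
  # identity on its own grid
  g <- testGrid(64)
  s2 <- NMRSpectrum(g, runif(64))
  expect_identical(intensities(resampleSpectrum(s2, g)), intensities(s2))
  expect_error(resampleSpectrum(s2, 1.0), "2 points")
})

test_that("max-normalisation scales to unit max, idempotently", {
  s <- NMRSpectrum(c(1, 0), c(2, 4))
  n1 <- normalizeMax(s)
  expect_equal(intensities(n1), c(0.5, 1.0))
  expect_equal(intensities(normalizeMax(n1)), intensities(n1))
  expect_error(normalizeMax(NMRSpectrum(c(1, 0), c(0, 0))), "positive")
})

test_that("library containers round-trip and reject duplicate names", {
  grid <- testGrid(64)
  lib <- NMRLibrary(lapply(1:3, function(i)
    NMRSpectrum(grid, runif(64), name = paste0("cpd", i),
                meta = list(freq = 400))))
  dir <- withr::local_tempdir()
  writeLibrary(lib, dir)
  back <- loadLibrary(dir)
  expect_equal(names(back), names(lib))
  expect_equal(ppmAxis(back), grid, tolerance = 1e-9)
  for (i in 1:3)
    expect_equal(intensities(back[[i]]), intensities(lib[[i]]),
                 tolerance = 1e-9)
  expect_equal(spectrumMeta(back[[1]])$freq, 400)

  # empty library round-trips
  edir <- withr::local_tempdir()
  writeLibrary(NMRLibrary(list()), edir)
  expect_length(loadLibrary(edir), 0)

  # duplicate names on load are a format error
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  man$names <- list("cpd1", "cpd1", "cpd3")
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(loadLibrary(dir), "duplicate")
})

test_that("spectrum validity enforces the grid and finiteness invariants", {
  expect_error(NMRSpectrum(c(1, 2, 4), c(0, 0, 0)), "uniform")
  expect_error(NMRSpectrum(c(1, 2), c(0, NA)), "finite")
  expect_error(NMRSpectrum(c(1, 2), c(0, 1, 2)), "length")
})
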