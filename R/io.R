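# Readers/writers for 1D NMR spectra and spectral libraries.
#
# Supported on disk: Bruker processed-1D directories (procs + 1r),
# JCAMP-DX 1D in AFFN (X++(Y..Y)) form, two-column ppm/intensity text,
# and the package's own library container (a directory of TSV matrices
# plus a JSON manifest).  Readers normalise the axis direction to the NMR
# display convention (high ppm first).

.asDescending <- function(ppm, intensity) {
  if (length(ppm) >= 2 && ppm[1] < ppm[2]) {
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  list(ppm = ppm, intensity = intensity)
}

#' Read a 1D NMR spectrum
#'
#' @param path file (table/JCAMP) or directory (Bruker processed data,
#'   the directory holding `procs` and `1r`, typically `.../pdata/1`)
#' @param format one of `"table"` (two columns: ppm, intensity; comma or
#'   whitespace separated), `"jcamp"`, `"bruker"`
#' @param name identifier; defaults to the file/title
#' @param normalize divide intensities by their maximum on ingest
#' @return an [NMRSpectrum-class] with a uniform, high-to-low ppm axis
#' @export
readSpectrum <- function(path, format = c("table", "jcamp", "bruker"),
                         name = NULL, normalize = FALSE) {
  format <- match.arg(format)
  sp <- switch(format,
    table  = .readTable(path, name),
    jcamp  = .readJcamp(path, name),
    bruker = .readBruker(path, name))
  if (!.uniformGridOK(sp@ppm))
    stop("non-uniform ppm grid in '", path, "' (beyond 1e-9 relative tolerance)")
  if (normalize) sp <- normalizeMax(sp)
  sp
}

.readTable <- function(path, name) {
  if (!file.exists(path)) stop("cannot read spectrum: no such file '", path, "'")
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  if (!length(txt)) stop("cannot read spectrum: '", path, "' is empty")
  sep <- if (any(grepl(",", txt[1], fixed = TRUE))) "," else ""
  df <- tryCatch(
    read.table(text = txt, sep = sep, header = FALSE, strip.white = TRUE),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e)))
  if (ncol(df) < 2 || !is.numeric(df[[1]]) || !is.numeric(df[[2]]))
    stop("'", path, "' is not two-column numeric (ppm, intensity)")
  d <- .asDescending(df[[1]], df[[2]])
  NMRSpectrum(d$ppm, d$intensity,
              name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
              meta = list(source = path, format = "table"))
}

#' Write a spectrum as two-column text or JCAMP-DX
#'
#' Round-trips through [readSpectrum()] within 1e-9.
#'
#' @param spectrum an [NMRSpectrum-class]
#' @param path output file
#' @param format `"table"` or `"jcamp"`
#' @return `path`, invisibly
#' @export
writeSpectrum <- function(spectrum, path, format = c("table", "jcamp")) {
  format <- match.arg(format)
  stopifnot(is(spectrum, "NMRSpectrum"))
  if (format == "table") {
    writeLines(sprintf("%.17g\t%.12g", spectrum@ppm, spectrum@intensity), path)
  } else {
    .writeJcamp(spectrum, path)
  }
  invisible(path)
}

# --- JCAMP-DX (1D, AFFN, (X++(Y..Y))) -------------------------------------

.writeJcamp <- function(spectrum, path) {
  n <- length(spectrum@ppm)
  freq <- spectrum@meta$freq
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("##TITLE= %s", spectrum@name)
  w("##JCAMP-DX= 5.00")
  w("##DATA TYPE= NMR SPECTRUM")
  w("##DATA CLASS= XYDATA")
  if (!is.null(freq)) w("##.OBSERVE FREQUENCY= %.6f", freq)
  w("##XUNITS= PPM")
  w("##YUNITS= ARBITRARY UNITS")
  w("##NPOINTS= %d", n)
  w("##FIRSTX= %.17g", spectrum@ppm[1])
  w("##LASTX= %.17g", spectrum@ppm[n])
  w("##DELTAX= %.17g", (spectrum@ppm[n] - spectrum@ppm[1]) / (n - 1))
  w("##XFACTOR= 1")
  w("##YFACTOR= 1")
  w("##FIRSTY= %.12g", spectrum@intensity[1])
  w("##XYDATA= (X++(Y..Y))")
  per <- 6L
  for (s in seq(1L, n, by = per)) {
    e <- min(s + per - 1L, n)
    w("%s", paste(c(sprintf("%.12g", spectrum@ppm[s]),
                    sprintf("%.12g", spectrum@intensity[s:e])), collapse = " "))
  }
  w("##END=")
}

.readJcamp <- function(path, name) {
  if (!file.exists(path)) stop("cannot read spectrum: no such file '", path, "'")
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("cannot read spectrum: '", path, "' is empty")
  ldr <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^##", key, "="), "", hit[1]))
  }
  npoints <- as.integer(ldr("NPOINTS"))
  firstx <- as.numeric(ldr("FIRSTX"))
  lastx <- as.numeric(ldr("LASTX"))
  xfac <- as.numeric(ldr("XFACTOR")); if (!length(xfac) || is.na(xfac)) xfac <- 1
  yfac <- as.numeric(ldr("YFACTOR")); if (!length(yfac) || is.na(yfac)) yfac <- 1
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("'", path, "' has no ##XYDATA= block")
  stop_ <- grep("^##END", lines)
  stop_ <- if (length(stop_)) min(stop_[stop_ > start[1]]) else length(lines) + 1L
  body <- lines[(start[1] + 1L):(stop_ - 1L)]
  body <- body[!grepl("^\\s*$", body)]
  y <- unlist(lapply(body, function(ln) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1]]
    as.numeric(tok[-1]) * yfac          # first token is the X checkpoint
  }), use.names = FALSE)
  if (is.na(npoints) || !length(npoints)) npoints <- length(y)
  if (length(y) != npoints)
    stop("'", path, "': expected ", npoints, " points, found ", length(y))
  if (anyNA(y)) stop("'", path, "': non-numeric Y data")
  ppm <- seq(firstx * xfac, lastx * xfac, length.out = npoints)
  d <- .asDescending(ppm, y)
  title <- ldr("TITLE")
  freq <- as.numeric(ldr("\\.OBSERVE FREQUENCY"))
  meta <- list(source = path, format = "jcamp")
  if (length(freq) && !is.na(freq)) meta$freq <- freq
  NMRSpectrum(d$ppm, d$intensity,
              name = if (!is.null(name)) name
                     else if (!is.null(title) && nzchar(title)) title
                     else sub("\\.[^.]*$", "", basename(path)),
              meta = meta)
}

# --- Bruker processed 1D --------------------------------------------------

.brukerParams <- function(procsPath) {
  lines <- readLines(procsPath, warn = FALSE)
  get <- function(key, numeric = TRUE) {
    hit <- grep(paste0("^##\\$", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    v <- trimws(sub("^##\\$[^=]*=", "", hit[1]))
    if (numeric) as.numeric(v) else v
  }
  list(SI = as.integer(get("SI")), OFFSET = get("OFFSET"),
       SW_p = get("SW_p"), SF = get("SF"),
       BYTORDP = get("BYTORDP"), NC_proc = get("NC_proc"),
       DTYPP = get("DTYPP"))
}

# path: the directory holding `procs` and `1r` (e.g. <exp>/pdata/1).
# The ppm axis is reconstructed from OFFSET (left edge, ppm), SW_p/SF
# (sweep width in ppm) and SI; integer data are scaled by 2^NC_proc.
.readBruker <- function(path, name) {
  if (!dir.exists(path)) stop("cannot read spectrum: no such directory '", path, "'")
  procs <- file.path(path, "procs")
  onef <- file.path(path, "1r")
  if (!file.exists(procs) || !file.exists(onef))
    stop("'", path, "' is not Bruker processed data (needs procs and 1r)")
  p <- .brukerParams(procs)
  if (is.na(p$SI) || is.na(p$OFFSET) || is.na(p$SW_p) || is.na(p$SF))
    stop("'", procs, "': missing SI/OFFSET/SW_p/SF")
  endian <- if (!is.na(p$BYTORDP) && p$BYTORDP == 1) "big" else "little"
  dtypp <- if (is.na(p$DTYPP)) 0 else p$DTYPP
  con <- file(onef, "rb")
  on.exit(close(con))
  y <- if (dtypp == 2) {
    readBin(con, "double", n = p$SI, size = 8, endian = endian)
  } else {
    nc <- if (is.na(p$NC_proc)) 0 else p$NC_proc
    readBin(con, "integer", n = p$SI, size = 4, endian = endian) * 2^nc
  }
  if (length(y) != p$SI)
    stop("'", onef, "' is truncated: expected ", p$SI, " points, got ", length(y))
  swPpm <- p$SW_p / p$SF
  ppm <- p$OFFSET - swPpm * (seq_len(p$SI) - 1) / p$SI
  NMRSpectrum(ppm, y,
              name = if (is.null(name)) basename(dirname(dirname(path))) else name,
              meta = list(source = path, format = "bruker", freq = p$SF))
}

# --- resampling and scaling -----------------------------------------------

#' Resample a spectrum onto a new uniform grid
#'
#' Linear interpolation; points outside the spectrum's ppm range are
#' filled with 0 (baseline-corrected spectra assumed).  Exact when the
#' grids coincide.
#'
#' @param spectrum an [NMRSpectrum-class]
#' @param grid target ppm axis (uniform, either direction)
#' @return an [NMRSpectrum-class] on `grid`
#' @export
resampleSpectrum <- function(spectrum, grid) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  grid <- as.numeric(grid)
  if (length(grid) < 2) stop("target grid needs at least 2 points")
  if (!.uniformGridOK(grid)) stop("target grid must be monotone and uniform")
  if (length(grid) == length(spectrum@ppm) &&
      max(abs(grid - spectrum@ppm)) <= 1e-12)
    return(spectrum)
  o <- order(spectrum@ppm)
  y <- approx(spectrum@ppm[o], spectrum@intensity[o], xout = grid,
              method = "linear", rule = 1)$y
  y[is.na(y)] <- 0
  NMRSpectrum(grid, y, name = spectrum@name, meta = spectrum@meta)
}

#' Scale a spectrum to unit maximum intensity
#'
#' Idempotent; errors when no strictly positive intensity exists.
#'
#' @param spectrum an [NMRSpectrum-class]
#' @return the spectrum divided by its maximum intensity
#' @export
normalizeMax <- function(spectrum) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  m <- max(spectrum@intensity)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize '", spectrum@name,
         "': no strictly positive intensity")
  NMRSpectrum(spectrum@ppm, spectrum@intensity / m,
              name = spectrum@name, meta = spectrum@meta)
}

# --- library container ----------------------------------------------------

#' Write / load a spectral library
#'
#' The container is a plain-text directory: `grid.tsv` (the shared ppm
#' axis), `intensities.tsv` (one column per entry, manifest order) and
#' `manifest.json` (entry names and metadata).  Round-trips losslessly
#' within 1e-9.
#'
#' @param library an [NMRLibrary-class]
#' @param path directory to create/overwrite
#' @return `path` (write) or an [NMRLibrary-class] (load)
#' @export
writeLibrary <- function(library, path) {
  stopifnot(is(library, "NMRLibrary"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(sprintf("%.17g", library@grid), file.path(path, "grid.tsv"))
  m <- intensities(library)
  con <- file(file.path(path, "intensities.tsv"), "w")
  if (length(library)) {
    apply_fmt <- function(row) paste(sprintf("%.12g", row), collapse = "\t")
    writeLines(vapply(seq_len(nrow(m)), function(i) apply_fmt(m[i, ]),
                      character(1)), con)
  }
  close(con)
  manifest <- list(
    container = "nmrmix-library", version = 1L,
    n = length(library),
    names = as.list(names(library)),
    meta = lapply(library@entries, function(s) s@meta))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeLibrary
#' @export
loadLibrary <- function(path) {
  man <- file.path(path, "manifest.json")
  if (!file.exists(man)) stop("'", path, "' is not a library container")
  manifest <- jsonlite::read_json(man)
  nm <- vapply(manifest$names, as.character, character(1))
  if (anyDuplicated(nm))
    stop("library container '", path, "' has duplicate entry names")
  grid <- as.numeric(readLines(file.path(path, "grid.tsv")))
  entries <- list()
  if (length(nm)) {
    m <- as.matrix(read.table(file.path(path, "intensities.tsv"), sep = "\t"))
    if (nrow(m) != length(grid) || ncol(m) != length(nm))
      stop("library container '", path, "' is inconsistent")
    entries <- lapply(seq_along(nm), function(j)
      NMRSpectrum(grid, m[, j], name = nm[j],
                  meta = .metaFromJson(manifest$meta[[j]])))
  }
  new("NMRLibrary", grid = grid, entries = entries)
}

.metaFromJson <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(v) if (is.list(v)) unlist(v) else v)
}
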