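#' Hyperspectral cubes
#'
#' A `hypercube` is a 3-D numeric array in `lines x pixels x bands` order,
#' carrying its wavelength grid (nm, strictly increasing) and a processing
#' `stage` tag: `"raw"` sensor counts, `"reflectance"` after two-point
#' calibration, or `"absorbance"` after the log10(1/R) transform.
#'
#' @param data numeric array, `lines x pixels x bands`.
#' @param wavelengths numeric vector of band centres (nm), strictly
#'   increasing, one per band.
#' @param stage one of `"raw"`, `"reflectance"`, `"absorbance"`.
#' @return A `hypercube` object.
#' @export
hypercube <- function(data, wavelengths, stage = c("raw", "reflectance", "absorbance")) {
  stage <- match.arg(stage)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    stop("bands dimension (", dim(data)[3], ") does not match wavelength length (",
         length(wavelengths), ")", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  structure(list(data = data, wavelengths = wavelengths, stage = stage),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d pixels x %d bands [%s], %.2f-%.2f nm\n",
              d[1], d[2], d[3], x$stage, min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Calibration frame pair
#'
#' Holds the dark-current frame (lamps off, entry window covered) and the
#' white-reference frame (PTFE tile at operation conditions) used for
#' two-point radiometric calibration. Before use each frame is reduced to
#' per-pixel-column medians across lines, suppressing line-to-line shot
#' noise in the single acquired reference frames.
#'
#' @param dark,white `hypercube`s (or bare arrays) with the same pixel and
#'   band geometry as the scene cubes they calibrate.
#' @return A `calibration_frames` object with `dark` and `white` matrices of
#'   size `pixels x bands`.
#' @export
calibration_frames <- function(dark, white) {
  dk <- if (inherits(dark, "hypercube")) dark$data else dark
  wh <- if (inherits(white, "hypercube")) white$data else white
  stopifnot(identical(dim(dk), dim(wh)))
  smooth <- function(a) apply(a, c(2, 3), median)
  structure(list(dark = smooth(dk), white = smooth(wh), dims = dim(dk)),
            class = "calibration_frames")
}

#' Two-point radiometric calibration
#'
#' Converts raw sensor counts to reflectance using the dark and white
#' reference frames: `R = (raw - dark) / (white - dark)`, per pixel column
#' and band. Values are clipped to `clip` afterwards; the default lower
#' bound avoids log-transform infinities from dead pixels and the upper
#' bound preserves moderate >100 % glints.
#'
#' @param raw a `hypercube` at stage `"raw"`.
#' @param frames a [calibration_frames()] object.
#' @param clip length-2 numeric, reflectance clipping bounds.
#' @return A `hypercube` at stage `"reflectance"`.
#' @export
calibrate_reflectance <- function(raw, frames, clip = c(1e-4, 1.5)) {
  stopifnot(inherits(raw, "hypercube"), inherits(frames, "calibration_frames"))
  if (raw$stage != "raw") stop("cube stage must be 'raw', not '", raw$stage, "'", call. = FALSE)
  d <- dim(raw$data)
  if (!identical(d[2:3], frames$dims[2:3]))
    stop("calibration frame geometry does not match the cube", call. = FALSE)
  denom <- frames$white - frames$dark              # pixels x bands
  bad <- apply(denom <= 0, 2, any)
  if (any(bad))
    stop("white - dark <= 0 after smoothing in band(s): ",
         paste(format(raw$wavelengths[bad]), collapse = ", "), call. = FALSE)
  r <- array(NA_real_, d)
  for (b in seq_len(d[3])) {
    r[, , b] <- sweep(sweep(raw$data[, , b, drop = TRUE], 2, frames$dark[, b]),
                      2, denom[, b], `/`)
  }
  r[r < clip[1]] <- clip[1]
  r[r > clip[2]] <- clip[2]
  hypercube(r, raw$wavelengths, "reflectance")
}

#' Absorbance transform
#'
#' `A = log10(1 / R)` applied band-wise to a reflectance cube.
#'
#' @param cube a `hypercube` at stage `"reflectance"`.
#' @return A `hypercube` at stage `"absorbance"`.
#' @export
to_absorbance <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$stage != "reflectance")
    stop("cube stage must be 'reflectance', not '", cube$stage, "'", call. = FALSE)
  hypercube(log10(1 / cube$data), cube$wavelengths, "absorbance")
}

#' Band subrange selection
#'
#' Keeps the bands with `min_nm <= lambda <= max_nm` (inclusive on both
#' ends). The instrument's spectral extremes are noisy; the analysis keeps
#' the 950-1650 nm subrange by default.
#'
#' @param cube a `hypercube` at any stage.
#' @param min_nm,max_nm subrange bounds in nm.
#' @return A `hypercube` with the reduced band set.
#' @export
subset_bands <- function(cube, min_nm = 950, max_nm = 1650) {
  stopifnot(inherits(cube, "hypercube"), min_nm < max_nm)
  keep <- cube$wavelengths >= min_nm & cube$wavelengths <= max_nm
  if (!any(keep))
    stop("no bands inside [", min_nm, ", ", max_nm, "] nm", call. = FALSE)
  hypercube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep], cube$stage)
}

# ---- ENVI-style I/O ---------------------------------------------------------

envi_dtype <- function(code) {
  switch(as.character(code),
         "2"  = list(what = "integer", size = 2L, signed = TRUE),
         "4"  = list(what = "double",  size = 4L, signed = TRUE),
         "5"  = list(what = "double",  size = 8L, signed = TRUE),
         "12" = list(what = "integer", size = 2L, signed = FALSE),
         stop("unsupported ENVI data type: ", code, call. = FALSE))
}

#' Read and write ENVI-style hyperspectral cubes
#'
#' Flat binary plus a `key = value` text header declaring `samples` (pixels
#' per line), `lines`, `bands`, `data type` (2, 4, 5 or 12), `interleave`
#' (bsq, bil or bip) and a `wavelength = { ... }` list in nm. Files are
#' little-endian. `read_cube()` materializes the grid in
#' `lines x pixels x bands` order regardless of interleave; `write_cube()`
#' always writes band-sequential (BSQ) 8-byte floats.
#'
#' @param header_path,data_path paths to the header text file and binary file.
#' @param cube a `hypercube` to write.
#' @param stage stage tag to assign to the cube read from disk.
#' @return `read_cube()` a `hypercube`; `write_cube()` the paths, invisibly.
#' @export
read_cube <- function(header_path, data_path, stage = "raw") {
  hdr <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("header lacks field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(hdr$wavelength)) stop("header lacks a wavelength list", call. = FALSE)
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines); nb <- as.integer(hdr$bands)
  wl <- as.numeric(strsplit(gsub("[{}\n]", "", hdr$wavelength), ",")[[1]])
  if (length(wl) != nb)
    stop("header declares ", nb, " bands but lists ", length(wl), " wavelengths", call. = FALSE)
  dt <- envi_dtype(hdr$`data type`)
  n <- ns * nl * nb
  raw <- readBin(data_path, what = dt$what, n = n + 1L, size = dt$size,
                 signed = dt$signed, endian = "little")
  if (length(raw) != n)
    stop("binary length ", length(raw), " does not match declared dimensions (", n, ")",
         call. = FALSE)
  arr <- switch(tolower(hdr$interleave),
                bsq = aperm(array(raw, c(ns, nl, nb)), c(2, 1, 3)),
                bil = aperm(array(raw, c(ns, nb, nl)), c(3, 1, 2)),
                bip = aperm(array(raw, c(nb, ns, nl)), c(3, 2, 1)),
                stop("unsupported interleave: ", hdr$interleave, call. = FALSE))
  hypercube(arr, wl, stage)
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- sub("^ENVI\n?", "", txt)
  # join brace-delimited values onto one logical line
  out <- list()
  pat <- "(?s)([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  starts <- m; lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- trimws(sub("=.*", "", piece))
    val <- trimws(sub("^[^=]*=", "", piece))
    out[[tolower(key)]] <- val
  }
  out
}

#' @rdname read_cube
#' @export
write_cube <- function(cube, header_path, data_path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("wavelength = {%s}", paste(format(cube$wavelengths, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, header_path)
  con <- file(data_path, "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(cube$data, c(2, 1, 3))), con, size = 8L, endian = "little")
  invisible(c(header = header_path, data = data_path))
}
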