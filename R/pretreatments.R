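#' WinISI-style pretreatment codes
#'
#' A pretreatment code combines a scatter-correction stage (`SNV`, `detrend`,
#' `MSC`, or none, possibly chained as in `"SNV+detrend"`) with a
#' gap-segment derivative stage written as four numbers `d,g,s1,s2`: the
#' derivative order, the gap (in bands) over which the derivative is taken,
#' the width of a first running-mean smoothing, and of a second smoothing.
#' `parse_pretreatment()` reads code strings exactly as conventionally
#' printed (`"SNV+detrend 2,5,5,1"`, `"MSC 1,5,5,1"`, `"None 0,0,1,1"`);
#' `format()` serializes back to that form.
#'
#' @param code a code string.
#' @param derivative_first apply the derivative stage before scatter
#'   correction instead of after (default scatter first).
#' @return A `pretreatment_code` object.
#' @export
parse_pretreatment <- function(code, derivative_first = FALSE) {
  txt <- trimws(code)
  m <- regmatches(txt, regexec("^([A-Za-z+]+)\\s+(\\d+),(\\d+),(\\d+),(\\d+)$", txt))[[1]]
  if (length(m) == 0L)
    stop("cannot parse pretreatment code: '", code, "'", call. = FALSE)
  ops_raw <- strsplit(m[2], "+", fixed = TRUE)[[1]]
  op_map <- c(snv = "SNV", detrend = "detrend", msc = "MSC", none = "none")
  ops <- op_map[tolower(ops_raw)]
  if (anyNA(ops))
    stop("unknown scatter operation in '", code, "'", call. = FALSE)
  ops <- ops[ops != "none"]
  d <- as.integer(m[3]); g <- as.integer(m[4])
  s1 <- as.integer(m[5]); s2 <- as.integer(m[6])
  if (!d %in% 0:2) stop("derivative order must be 0, 1 or 2", call. = FALSE)
  if (d >= 1 && g < 1) stop("gap must be >= 1 when a derivative is taken", call. = FALSE)
  if (s1 < 1 || s2 < 1) stop("smoothing widths must be >= 1", call. = FALSE)
  structure(list(scatter_ops = unname(ops), d = d, g = g, s1 = s1, s2 = s2,
                 msc_reference = NULL, derivative_first = derivative_first),
            class = "pretreatment_code")
}

#' @export
format.pretreatment_code <- function(x, ...) {
  ops <- if (length(x$scatter_ops) == 0L) "None"
         else paste(ifelse(x$scatter_ops == "detrend", "detrend", x$scatter_ops),
                    collapse = "+")
  # leading op is capitalized when detrend stands alone, as printed
  if (ops == "detrend") ops <- "Detrend"
  sprintf("%s %d,%d,%d,%d", ops, x$d, x$g, x$s1, x$s2)
}

#' @export
print.pretreatment_code <- function(x, ...) {
  cat("<pretreatment_code>", format(x),
      if (!is.null(x$msc_reference)) "(MSC reference stored)", "\n")
  invisible(x)
}

#' Standard normal variate
#'
#' Per-spectrum centering and unit-variance scaling (n-1 denominator),
#' removing multiplicative scatter and additive baseline per spectrum.
#'
#' @param spectra spectrum table or matrix (rows = samples).
#' @return Same shape as the input, transformed.
#' @export
snv <- function(spectra) {
  x <- spectra_matrix_or_plain(spectra)
  s <- apply(x, 1, sd)
  if (any(s <= 0)) {
    bad <- rownames(x)[s <= 0] %||% which(s <= 0)
    stop("zero-variance spectrum for sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- (x - rowMeans(x)) / s
  rebuild_like(spectra, out)
}

#' Polynomial detrend
#'
#' Subtracts from each spectrum its own least-squares polynomial (default
#' quadratic) in wavelength; usually chained after SNV as `"SNV+detrend"`.
#'
#' @param spectra spectrum table or matrix.
#' @param wavelengths band grid (taken from the input when omitted).
#' @param degree polynomial degree.
#' @return Same shape as the input, detrended.
#' @export
detrend <- function(spectra, wavelengths = NULL, degree = 2) {
  x <- spectra_matrix_or_plain(spectra)
  wl <- wavelengths %||% input_wavelengths(spectra, ncol(x))
  if (length(unique(wl)) <= degree)
    stop("degenerate wavelength grid for degree-", degree, " detrend", call. = FALSE)
  # orthonormal polynomial basis keeps the projection well-conditioned on
  # nm-scale grids
  basis <- cbind(1 / sqrt(length(wl)), stats::poly(wl, degree = degree))
  out <- x - (x %*% basis) %*% t(basis)
  rebuild_like(spectra, out)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum (`x ~ a + b * ref`) and
#' returns `(x - a) / b`. The reference is the calibration-set mean spectrum,
#' stored at fit time and reused at prediction time.
#'
#' @param spectra spectrum table or matrix.
#' @param reference reference spectrum (defaults to the column mean of
#'   `spectra`, i.e. fit mode).
#' @return Same shape as the input, corrected.
#' @export
msc <- function(spectra, reference = NULL) {
  x <- spectra_matrix_or_plain(spectra)
  ref <- reference %||% colMeans(x)
  stopifnot(length(ref) == ncol(x))
  refc <- ref - mean(ref)
  denom <- sum(refc^2)
  # slope = cov(x, ref)/var(ref); intercept from the means
  b <- drop((x - rowMeans(x)) %*% refc) / denom
  a <- rowMeans(x) - b * mean(ref)
  if (any(abs(b) < 1e-8)) {
    bad <- rownames(x)[abs(b) < 1e-8] %||% which(abs(b) < 1e-8)
    stop("MSC slope ~ 0 for sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- (x - a) / b
  rebuild_like(spectra, out)
}

#' Gap-segment derivative
#'
#' First running-mean smoothing of width `s1`, then the gap derivative
#' (`d = 1`: `D(i) = s(i+g) - s(i-g)`; `d = 2`:
#' `D(i) = s(i-g) - 2 s(i) + s(i+g)`; `d = 0`: identity), then a second
#' running-mean smoothing of width `s2`. A central-difference stencil with
#' symmetric support is used; edge bands without full support are dropped
#' rather than padded, and the surviving wavelength grid is returned with
#' the result. Widths of 1 mean no smoothing; even widths are rounded up to
#' the next odd width with a warning.
#'
#' @param spectra spectrum table or matrix.
#' @param d derivative order (0, 1 or 2).
#' @param g gap in bands (`>= 1` when `d >= 1`).
#' @param s1,s2 running-mean widths.
#' @param wavelengths band grid (taken from the input when omitted).
#' @return Same kind as the input, with reduced band support.
#' @export
gap_segment_derivative <- function(spectra, d, g, s1, s2, wavelengths = NULL) {
  x <- spectra_matrix_or_plain(spectra)
  wl <- wavelengths %||% input_wavelengths(spectra, ncol(x))
  s1 <- odd_width(s1); s2 <- odd_width(s2)
  sm <- running_mean(x, s1); wl <- trim_wl(wl, s1)
  if (d >= 1) {
    nb <- ncol(sm)
    if (nb < 2 * g + 1) stop("band support exhausted by gap derivative", call. = FALSE)
    core <- (g + 1):(nb - g)
    sm <- if (d == 1) sm[, core + g, drop = FALSE] - sm[, core - g, drop = FALSE]
          else sm[, core - g, drop = FALSE] - 2 * sm[, core, drop = FALSE] +
               sm[, core + g, drop = FALSE]
    wl <- wl[core]
  }
  sm <- running_mean(sm, s2); wl <- trim_wl(wl, s2)
  if (ncol(sm) < 1L) stop("band support exhausted by smoothing", call. = FALSE)
  rebuild_like(spectra, sm, wl)
}

odd_width <- function(s) {
  if (s %% 2 == 0) {
    warning("even smoothing width ", s, " rounded up to ", s + 1)
    s + 1L
  } else as.integer(s)
}

running_mean <- function(x, s) {
  if (s <= 1L) return(x)
  nb <- ncol(x)
  if (nb < s) stop("band support exhausted by smoothing", call. = FALSE)
  h <- (s - 1L) %/% 2L
  core <- (h + 1L):(nb - h)
  if (nrow(x) == 0L) return(x[, core, drop = FALSE])
  cs <- cbind(0, t(apply(x, 1, cumsum)))
  (cs[, core + h + 1L, drop = FALSE] - cs[, core - h, drop = FALSE]) / s
}

trim_wl <- function(wl, s) {
  if (s <= 1L) return(wl)
  h <- (s - 1L) %/% 2L
  wl[(h + 1L):(length(wl) - h)]
}

#' Apply a pretreatment code
#'
#' Applies the scatter operations in their listed order, then the
#' gap-segment derivative stage (or the reverse when the code was parsed
#' with `derivative_first = TRUE`). In `"fit"` mode an MSC reference (the
#' input mean spectrum) is recorded on the returned code; `"transform"` mode
#' requires that reference and reuses it, so prediction-time spectra are
#' corrected against the calibration reference.
#'
#' @param spectra spectrum table or matrix.
#' @param code a `pretreatment_code` or code string.
#' @param mode `"fit"` or `"transform"`.
#' @return A list with `spectra` (same kind as input, possibly narrower band
#'   support), `wavelengths`, and `code` (with MSC reference recorded in fit
#'   mode).
#' @export
apply_pretreatment <- function(spectra, code, mode = c("fit", "transform")) {
  mode <- match.arg(mode)
  if (is.character(code)) code <- parse_pretreatment(code)
  x <- spectra
  wl <- input_wavelengths(spectra, ncol(spectra_matrix_or_plain(spectra)))

  scatter_stage <- function(x) {
    for (op in code$scatter_ops) {
      x <- switch(op,
        SNV = snv(x),
        detrend = detrend(x, wavelengths = current_wl(x, wl)),
        MSC = {
          if (mode == "transform") {
            if (is.null(code$msc_reference))
              stop("MSC transform requested before fit: no stored reference",
                   call. = FALSE)
            msc(x, code$msc_reference)
          } else {
            code$msc_reference <<- colMeans(spectra_matrix_or_plain(x))
            msc(x)
          }
        })
    }
    x
  }
  deriv_stage <- function(x)
    gap_segment_derivative(x, code$d, code$g, code$s1, code$s2,
                           wavelengths = current_wl(x, wl))

  out <- if (isTRUE(code$derivative_first)) scatter_stage(deriv_stage(x))
         else deriv_stage(scatter_stage(x))
  list(spectra = out,
       wavelengths = current_wl(out, wl),
       code = code)
}

current_wl <- function(x, fallback) {
  tryCatch(spectra_wavelengths(x), error = function(e) fallback)
}

input_wavelengths <- function(spectra, nb) {
  tryCatch(spectra_wavelengths(spectra), error = function(e) seq_len(nb))
}

# matrix view that tolerates matrices without a wavelengths attribute
spectra_matrix_or_plain <- function(spectra) {
  if (is.matrix(spectra)) spectra else spectra_matrix(spectra)
}

rebuild_like <- function(input, mat, wavelengths = NULL) {
  wl <- wavelengths %||% input_wavelengths(input, ncol(mat))
  if (is.matrix(input)) {
    rownames(mat) <- rownames(input)
    if (!is.null(attr(input, "wavelengths")) || !is.null(wavelengths))
      attr(mat, "wavelengths") <- wl
    return(mat)
  }
  rebuild_spectra(input, mat, wl)
}
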