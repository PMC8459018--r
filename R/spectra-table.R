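#' Spectrum tables
#'
#' A spectrum table is a wide tibble holding one mean absorbance spectrum per
#' row: an `id` column, optional `variety` and `area` metadata columns, and
#' one numeric column per wavelength, named by the wavelength in nm
#' (e.g. `"1203.25"`). All pretreatment, selection and regression functions
#' accept either a spectrum table or a plain numeric matrix whose columns are
#' bands.
#'
#' @param x numeric matrix (rows = samples, columns = bands).
#' @param wavelengths numeric vector of band centres in nm, one per column.
#' @param id character vector of sample identifiers (default `s1`, `s2`, ...).
#' @param variety optional character vector of variety labels.
#' @param area optional numeric vector (ROI pixel areas).
#' @return `spectra_table()` returns a tibble; `spectra_matrix()` a numeric
#'   matrix with a `wavelengths` attribute; `spectra_wavelengths()` the
#'   wavelength grid in nm.
#' @export
spectra_table <- function(x, wavelengths, id = NULL, variety = NULL, area = NULL) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(wavelengths))
  id <- id %||% paste0("s", seq_len(nrow(x)))
  out <- tibble::tibble(id = as.character(id))
  if (!is.null(variety)) out$variety <- as.character(variety)
  if (!is.null(area)) out$area <- as.numeric(area)
  mat <- as.data.frame(x)
  names(mat) <- format_wavelength(wavelengths)
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}

format_wavelength <- function(wl) {
  # fixed 2-dp names so that parse(format(wl)) round-trips the grid
  sprintf("%.2f", wl)
}

is_band_column <- function(nm) grepl("^[0-9]+(\\.[0-9]+)?$", nm)

#' @rdname spectra_table
#' @export
spectra_wavelengths <- function(x) {
  if (is.matrix(x)) {
    wl <- attr(x, "wavelengths")
    if (is.null(wl)) stop("matrix has no 'wavelengths' attribute", call. = FALSE)
    return(wl)
  }
  as.numeric(names(x)[is_band_column(names(x))])
}

#' @rdname spectra_table
#' @export
spectra_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(attr(x, "wavelengths")))
      stop("matrix input must carry a 'wavelengths' attribute", call. = FALSE)
    return(x)
  }
  stopifnot(is.data.frame(x))
  band_cols <- names(x)[is_band_column(names(x))]
  if (length(band_cols) == 0L) stop("no band columns found", call. = FALSE)
  m <- as.matrix(x[band_cols])
  rownames(m) <- if ("id" %in% names(x)) as.character(x$id) else NULL
  attr(m, "wavelengths") <- as.numeric(band_cols)
  m
}

#' @rdname spectra_table
#' @export
spectra_ids <- function(x) {
  if (is.matrix(x)) rownames(x) %||% paste0("s", seq_len(nrow(x)))
  else as.character(x$id)
}

# rebuild a table like `tbl` but with new band data (used after pretreatment,
# which may shrink the band support)
rebuild_spectra <- function(tbl, mat, wavelengths) {
  if (is.matrix(tbl)) {
    attr(mat, "wavelengths") <- wavelengths
    rownames(mat) <- rownames(tbl)
    return(mat)
  }
  meta <- tbl[!is_band_column(names(tbl))]
  dplyr::bind_cols(meta, spectra_table(mat, wavelengths)[-1])
}
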