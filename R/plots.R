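#' Plot spectra
#'
#' Line plot of every spectrum in a spectrum table, coloured by variety
#' when present.
#'
#' @param spectra a spectrum table.
#' @param alpha line transparency.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, alpha = 0.4) {
  m <- spectra_matrix(spectra)
  long <- tibble::tibble(
    id = rep(spectra_ids(spectra), times = ncol(m)),
    wavelength = rep(spectra_wavelengths(spectra), each = nrow(m)),
    absorbance = as.vector(m))
  if (is.data.frame(spectra) && "variety" %in% names(spectra)) {
    long$variety <- rep(spectra$variety, times = ncol(m))
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$absorbance,
                                            group = .data$id, colour = .data$variety))
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$absorbance,
                                            group = .data$id))
  }
  p + ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance (log 1/R)")
}

#' @export
autoplot.mpls_model <- function(object, ...) {
  df <- tibble::tibble(factors = seq_along(object$secv_by_factor),
                       secv = object$secv_by_factor)
  ggplot2::ggplot(df, ggplot2::aes(.data$factors, .data$secv)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_factors, linetype = 2) +
    ggplot2::labs(x = "PLS factors", y = "SECV",
                  title = sprintf("%s: %d factors selected",
                                  format(object$code), object$n_factors))
}

#' @export
autoplot.selection_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$h, fill = .data$set)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::geom_vline(xintercept = 3, linetype = 2) +
    ggplot2::labs(x = "global H", y = "samples")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
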