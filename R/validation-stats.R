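#' Calibration and validation error statistics
#'
#' The NIR reporting conventions: `SEC = sqrt(SSE / (n - f - 1))` (residual
#' SD corrected for the `f` PLS factors and the intercept),
#' `SECV = sqrt(sum(e_cv^2) / n)`, and `RSQ = 1 - SSE/SST` on the
#' calibration set.
#'
#' @param residuals calibration residuals `y - yhat`.
#' @param f number of PLS factors in the model.
#' @return A single numeric value.
#' @export
sec <- function(residuals, f) {
  n <- length(residuals)
  if (n <= f + 1) stop("need n > f + 1 for SEC", call. = FALSE)
  sqrt(sum(residuals^2) / (n - f - 1))
}

#' @rdname sec
#' @param cv_residuals cross-validated residuals.
#' @export
secv <- function(cv_residuals) sqrt(mean(cv_residuals^2))

#' @rdname sec
#' @param y,yhat observed and fitted calibration values.
#' @export
rsq <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("SST = 0: constant reference values", call. = FALSE)
  1 - sum((y - yhat)^2) / sst
}

#' Standard error of prediction (external validation)
#'
#' `bias = mean(e)` and the bias-corrected
#' `SEP = sqrt(sum((e - bias)^2) / (n - 1))`; the uncorrected
#' `RMSEP = sqrt(mean(e^2))` is reported alongside since either convention
#' appears in NIR software output.
#'
#' @param y_val,yhat_val observed and predicted validation values
#'   (`n >= 3`).
#' @return A list with `sep`, `bias`, `rmsep`, `n_val`.
#' @export
sep <- function(y_val, yhat_val) {
  e <- y_val - yhat_val
  n <- length(e)
  if (n < 3) stop("need at least 3 validation samples", call. = FALSE)
  bias <- mean(e)
  list(sep = sqrt(sum((e - bias)^2) / (n - 1)),
       bias = bias,
       rmsep = sqrt(mean(e^2)),
       n_val = n)
}

#' Estimated applicability range
#'
#' `Est.Min / Est.Max = mean(y) -/+ 3 * SD(y)` (n-1 denominator) over the
#' calibration reference values: the conventional statement of the range a
#' calibration can be applied over.
#'
#' @param y_cal calibration reference values (`n >= 2`).
#' @return Named numeric vector `est_min`, `est_max`.
#' @export
estimated_range <- function(y_cal) {
  stopifnot(length(y_cal) >= 2)
  m <- mean(y_cal); s <- sd(y_cal)
  c(est_min = m - 3 * s, est_max = m + 3 * s)
}

#' Percent error relative to the range midpoint
#'
#' Errors are expressed as a percentage of the mean of the estimated range:
#' `100 * err / ((est_min + est_max) / 2)`.
#'
#' @param err an error in analyte units (SECV or SEP).
#' @param est_min,est_max applicability range bounds.
#' @return Percent error.
#' @export
percent_error <- function(err, est_min, est_max) {
  mid <- (est_min + est_max) / 2
  if (mid == 0) stop("range midpoint is 0", call. = FALSE)
  100 * err / mid
}

#' Build a full validation report for an MPLS model
#'
#' Mirrors the conventional calibration-report row: pretreatment code, T
#' outliers, PLS factors, N, Est.Min, SD, Est.Max, SEC, RSQ, SECV, SEP,
#' bias, RMSEP and the percent-of-range errors. Percentages are reported to
#' 3 decimals (round-half-even).
#'
#' @param model an `mpls_model`.
#' @param x_val validation spectra (spectrum table or matrix); `NULL` (or
#'   fewer than 3 validation samples) leaves the external-validation columns
#'   `NA` with a warning.
#' @param y_val validation reference values.
#' @param analyte analyte label for the report row.
#' @return A one-row tibble.
#' @export
validation_report <- function(model, x_val = NULL, y_val = NULL,
                              analyte = "analyte") {
  rng <- estimated_range(model$y_cal)
  if (is.null(x_val) || length(y_val) < 3) {
    if (!is.null(x_val) || length(y_val) > 0)
      warning("fewer than 3 validation samples: SEP not estimated")
    sp <- list(sep = NA_real_, bias = NA_real_, rmsep = NA_real_,
               n_val = length(y_val))
  } else {
    yhat <- predict(model, x_val)
    sp <- sep(y_val, yhat)
  }
  tibble::tibble(
    analyte = analyte,
    pretreatment = format(model$code),
    t_outliers = nrow(model$removed_outliers),
    pls_factors = model$n_factors,
    n = model$n_cal,
    est_min = rng[["est_min"]],
    sd = sd(model$y_cal),
    est_max = rng[["est_max"]],
    sec = model$sec,
    rsq = model$rsq,
    secv = model$secv,
    sep = sp$sep,
    bias = sp$bias,
    rmsep = sp$rmsep,
    n_val = sp$n_val,
    secv_pct = round(percent_error(model$secv, rng[["est_min"]], rng[["est_max"]]), 3),
    sep_pct = if (is.na(sp$sep)) NA_real_
              else round(percent_error(sp$sep, rng[["est_min"]], rng[["est_max"]]), 3))
}
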