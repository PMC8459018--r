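#' Modified partial least squares (MPLS)
#'
#' Single-response PLS in which, after each extracted factor, every spectral
#' residual column and the chemistry residual are divided by their standard
#' deviations before the next factor is extracted (the Shenk-Westerhaus
#' modification). The stored per-factor rescalings make predictions exactly
#' reproducible from the model state; with all rescalings forced to one the
#' algorithm reduces to standard single-y PLS.
#'
#' `mpls()` runs the full calibration pipeline: pretreatment (fit mode),
#' cross-validated factor selection, iterative T-statistic chemistry-outlier
#' elimination, and a final fit at the chosen factor count.
#'
#' @param x calibration spectra: spectrum table or matrix.
#' @param y reference values (one analyte), same length as rows of `x`.
#' @param code pretreatment code string or `pretreatment_code`.
#' @param f_max maximum factors tried in cross-validation (default
#'   `min(15, floor(N/3))`).
#' @param n_folds cross-validation folds (default 6).
#' @param t_threshold T-statistic threshold for chemistry outliers
#'   (strict `>`, default 2.5).
#' @param max_passes maximum outlier-elimination passes (default 2).
#' @param seed integer seed for the fold shuffle.
#' @return An `mpls_model` with the pretreatment code (MSC reference
#'   recorded), factor stack, chosen factor count, SECV curve, removed
#'   outlier ledger, and training statistics.
#' @export
mpls <- function(x, y, code = "None 0,0,1,1", f_max = NULL, n_folds = 6,
                 t_threshold = 2.5, max_passes = 2, seed = 1) {
  ids <- spectra_ids(x)
  stopifnot(length(y) == length(ids))
  if (sd(y) == 0) stop("zero-variance reference values", call. = FALSE)
  pre <- apply_pretreatment(x, code, mode = "fit")
  xm <- unname(spectra_matrix_or_plain(pre$spectra))
  keep <- seq_len(nrow(xm))
  removed <- tibble::tibble(id = character(0), t_value = numeric(0),
                            pass = integer(0))

  fit_once <- function(idx, pass_seed) {
    xk <- xm[idx, , drop = FALSE]; yk <- y[idx]
    fmax <- f_max %||% min(15L, floor(length(idx) / 3))
    cv <- mpls_cross_validate(xk, yk, fmax, n_folds = n_folds, seed = pass_seed)
    list(cv = cv, idx = idx)
  }

  pass <- 0L
  repeat {
    pass <- pass + 1L
    res <- fit_once(keep, seed)
    cv <- res$cv
    secv_chosen <- cv$secv_by_factor[cv$chosen_factors]
    # an (essentially) exact cross-validated fit has no chemistry outliers;
    # avoids 0/0 T ratios
    t_vals <- if (secv_chosen < 1e-10 * sd(y[keep])) rep(0, length(keep))
              else abs(y[keep] - cv$y_cv[, cv$chosen_factors]) / secv_chosen
    out <- which(t_vals > t_threshold)
    if (length(out) == 0L || pass > max_passes) break
    if (length(keep) - length(out) < 10L) {
      warning("T-outlier removal stopped: fewer than 10 samples would remain")
      break
    }
    removed <- dplyr::bind_rows(removed,
      tibble::tibble(id = ids[keep[out]], t_value = t_vals[out], pass = pass))
    keep <- keep[-out]
  }

  nf <- res$cv$chosen_factors
  stack <- fit_mpls_factors(xm[keep, , drop = FALSE], y[keep], nf)
  yhat <- predict_mpls_factors(stack, xm[keep, , drop = FALSE], nf)
  resid <- y[keep] - yhat
  model <- structure(list(
    code = pre$code,
    wavelengths = pre$wavelengths,
    stack = stack,
    n_factors = nf,
    secv_by_factor = res$cv$secv_by_factor,
    secv = res$cv$secv_by_factor[nf],
    fold_assignment = res$cv$fold_assignment,
    removed_outliers = removed,
    calibration_ids = ids[keep],
    y_cal = y[keep],
    sec = sec(resid, f = nf),
    rsq = rsq(y[keep], yhat),
    n_cal = length(keep),
    seed = as.integer(seed)),
    class = "mpls_model")
  model
}

#' @export
print.mpls_model <- function(x, ...) {
  cat(sprintf("<mpls_model> %s | %d factors | N = %d | SEC %.4g | RSQ %.3f | SECV %.4g\n",
              format(x$code), x$n_factors, x$n_cal, x$sec, x$rsq, x$secv))
  if (nrow(x$removed_outliers))
    cat("  T outliers removed:", paste(x$removed_outliers$id, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the MPLS factor stack
#'
#' Low-level single-response sequence. Per factor: weight `w` proportional
#' to `X'y` (unit norm), scores `t = X w`, x-loading `p = X't / t't`,
#' y-loading `q = y't / t't`, deflation of X and y; then the modification:
#' X residual columns and the y residual are divided by their SDs, and the
#' scalings stored so predictions can replay them. Requesting more factors
#' than the effective rank truncates with a warning.
#'
#' @param x numeric matrix (rows = samples), already pretreated.
#' @param y numeric response.
#' @param n_factors factors to extract.
#' @param modified divide residuals by their SDs after each factor
#'   (`FALSE` gives standard PLS).
#' @return A factor stack used by [predict_mpls_factors()].
#' @export
fit_mpls_factors <- function(x, y, n_factors, modified = TRUE) {
  stopifnot(nrow(x) == length(y), nrow(x) > n_factors + 1)
  x_center <- colMeans(x); y_center <- mean(y)
  xw <- sweep(x, 2, x_center); yw <- y - y_center
  nb <- ncol(x)
  w <- p <- xs <- matrix(NA_real_, nb, n_factors)
  q <- ys <- numeric(n_factors)
  actual <- 0L
  for (f in seq_len(n_factors)) {
    wf <- drop(crossprod(xw, yw))
    nw <- sqrt(sum(wf^2))
    if (nw < 1e-12 * max(1, sqrt(sum(xw^2)))) {
      warning("factor ", f, " exceeds the effective rank; truncating at ",
              f - 1L, " factor(s)")
      break
    }
    wf <- wf / nw
    tf <- drop(xw %*% wf)
    tt <- sum(tf^2)
    pf <- drop(crossprod(xw, tf)) / tt
    qf <- sum(yw * tf) / tt
    xw <- xw - tcrossprod(tf, pf)
    yw <- yw - qf * tf
    if (modified) {
      sx <- apply(xw, 2, sd)
      sx[sx < 1e-12] <- 1
      sy <- sd(yw)
      if (!is.finite(sy) || sy < 1e-12) sy <- 1
    } else {
      sx <- rep(1, nb); sy <- 1
    }
    xw <- sweep(xw, 2, sx, `/`)
    yw <- yw / sy
    w[, f] <- wf; p[, f] <- pf; q[f] <- qf
    xs[, f] <- sx; ys[f] <- sy
    actual <- f
  }
  list(x_center = x_center, y_center = y_center,
       w = w[, seq_len(actual), drop = FALSE],
       p = p[, seq_len(actual), drop = FALSE],
       q = q[seq_len(actual)],
       x_scale = xs[, seq_len(actual), drop = FALSE],
       y_scale = ys[seq_len(actual)],
       n_factors = actual)
}

#' @rdname fit_mpls_factors
#' @param stack a factor stack from `fit_mpls_factors()`.
#' @param x_new new pretreated spectra (matrix).
#' @param n_factors factors to use (default all in the stack).
#' @export
predict_mpls_factors <- function(stack, x_new, n_factors = stack$n_factors) {
  stopifnot(n_factors <= stack$n_factors)
  xw <- sweep(as.matrix(x_new), 2, stack$x_center)
  yhat <- rep(stack$y_center, nrow(xw))
  yscale_cum <- 1
  for (f in seq_len(n_factors)) {
    tf <- drop(xw %*% stack$w[, f])
    yhat <- yhat + yscale_cum * stack$q[f] * tf
    xw <- sweep(xw - tcrossprod(tf, stack$p[, f]), 2, stack$x_scale[, f], `/`)
    yscale_cum <- yscale_cum * stack$y_scale[f]
  }
  yhat
}

#' Cross-validated factor selection
#'
#' Samples are shuffled once from `seed` and cut into contiguous folds;
#' `SECV(f) = sqrt(sum_i (y_i - yhat_cv,i(f))^2 / N)` is computed for
#' `f = 1..f_max` and the factor count is the global argmin.
#'
#' @param x pretreated spectra matrix.
#' @param y response vector.
#' @param f_max maximum factors.
#' @param n_folds number of folds (`>= 2`; every fold needs `>= 2` samples).
#' @param seed integer seed for the shuffle.
#' @return A list: `secv_by_factor`, `chosen_factors`, `fold_assignment`,
#'   and `y_cv` (N x f_max matrix of cross-validated predictions).
#' @export
mpls_cross_validate <- function(x, y, f_max, n_folds = 6, seed = 1) {
  n <- nrow(x)
  stopifnot(n_folds >= 2, n >= 2 * n_folds)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  fold <- integer(n)
  fold[perm] <- cut(seq_len(n), n_folds, labels = FALSE)
  if (min(table(fold)) < 2L) stop("a fold has fewer than 2 samples", call. = FALSE)
  f_max <- min(f_max, n - max(table(fold)) - 2L)
  y_cv <- matrix(NA_real_, n, f_max)
  for (k in seq_len(n_folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    stack <- fit_mpls_factors(x[tr, , drop = FALSE], y[tr], f_max)
    for (f in seq_len(stack$n_factors))
      y_cv[te, f] <- predict_mpls_factors(stack, x[te, , drop = FALSE], f)
    if (stack$n_factors < f_max)
      for (f in (stack$n_factors + 1L):f_max) y_cv[te, f] <- y_cv[te, stack$n_factors]
  }
  secv_f <- sqrt(colMeans((y - y_cv)^2))
  list(secv_by_factor = secv_f,
       chosen_factors = which.min(secv_f),
       fold_assignment = fold,
       y_cv = y_cv)
}

#' Predict from an MPLS model
#'
#' Applies the stored pretreatment code in transform mode (reusing the MSC
#' reference recorded at fit time) and replays the factor stack.
#'
#' @param object an `mpls_model`.
#' @param newdata spectrum table or matrix on the model's original
#'   wavelength grid.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.mpls_model <- function(object, newdata, ...) {
  pre <- apply_pretreatment(newdata, object$code, mode = "transform")
  xm <- unname(spectra_matrix_or_plain(pre$spectra))
  if (ncol(xm) != length(object$stack$x_center))
    stop("newdata band support does not match the model", call. = FALSE)
  predict_mpls_factors(object$stack, xm, object$n_factors)
}

#' @export
tidy.mpls_model <- function(x, ...) {
  tibble::tibble(factor = seq_len(x$n_factors),
                 y_loading = x$stack$q,
                 y_residual_scale = x$stack$y_scale,
                 secv = x$secv_by_factor[seq_len(x$n_factors)])
}

#' @export
glance.mpls_model <- function(x, ...) {
  tibble::tibble(pretreatment = format(x$code),
                 n_cal = x$n_cal,
                 t_outliers = nrow(x$removed_outliers),
                 pls_factors = x$n_factors,
                 sec = x$sec, rsq = x$rsq, secv = x$secv)
}

#' Serialize an MPLS model to JSON
#'
#' Full-precision JSON persistence: a reloaded model gives bitwise-identical
#' predictions.
#'
#' @param model an `mpls_model`.
#' @param path output path.
#' @return `read_mpls()` returns the model.
#' @export
write_mpls <- function(model, path) {
  ser <- model
  ser$code$msc_reference <- as.numeric(ser$code$msc_reference)
  jsonlite::write_json(
    list(code = unclass(ser$code), wavelengths = ser$wavelengths,
         stack = ser$stack, n_factors = ser$n_factors,
         secv_by_factor = ser$secv_by_factor, secv = ser$secv,
         removed_outliers = ser$removed_outliers,
         calibration_ids = ser$calibration_ids, y_cal = ser$y_cal,
         sec = ser$sec, rsq = ser$rsq, n_cal = ser$n_cal, seed = ser$seed),
    path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_mpls
#' @export
read_mpls <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  code <- structure(j$code, class = "pretreatment_code")
  if (length(code$msc_reference) == 0L) code$msc_reference <- NULL
  code$scatter_ops <- as.character(code$scatter_ops %||% character(0))
  stack <- j$stack
  stack$w <- as.matrix(stack$w); stack$p <- as.matrix(stack$p)
  stack$x_scale <- as.matrix(stack$x_scale)
  structure(list(code = code, wavelengths = j$wavelengths, stack = stack,
                 n_factors = j$n_factors, secv_by_factor = j$secv_by_factor,
                 secv = j$secv,
                 removed_outliers = tibble::as_tibble(j$removed_outliers),
                 calibration_ids = j$calibration_ids, y_cal = j$y_cal,
                 sec = j$sec, rsq = j$rsq, n_cal = j$n_cal, seed = j$seed),
            class = "mpls_model")
}
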