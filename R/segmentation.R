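#' Stepwise LDA pixel classifier
#'
#' Trains a two-class (kernel vs background) linear discriminant on pixel
#' spectra with forward-stepwise band selection minimizing Wilks' lambda.
#' A band enters when its partial F reaches `f_enter` and is removed when
#' its partial F falls below `f_remove` (the classic 3.84/2.71 stepwise
#' defaults); selection stops when no band qualifies or `max_vars` is
#' reached. The Fisher discriminant is then fit on the selected bands with
#' equal priors and the decision threshold at the midpoint of the projected
#' class means.
#'
#' @param pixels numeric matrix of pixel spectra (rows = pixels), or a
#'   spectrum table.
#' @param labels factor/character/logical per pixel: `"kernel"`/`TRUE` vs
#'   `"background"`/`FALSE`.
#' @param f_enter,f_remove partial-F thresholds to enter/remove a band.
#' @param max_vars maximum number of selected bands.
#' @return An `lda_model`: selected band indices (in selection order),
#'   discriminant weights and intercept, class means, and a per-step
#'   `training_summary` tibble with Wilks' lambda and partial F.
#' @export
train_stepwise_lda <- function(pixels, labels, f_enter = 3.84, f_remove = 2.71,
                               max_vars = 30) {
  x <- if (is.matrix(pixels) && is.null(attr(pixels, "wavelengths"))) pixels
       else spectra_matrix(pixels)
  wl <- attr(x, "wavelengths")
  y <- normalize_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  n <- nrow(x)
  if (n <= max_vars) stop("need more pixels than max_vars", call. = FALSE)

  const <- apply(x, 2, function(v) var(v) < .Machine$double.eps * 100)
  if (any(const))
    warning(sum(const), " constant band(s) skipped in stepwise selection")

  # total and within scatter matrices over all bands
  xc <- scale(x, center = TRUE, scale = FALSE)
  tot <- crossprod(xc)
  wth <- matrix(0, ncol(x), ncol(x))
  for (cl in unique(y)) {
    xg <- x[y == cl, , drop = FALSE]
    wth <- wth + crossprod(scale(xg, center = TRUE, scale = FALSE))
  }
  lambda_of <- function(s) {
    if (length(s) == 0L) return(1)
    det(wth[s, s, drop = FALSE]) / det(tot[s, s, drop = FALSE])
  }

  selected <- integer(0)
  steps <- list()
  lam_cur <- 1
  candidates <- which(!const)
  repeat {
    if (length(selected) >= max_vars) break
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0L) break
    p <- length(selected)
    lam_new <- vapply(pool, function(j) lambda_of(c(selected, j)), numeric(1))
    f_part <- (n - 2 - p) * (lam_cur / lam_new - 1)
    best <- which.max(f_part)
    if (!is.finite(f_part[best]) || f_part[best] < f_enter) break
    selected <- c(selected, pool[best])
    lam_cur <- lam_new[best]
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = length(steps) + 1L, action = "enter", band = pool[best],
      wavelength = if (is.null(wl)) NA_real_ else wl[pool[best]],
      wilks = lam_cur, partial_f = f_part[best])
    # backward pass: drop bands whose partial F fell below f_remove
    repeat {
      if (length(selected) < 2L) break
      p <- length(selected)
      lam_wo <- vapply(selected, function(j) lambda_of(setdiff(selected, j)), numeric(1))
      f_rm <- (n - 2 - (p - 1)) * (lam_wo / lam_cur - 1)
      worst <- which.min(f_rm)
      if (f_rm[worst] >= f_remove) break
      dropped <- selected[worst]
      selected <- setdiff(selected, dropped)
      lam_cur <- lambda_of(selected)
      steps[[length(steps) + 1L]] <- tibble::tibble(
        step = length(steps) + 1L, action = "remove", band = dropped,
        wavelength = if (is.null(wl)) NA_real_ else wl[dropped],
        wilks = lam_cur, partial_f = f_rm[worst])
    }
  }
  if (length(selected) == 0L)
    stop("no band reached the F-to-enter threshold", call. = FALSE)

  xs <- x[, selected, drop = FALSE]
  m_k <- colMeans(xs[y == "kernel", , drop = FALSE])
  m_b <- colMeans(xs[y == "background", , drop = FALSE])
  sw <- wth[selected, selected, drop = FALSE] / (n - 2)
  w <- solve(sw, m_k - m_b)
  b <- -sum(w * (m_k + m_b) / 2)
  structure(list(selected_band_indices = selected,
                 wavelengths = if (is.null(wl)) NULL else wl[selected],
                 weights = w, intercept = b,
                 class_means = list(kernel = m_k, background = m_b),
                 training_summary = dplyr::bind_rows(steps)),
            class = "lda_model")
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(ifelse(labels, "kernel", "background"))
  lab <- tolower(as.character(labels))
  if (!all(lab %in% c("kernel", "background")))
    stop("labels must be kernel/background (or logical)", call. = FALSE)
  lab
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d selected band(s)", length(x$selected_band_indices)))
  if (!is.null(x$wavelengths))
    cat(":", paste(format(x$wavelengths), collapse = ", "), "nm")
  cat("\n")
  invisible(x)
}

lda_scores <- function(model, x) {
  drop(x[, model$selected_band_indices, drop = FALSE] %*% model$weights) + model$intercept
}

#' Classify cube pixels with a trained LDA model
#'
#' @param model an `lda_model` from [train_stepwise_lda()].
#' @param cube a `hypercube` at stage `"absorbance"` sharing the model's
#'   band grid.
#' @return An integer matrix (`lines x pixels`): 1 = kernel, 0 = background.
#' @export
classify_pixels <- function(model, cube) {
  stopifnot(inherits(model, "lda_model"), inherits(cube, "hypercube"))
  if (!is.null(model$wavelengths)) {
    have <- cube$wavelengths[model$selected_band_indices]
    if (length(cube$wavelengths) < max(model$selected_band_indices) ||
        max(abs(have - model$wavelengths)) > 1e-6)
      stop("cube band grid does not carry the model's selected bands", call. = FALSE)
  }
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])   # pixel-major (line fastest)
  sc <- lda_scores(model, flat)
  matrix(as.integer(sc > 0), d[1], d[2])
}

#' Extract kernel objects from a segmentation mask
#'
#' Labels 4-connected components of kernel pixels, drops components smaller
#' than `min_area` (classifier speckle), and assigns ids in reading order of
#' component centroids (top-to-bottom, then left-to-right).
#'
#' @param mask integer/logical matrix from [classify_pixels()].
#' @param min_area minimum component area in pixels.
#' @return A tibble with `kernel_id`, `area`, `centroid_line`,
#'   `centroid_pixel` and a `pixels` list-column of `(line, pixel)` index
#'   matrices.
#' @export
extract_objects <- function(mask, min_area = 50) {
  lab <- label_components4(mask > 0)
  if (max(lab) == 0L)
    return(tibble::tibble(kernel_id = integer(0), area = integer(0),
                          centroid_line = numeric(0), centroid_pixel = numeric(0),
                          pixels = list()))
  comps <- lapply(seq_len(max(lab)), function(i) which(lab == i, arr.ind = TRUE))
  comps <- comps[vapply(comps, nrow, integer(1)) >= min_area]
  if (length(comps) == 0L) return(extract_objects(matrix(0L, 1, 1), min_area))
  cents <- t(vapply(comps, colMeans, numeric(2)))
  ord <- order(cents[, 1], cents[, 2])
  tibble::tibble(
    kernel_id = seq_along(ord),
    area = vapply(comps[ord], nrow, integer(1)),
    centroid_line = cents[ord, 1], centroid_pixel = cents[ord, 2],
    pixels = comps[ord])
}

# 4-connected component labelling by flood fill
label_components4 <- function(bin) {
  nl <- nrow(bin); np <- ncol(bin)
  lab <- matrix(0L, nl, np)
  nxt <- 0L
  idx <- which(bin)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      for (p in cur) {
        l <- ((p - 1L) %% nl) + 1L
        c <- ((p - 1L) %/% nl) + 1L
        nb <- c(if (l > 1L) p - 1L, if (l < nl) p + 1L,
                if (c > 1L) p - nl, if (c < np) p + nl)
        nb <- nb[bin[nb] & lab[nb] == 0L]
        lab[nb] <- nxt
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Per-kernel mean spectra
#'
#' `mean_spectrum()` averages one ROI's pixel spectra; `roi_mean_spectra()`
#' builds the full spectrum table for a set of extracted objects.
#'
#' @param cube a `hypercube` at stage `"absorbance"`.
#' @param roi one row of the [extract_objects()] tibble (a list with a
#'   `pixels` matrix), or the pixel index matrix itself.
#' @return `mean_spectrum()` a numeric vector (one value per band);
#'   `roi_mean_spectra()` a spectrum table with `id` and `area` columns.
#' @export
mean_spectrum <- function(cube, roi) {
  px <- if (is.matrix(roi)) roi else roi$pixels[[1]]
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  lin <- (px[, 2] - 1L) * d[1] + px[, 1]
  colMeans(flat[lin, , drop = FALSE])
}

#' @rdname mean_spectrum
#' @param rois the tibble from [extract_objects()].
#' @param ids optional character ids (default `kernel_id`).
#' @export
roi_mean_spectra <- function(cube, rois, ids = NULL) {
  m <- t(vapply(rois$pixels, function(px) mean_spectrum(cube, px),
                numeric(length(cube$wavelengths))))
  spectra_table(m, cube$wavelengths,
                id = ids %||% as.character(rois$kernel_id), area = rois$area)
}

#' Merge the two rotated acquisitions of one scene
#'
#' Per-kernel spectra from the two 180-degree-rotated acquisitions are
#' averaged according to a pairing; the merged table is keyed by the ids of
#' acquisition A.
#'
#' @param spectra_a,spectra_b spectrum tables for acquisitions A and B.
#' @param pairing tibble with columns `id_a`, `id_b` (a bijection).
#' @return A spectrum table with A's ids and the element-wise mean spectra.
#' @export
merge_acquisitions <- function(spectra_a, spectra_b, pairing) {
  ma <- spectra_matrix(spectra_a); mb <- spectra_matrix(spectra_b)
  ida <- spectra_ids(spectra_a); idb <- spectra_ids(spectra_b)
  pa <- as.character(pairing$id_a); pb <- as.character(pairing$id_b)
  if (anyDuplicated(pa) || anyDuplicated(pb) || length(pa) != length(pb))
    stop("pairing must be a bijection", call. = FALSE)
  un_a <- setdiff(ida, pa); un_b <- setdiff(idb, pb)
  miss <- c(setdiff(pa, ida), setdiff(pb, idb))
  if (length(un_a) || length(un_b) || length(miss))
    stop("unpaired kernel id(s): ",
         paste(unique(c(un_a, un_b, miss)), collapse = ", "), call. = FALSE)
  merged <- (ma[match(pa, ida), , drop = FALSE] +
             mb[match(pb, idb), , drop = FALSE]) / 2
  tbl <- spectra_table(merged, spectra_wavelengths(spectra_a), id = pa)
  if (is.data.frame(spectra_a) && "variety" %in% names(spectra_a))
    tbl <- dplyr::mutate(tbl,
      variety = spectra_a$variety[match(pa, ida)], .after = "id")
  tbl
}

#' Pair kernels across rotated acquisitions by geometry
#'
#' When no ground-truth pairing is available, kernels of acquisition B are
#' matched to those of A by nearest neighbour between A's centroids and B's
#' centroids reflected through the scene centre (the 180-degree rotation).
#'
#' @param rois_a,rois_b [extract_objects()] tibbles for the two acquisitions.
#' @param dims scene size `c(lines, pixels)`.
#' @return A tibble `id_a`, `id_b`.
#' @export
pair_rotated_acquisitions <- function(rois_a, rois_b, dims) {
  stopifnot(nrow(rois_a) == nrow(rois_b))
  rb_l <- dims[1] + 1 - rois_b$centroid_line
  rb_p <- dims[2] + 1 - rois_b$centroid_pixel
  used <- logical(nrow(rois_b)); id_b <- integer(nrow(rois_a))
  for (i in seq_len(nrow(rois_a))) {
    d2 <- (rois_a$centroid_line[i] - rb_l)^2 + (rois_a$centroid_pixel[i] - rb_p)^2
    d2[used] <- Inf
    j <- which.min(d2)
    used[j] <- TRUE
    id_b[i] <- rois_b$kernel_id[j]
  }
  tibble::tibble(id_a = rois_a$kernel_id, id_b = id_b)
}
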