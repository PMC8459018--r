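# shared fixtures: coarse band grids and small scenes keep the imaging
# suites fast while exercising the full chain

coarse_grid <- function() seq(950, 1650, by = 25)

coarse_signatures <- function() default_signature_set(coarse_grid())

# a signature set whose components separate on exactly three bands, for
# band-selection checks
three_band_signatures <- function(grid = coarse_grid()) {
  gauss <- function(c0, w, h) h * exp(-0.5 * ((grid - c0) / w)^2)
  signature_set(grid, list(
    fat = gauss(1225, 12, 0.6),
    sfa = gauss(1475, 12, 0.7),
    mufa = gauss(1225, 12, 0.5),
    pufa = gauss(1600, 12, 0.5),
    moisture = gauss(1475, 12, 0.3)))
}

small_panel <- function(n_per_variety = 2, seed = 1) {
  generate_reference_panel(n_per_variety = n_per_variety, seed = seed)
}

small_scene <- function(seed = 1, n_kernels = 10, noise = noise_config(),
                        signatures = coarse_signatures()) {
  panel <- small_panel(2, seed)[seq_len(n_kernels), ]
  generate_scene(panel, signatures, noise, seed = seed,
                 dims = c(140, 120), kernel_area = c(60, 120))
}

scene_absorbance <- function(acq) {
  to_absorbance(calibrate_reflectance(
    acq$raw, calibration_frames(acq$dark, acq$white)))
}

# sample labelled pixels from a scene's ground truth
scene_pixels <- function(acq, cube, n_per_class = 400, seed = 1) {
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  attr(flat, "wavelengths") <- cube$wavelengths
  is_kernel <- as.vector(acq$truth$mask > 0)
  set.seed(seed)
  pick <- c(sample(which(is_kernel), n_per_class),
            sample(which(!is_kernel), n_per_class))
  px <- flat[pick, , drop = FALSE]
  attr(px, "wavelengths") <- cube$wavelengths
  list(pixels = px, labels = is_kernel[pick])
}

# independent single-response PLS oracle: plain NIPALS-style loop written
# directly from the textbook recursion, no shared code with the package
naive_pls <- function(x, y, n_factors) {
  x0 <- scale(x, center = TRUE, scale = FALSE)
  y0 <- y - mean(y)
  ws <- list(); ps <- list(); qs <- numeric(0)
  for (f in seq_len(n_factors)) {
    w <- crossprod(x0, y0)
    w <- w / sqrt(sum(w^2))
    t <- x0 %*% w
    p <- crossprod(x0, t) / drop(crossprod(t))
    q <- drop(crossprod(y0, t)) / drop(crossprod(t))
    x0 <- x0 - t %*% t(p)
    y0 <- y0 - q * t
    ws[[f]] <- w; ps[[f]] <- p; qs[f] <- q
  }
  list(ws = ws, ps = ps, qs = qs,
       x_mean = colMeans(x), y_mean = mean(y))
}

naive_pls_predict <- function(fit, x_new) {
  xw <- sweep(as.matrix(x_new), 2, fit$x_mean)
  yhat <- rep(fit$y_mean, nrow(xw))
  for (f in seq_along(fit$qs)) {
    t <- xw %*% fit$ws[[f]]
    yhat <- yhat + fit$qs[f] * drop(t)
    xw <- xw - t %*% t(fit$ps[[f]])
  }
  yhat
}

# Table-of-variety-means composition fixture: one row per variety holding
# the reference means. With include_families the reported family-total rows
# are used; otherwise the families are recomputed from the (rounded) acid
# means via family_sums()
reference_means_table <- function(include_families = TRUE) {
  ref <- walnut_composition_reference()
  if (!include_families) ref <- ref[!ref$analyte %in% c("SFA", "MUFA", "PUFA"), ]
  wide <- tidyr::pivot_wider(ref[c("variety", "analyte", "mean")],
                             names_from = "analyte", values_from = "mean")
  if (!include_families) wide <- family_sums(wide)
  wide
}
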