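test_that("stepwise selection finds the single informative band", {
  set.seed(11)
  n <- 120; b <- 51; informative <- 17
  x <- matrix(rnorm(n * b), n, b)
  y <- rep(c("kernel", "background"), each = n / 2)
  x[y == "kernel", informative] <- x[y == "kernel", informative] + 4
  model <- train_stepwise_lda(x, y)
  # exhaustive single-band F-scan oracle
  f_scan <- vapply(seq_len(b), function(j) {
    summary(aov(x[, j] ~ factor(y)))[[1]][["F value"]][1]
  }, numeric(1))
  expect_equal(which.max(f_scan), informative)
  expect_equal(model$selected_band_indices[1], informative)
  expect_identical(model$training_summary$action[1], "enter")
})

test_that("shuffled labels rarely admit any band", {
  set.seed(22)
  n <- 60; b <- 20
  x <- matrix(rnorm(n * b), n, b)
  # at the multiplicity-corrected entry threshold (family-wise 5% over the
  # b candidate partial-F scans) a label permutation should admit no band
  # in at least 95% of trials
  f_bonf <- qf(1 - 0.05 / b, 1, n - 2)
  admitted <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    y <- sample(rep(c("kernel", "background"), each = n / 2))
    !inherits(try(train_stepwise_lda(x, y, f_enter = f_bonf), silent = TRUE),
              "try-error")
  }, logical(1))
  expect_lte(mean(admitted), 0.05)
  # at the classic 3.84 default the per-band false-entry rate stays near
  # its nominal 5%: admissions happen but select at most a couple of bands
  set.seed(31)
  y <- sample(rep(c("kernel", "background"), each = n / 2))
  fit <- try(train_stepwise_lda(x, y), silent = TRUE)
  if (!inherits(fit, "try-error"))
    expect_lte(length(fit$selected_band_indices), 4)
})

test_that("linearly separable pixels are classified perfectly", {
  set.seed(33)
  n <- 100
  x <- matrix(rnorm(n * 10, sd = 0.1), n, 10)
  y <- rep(c("kernel", "background"), each = n / 2)
  x[y == "kernel", 3] <- x[y == "kernel", 3] + 5
  model <- train_stepwise_lda(x, y)
  sc <- walnutnir:::lda_scores(model, x)
  pred <- ifelse(sc > 0, "kernel", "background")
  expect_identical(pred, y)
  expect_error(train_stepwise_lda(x, rep("kernel", n)), "both classes")
})

test_that("scene segmentation is pixel-accurate and counts kernels exactly", {
  sc <- small_scene(seed = 5)
  cube <- scene_absorbance(sc$a)
  px <- scene_pixels(sc$a, cube, seed = 5)
  model <- train_stepwise_lda(px$pixels, px$labels)
  mask <- classify_pixels(model, cube)
  truth <- sc$a$truth$mask > 0
  expect_gte(mean((mask > 0) == truth), 0.99)
  rois <- extract_objects(mask)
  expect_equal(nrow(rois), 10)
  # the model applied back to its own training pixels reproduces the
  # training predictions embedded in the mask
  tr_pred <- walnutnir:::lda_scores(model, px$pixels) > 0
  expect_gte(mean(tr_pred == px$labels), 0.99)
  # all-background scene
  empty <- hypercube(cube$data[1:20, 1:20, , drop = FALSE] * 0 +
                       rep(log10(1 / 0.85), each = 400), cube$wavelengths,
                     "absorbance")
  expect_true(all(classify_pixels(model, empty) == 0))
})

test_that("connected components use 4-connectivity and drop speckle", {
  m <- matrix(0L, 8, 8)
  m[2:3, 2:3] <- 1L   # block A
  m[4:5, 4:5] <- 1L   # block B touches A only diagonally
  rois <- extract_objects(m, min_area = 2)
  expect_equal(nrow(rois), 2)
  m2 <- m; m2[8, 8] <- 1L  # single-pixel speckle
  rois2 <- extract_objects(m2, min_area = 2)
  expect_equal(nrow(rois2), 2)
  expect_equal(nrow(extract_objects(matrix(0L, 4, 4))), 0)
})

test_that("ROI ids follow reading order of centroids", {
  m <- matrix(0L, 10, 10)
  m[7:9, 1:3] <- 1L   # lower-left
  m[1:3, 6:8] <- 1L   # upper-right
  rois <- extract_objects(m, min_area = 4)
  expect_equal(rois$centroid_line, c(2, 8))
})

test_that("mean spectra and acquisition merging behave on known inputs", {
  sc <- small_scene(seed = 9, noise = noise_off())
  cube_a <- scene_absorbance(sc$a)
  cube_b <- scene_absorbance(sc$b)
  rois_a <- extract_objects(sc$a$truth$mask)
  rois_b <- extract_objects(sc$b$truth$mask)
  spa <- roi_mean_spectra(cube_a, rois_a)
  spb <- roi_mean_spectra(cube_b, rois_b)
  # identical pixels -> that pixel's spectrum
  one_px <- sc$a$truth$mask == 1
  idx <- which(one_px, arr.ind = TRUE)
  expect_equal(mean_spectrum(cube_a, idx[1, , drop = FALSE]),
               cube_a$data[idx[1, 1], idx[1, 2], ], tolerance = 1e-12)
  # A = B -> merge is the identity
  same <- merge_acquisitions(spa, spa,
                             tibble::tibble(id_a = spa$id, id_b = spa$id))
  expect_equal(spectra_matrix(same), spectra_matrix(spa), tolerance = 0,
               ignore_attr = TRUE)
  # noise off: merged spectrum equals the generator's Beer-Lambert truth
  merged <- merge_acquisitions(spa, spb, sc$pairing)
  panel <- small_panel(2, 9)[1:10, ]
  truth <- render_absorbance(walnutnir:::composition_components(panel),
                             coarse_signatures())
  comp <- sc$a$truth$compositions
  for (i in seq_len(nrow(merged))) {
    k <- as.integer(merged$id[i])
    row <- match(comp$sample_id[match(k, comp$kernel_id)], panel$sample_id)
    expect_equal(unname(spectra_matrix(merged)[i, ]), unname(truth[row, ]),
                 tolerance = 1e-8)
  }
  # unpaired kernels are reported
  expect_error(merge_acquisitions(spa, spb, sc$pairing[-1, ]), "unpaired")
})

test_that("geometric pairing recovers the truth pairing on rotated scenes", {
  sc <- small_scene(seed = 13)
  rois_a <- extract_objects(sc$a$truth$mask)
  rois_b <- extract_objects(sc$b$truth$mask)
  got <- pair_rotated_acquisitions(rois_a, rois_b, dims = c(140, 120))
  truth <- dplyr::arrange(sc$pairing, id_a)
  expect_equal(got$id_b, truth$id_b)
})
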