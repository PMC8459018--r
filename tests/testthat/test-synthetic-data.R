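test_that("variety profiles satisfy the composition invariants", {
  profs <- walnut_variety_profiles()
  expect_named(profs, c("Chandler", "Franquette", "Howard", "Lara", "Tulare"))
  for (p in profs) {
    expect_true(all(p$fa_means >= 0))
    expect_true(all(p$fa_ses >= 0))
    s <- sum(p$fa_means)
    expect_gte(s, 95); expect_lte(s, 105)
  }
})

test_that("zero-SE profiles reproduce the variety family totals up to renormalization", {
  profs <- walnut_variety_profiles()
  profs <- lapply(profs, function(p) {
    p$fa_ses[] <- 0; p$se_total_fat <- 0; p
  })
  panel <- generate_reference_panel(profs, n_per_variety = 1, seed = 1)
  fr <- panel[panel$variety == "Franquette", ]
  raw_sum <- sum(walnut_variety_profiles()$Franquette$fa_means)
  expect_equal(fr$MUFA, 16.79 * 100 / raw_sum, tolerance = 1e-10)
  expect_equal(fr$PUFA, 73.03 * 100 / raw_sum, tolerance = 1e-10)
  # the ratio is invariant under the renormalization
  expect_equal(fr$MUFA / fr$PUFA, 16.79 / 73.03, tolerance = 1e-12)
})

test_that("panel generation rejects degenerate inputs", {
  expect_error(generate_reference_panel(list(), 5, seed = 1), "empty")
  expect_error(generate_reference_panel(n_per_variety = 0, seed = 1), ">= 1")
})

test_that("generated acid vectors sum to 100 exactly", {
  panel <- generate_reference_panel(n_per_variety = 20, seed = 4)
  sums <- rowSums(as.matrix(panel[fatty_acid_families()$acid]))
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(as.matrix(panel[fatty_acid_families()$acid]) >= 0))
})

test_that("per-variety sample means agree with a direct Monte-Carlo oracle", {
  panel <- generate_reference_panel(n_per_variety = 33, seed = 1)
  profs <- walnut_variety_profiles()
  fam <- fatty_acid_families()
  # independent oracle: re-draw the generator's model directly at large n
  set.seed(99)
  for (v in names(profs)) {
    p <- profs[[v]]
    sds <- sqrt(p$n_ref) * p$fa_ses
    draws <- matrix(rnorm(10000 * 16, rep(p$fa_means, each = 10000),
                          rep(sds, each = 10000)), nrow = 10000)
    draws[draws < 0] <- 0
    draws <- 100 * draws / rowSums(draws)
    mc_mean <- colMeans(draws)
    mc_se33 <- apply(draws, 2, sd) / sqrt(33)
    got <- colMeans(as.matrix(panel[panel$variety == v, fam$acid]))
    tol <- pmax(3 * mc_se33, 1e-8)
    expect_true(all(abs(got - mc_mean) <= tol),
                info = paste("variety", v))
  }
})

test_that("generator spread matches the targeted standard errors", {
  # n_ref = 20: the per-sample SD is sqrt(20)*SE, so the SE of a 20-kernel
  # sample mean should recover the input SE (checked where truncation and
  # renormalization are negligible: mean > 3 draw-SDs)
  profs <- walnut_variety_profiles(n_ref = 20)
  panel <- generate_reference_panel(profs, n_per_variety = 2000, seed = 2)
  for (v in c("Chandler", "Lara")) {
    p <- profs[[v]]
    sds <- sqrt(20) * p$fa_ses
    # total fat is not renormalized: its implied SE must hit the target
    fat_se <- sd(panel$total_fat[panel$variety == v]) / sqrt(20)
    expect_lt(abs(fat_se / p$se_total_fat - 1), 0.10)
    # acids pass through the closure to 100%, which shrinks the spread of
    # the large acids; the target after closure comes from an independent
    # Monte-Carlo of the same generative model
    set.seed(123)
    draws <- matrix(rnorm(10000 * 16, rep(p$fa_means, each = 10000),
                          rep(sds, each = 10000)), nrow = 10000)
    draws[draws < 0] <- 0
    draws <- 100 * draws / rowSums(draws)
    target_se20 <- apply(draws, 2, sd) / sqrt(20)
    testable <- p$fa_means > 3 * sds & sds > 0
    expect_gt(sum(testable), 2)
    got_se20 <- apply(as.matrix(panel[panel$variety == v,
                                      names(p$fa_means)[testable]]), 2, sd) / sqrt(20)
    expect_true(all(abs(got_se20 / target_se20[testable] - 1) < 0.10),
                info = paste("variety", v))
    # and where the closure correction is small the raw SE target itself
    # is met
    small_share <- testable & p$fa_means < 5
    expect_true(all(abs(got_se20[names(p$fa_means)[small_share]] /
                          p$fa_ses[small_share] - 1) < 0.10),
                info = paste("variety", v, "(raw targets)"))
  }
})

test_that("scene encoding is exactly invertible when noise is off", {
  sc <- small_scene(seed = 3, noise = noise_off())
  cube <- calibrate_reflectance(sc$a$raw, calibration_frames(sc$a$dark, sc$a$white))
  panel <- small_panel(2, 3)[1:10, ]
  sigs <- coarse_signatures()
  a_true <- render_absorbance(walnutnir:::composition_components(panel), sigs)
  ab <- to_absorbance(cube)
  for (k in c(1, 5, 10)) {
    px <- which(sc$a$truth$mask == k, arr.ind = TRUE)[1, ]
    got <- ab$data[px[1], px[2], ]
    i <- match(k, sc$a$truth$compositions$kernel_id)
    row <- match(sc$a$truth$compositions$sample_id[i], panel$sample_id)
    expect_equal(unname(got), unname(a_true[row, ]), tolerance = 1e-10)
  }
  # background pixel: flat reflectance
  bg <- which(sc$a$truth$mask == 0, arr.ind = TRUE)[1, ]
  expect_equal(unname(cube$data[bg[1], bg[2], ]),
               rep(0.85, length(cube$wavelengths)), tolerance = 1e-10)
})

test_that("zero composition encodes zero absorbance and unit reflectance", {
  sigs <- coarse_signatures()
  conc <- matrix(0, 1, 5,
                 dimnames = list(NULL, c("fat", "sfa", "mufa", "pufa", "moisture")))
  a <- render_absorbance(conc, sigs)
  expect_true(all(a == 0))
  expect_true(all(10^-a == 1))
})

test_that("noisy kernel spectra correlate with their noiseless rendering", {
  sc_noisy <- small_scene(seed = 7, noise = noise_config())
  sc_clean <- small_scene(seed = 7, noise = noise_off())
  cube_n <- scene_absorbance(sc_noisy$a)
  cube_c <- scene_absorbance(sc_clean$a)
  for (k in 1:10) {
    px <- which(sc_noisy$a$truth$mask == k, arr.ind = TRUE)
    mn <- mean_spectrum(cube_n, px)
    mc <- mean_spectrum(cube_c, px)
    expect_gt(cor(mn, mc), 0.99)
  }
})

test_that("scene generation enforces its preconditions", {
  panel <- small_panel(3, 1)
  expect_error(generate_scene(panel[1:11, ], coarse_signatures()), "at most 10")
  bad_sigs <- signature_set(coarse_grid(),
                            list(fat = rep(1, length(coarse_grid()))))
  expect_error(generate_scene(panel[1:2, ], bad_sigs), "no signature")
})
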