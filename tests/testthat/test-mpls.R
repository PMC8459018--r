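linear_truth <- function(n = 40, b = 25, k = 3, noise = 0, seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n * k), n, k)
  load <- matrix(rnorm(b * k), b, k)
  x <- scores %*% t(load)
  beta <- rnorm(k)
  y <- drop(scores %*% beta) + rnorm(n, sd = noise)
  attr(x, "wavelengths") <- seq_len(b)
  list(x = x, y = y, k = k)
}

test_that("noiseless linear truth is recovered exactly at the true rank", {
  d <- linear_truth()
  stack <- fit_mpls_factors(d$x, d$y, d$k)
  yhat <- predict_mpls_factors(stack, d$x)
  expect_lt(sqrt(sum((d$y - yhat)^2)) / sqrt(sum(d$y^2)), 1e-8)
})

test_that("with unit residual scaling MPLS equals the independent PLS oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:50) {
    n <- sample(12:30, 1); b <- sample(5:40, 1)
    f <- sample(1:min(6, n - 2, b), 1)
    x <- matrix(rnorm(n * b), n, b)
    y <- rnorm(n)
    stack <- fit_mpls_factors(x, y, f, modified = FALSE)
    oracle <- naive_pls(x, y, f)
    x_new <- matrix(rnorm(8 * b), 8, b)
    delta <- max(abs(predict_mpls_factors(stack, x_new) -
                     naive_pls_predict(oracle, x_new)))
    worst <- max(worst, delta)
  }
  expect_lt(worst, 1e-8)
})

test_that("factor 1 of MPLS coincides with standard PLS (scaling starts after)", {
  d <- linear_truth(noise = 0.2, seed = 3)
  mod <- fit_mpls_factors(d$x, d$y, 4, modified = TRUE)
  std <- naive_pls(d$x, d$y, 1)
  expect_equal(unname(mod$w[, 1]), unname(drop(std$ws[[1]])), tolerance = 1e-12)
  expect_equal(mod$q[1], std$qs[1], tolerance = 1e-12)
  x_new <- d$x[1:5, , drop = FALSE]
  expect_equal(predict_mpls_factors(mod, x_new, 1),
               naive_pls_predict(std, x_new), tolerance = 1e-10)
})

test_that("training SEC is non-increasing in the factor count", {
  d <- linear_truth(n = 35, b = 20, k = 5, noise = 0.5, seed = 9)
  stack <- fit_mpls_factors(d$x, d$y, 8)
  sse <- vapply(seq_len(stack$n_factors), function(f)
    sum((d$y - predict_mpls_factors(stack, d$x, f))^2), numeric(1))
  expect_true(all(diff(sse) <= 1e-10))
})

test_that("requesting factors beyond the rank truncates with a warning", {
  d <- linear_truth(n = 20, b = 10, k = 2)
  expect_warning(stack <- fit_mpls_factors(d$x, d$y, 8), "rank")
  expect_lte(stack$n_factors, 3)
})

test_that("cross-validation selects close to the true dimensionality", {
  hits <- vapply(1:10, function(s) {
    d <- linear_truth(n = 48, b = 20, k = 3, noise = 1e-6, seed = 100 + s)
    cv <- mpls_cross_validate(d$x, d$y, f_max = 8, n_folds = 6, seed = s)
    cv$chosen_factors
  }, numeric(1))
  expect_true(all(abs(hits - 3) <= 1))
})

test_that("cross-validation does not manufacture signal from pure noise", {
  set.seed(77)
  x <- matrix(rnorm(48 * 20), 48, 20)
  y <- rnorm(48)
  cv <- mpls_cross_validate(x, y, f_max = 8, n_folds = 6, seed = 1)
  # no SECV below the spread of y itself (population SD)
  expect_gte(min(cv$secv_by_factor), sqrt(mean((y - mean(y))^2)) * 0.95)
})

test_that("folds partition the samples into equal contiguous blocks", {
  x <- matrix(rnorm(12 * 6), 12, 6)
  y <- rnorm(12)
  cv <- mpls_cross_validate(x, y, f_max = 2, n_folds = 6, seed = 4)
  expect_identical(unname(as.vector(table(cv$fold_assignment))), rep(2L, 6))
  expect_error(mpls_cross_validate(x, y, 2, n_folds = 7), "2")
})

test_that("T-statistic elimination removes exactly the planted outlier", {
  d <- linear_truth(n = 40, b = 15, k = 2, noise = 0.1, seed = 5)
  y_bad <- d$y
  y_bad[17] <- y_bad[17] + 30   # many SECVs away
  ids <- paste0("s", 1:40)
  xm <- d$x; rownames(xm) <- ids
  model <- mpls(xm, y_bad, code = "None 0,0,1,1", f_max = 4, seed = 2)
  hit <- model$removed_outliers[model$removed_outliers$id == "s17", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$pass, 1L)
  expect_gt(hit$t_value, 2.5)
  # with (numerically) zero cross-validated residuals nothing is removed
  d0 <- linear_truth(n = 40, b = 15, k = 2, noise = 0, seed = 5)
  clean <- mpls(d0$x, d0$y, code = "None 0,0,1,1", f_max = 4, seed = 2)
  expect_equal(nrow(clean$removed_outliers), 0)
})

test_that("full fit on noiseless data reproduces training responses", {
  d <- linear_truth(n = 36, b = 18, k = 3, noise = 0, seed = 8)
  model <- mpls(d$x, d$y, code = "None 0,0,1,1", f_max = 6, seed = 1)
  yhat <- predict(model, d$x)
  expect_gt(rsq(d$y[match(model$calibration_ids, spectra_ids(d$x))],
                yhat[match(model$calibration_ids, spectra_ids(d$x))]), 1 - 1e-8)
})

test_that("serialized models reload to bitwise-identical predictions", {
  panel <- small_panel(6, seed = 31)
  spec <- simulate_kernel_spectra(panel, coarse_signatures(), seed = 31)
  model <- mpls(spec, panel$total_fat, code = "MSC 1,5,5,1", f_max = 6, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_mpls(model, path)
  back <- read_mpls(path)
  p1 <- predict(model, spec)
  p2 <- predict(back, spec)
  expect_identical(p1, p2)
  expect_identical(format(back$code), format(model$code))
})

test_that("tidy and glance summarize the fitted model", {
  d <- linear_truth(n = 30, b = 12, k = 2, noise = 0.2, seed = 6)
  model <- mpls(d$x, d$y, code = "None 0,0,1,1", f_max = 4, seed = 1)
  td <- tidy(model)
  expect_identical(nrow(td), model$n_factors)
  gl <- glance(model)
  expect_identical(gl$pls_factors, model$n_factors)
  expect_identical(gl$pretreatment, "None 0,0,1,1")
  expect_lt(abs(gl$secv - model$secv), 1e-15)
})

test_that("external validation recovers the synthetic composition signal", {
  panel <- generate_reference_panel(n_per_variety = 33, seed = 3)
  spec <- simulate_kernel_spectra(panel, noise = noise_config(), seed = 3)
  panel <- add_reference_noise(panel, noise_config(), seed = 3)
  cal <- seq_len(110); val <- 111:165
  model <- mpls(spec[cal, ], panel$total_fat[cal], code = "SNV 2,5,5,1",
                n_folds = 6, seed = 3)
  yhat <- predict(model, spec[val, ])
  expect_gt(rsq(panel$total_fat[val], yhat), 0.9)
  sp <- sep(panel$total_fat[val], yhat)
  expect_lte(sp$sep, 2 * noise_config()$reference_sd)
})
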