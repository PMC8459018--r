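rand_spectra <- function(n = 6, b = 40, seed = 1) {
  set.seed(seed)
  wl <- seq(1000, by = 5, length.out = b)
  x <- matrix(rnorm(n * b), n, b) + outer(rep(1, n), sin(wl / 50))
  attr(x, "wavelengths") <- wl
  x
}

test_that("SNV standardizes each spectrum and is affine-invariant", {
  x <- rand_spectra()
  out <- snv(x)
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_true(all(abs(apply(out, 1, sd) - 1) < 1e-12))
  shifted <- 3.2 * x + 7.5
  attr(shifted, "wavelengths") <- attr(x, "wavelengths")
  expect_equal(snv(shifted), out, tolerance = 1e-12)
  flat <- x; flat[2, ] <- 5
  expect_error(snv(flat), "zero-variance")
})

test_that("detrend removes its polynomial exactly and leaves orthogonal residuals", {
  wl <- seq(950, 1650, length.out = 50)
  quad <- outer(c(1, -2, 0.5), rep(1, 50)) * 1e-4 * rbind(wl^2, wl^2, wl^2) +
    outer(c(0.3, 1, -1), wl / 1000) + 2
  attr(quad, "wavelengths") <- wl
  expect_true(all(abs(detrend(quad)) < 1e-6 * max(abs(quad))))

  x <- rand_spectra(b = 50)
  attr(x, "wavelengths") <- wl
  out <- detrend(x)
  basis <- cbind(1, wl, wl^2)
  gram <- abs(out %*% basis) / nrow(basis)
  expect_true(all(gram < 1e-6))

  # quadratic + Gaussian band: residual equals the band minus its explicit
  # least-squares quadratic projection
  band <- exp(-0.5 * ((wl - 1300) / 40)^2)
  spec <- matrix(1e-4 * wl^2 - 0.1 * wl + 3 + band, 1)
  attr(spec, "wavelengths") <- wl
  fit <- lm(band ~ wl + I(wl^2))
  expect_equal(drop(detrend(spec)), unname(residuals(fit)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("MSC inverts affine scatter against the reference", {
  x <- rand_spectra()
  ref <- colMeans(x)
  distorted <- 2 * matrix(ref, nrow = 4, ncol = ncol(x), byrow = TRUE) + 3
  attr(distorted, "wavelengths") <- attr(x, "wavelengths")
  out <- msc(distorted, ref)
  expect_equal(out, matrix(ref, 4, ncol(x), byrow = TRUE),
               tolerance = 1e-10, ignore_attr = TRUE)
  self <- matrix(ref, 1); attr(self, "wavelengths") <- attr(x, "wavelengths")
  expect_equal(drop(msc(self, ref)), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
  # regression oracle: each corrected spectrum regressed on ref has
  # intercept 0, slope 1
  corr <- msc(x, ref)
  for (i in seq_len(nrow(corr))) {
    cf <- coef(lm(corr[i, ] ~ ref))
    expect_equal(unname(cf), c(0, 1), tolerance = 1e-9)
  }
})

test_that("gap-segment derivatives annihilate constants and linears", {
  wl <- seq(1000, by = 5, length.out = 60)
  const <- matrix(4, 2, 60); attr(const, "wavelengths") <- wl
  lin <- rbind(wl * 0.01, wl * -0.02 + 3); attr(lin, "wavelengths") <- wl
  for (par in list(c(1, 2, 1, 1), c(1, 5, 5, 1), c(2, 5, 5, 1))) {
    out <- gap_segment_derivative(const, par[1], par[2], par[3], par[4])
    expect_true(all(abs(out) < 1e-12))
  }
  out2 <- gap_segment_derivative(lin, 2, 5, 5, 1)
  expect_true(all(abs(out2) < 1e-9))
  # d=1 on a linear ramp gives the constant 2*g*slope
  out1 <- gap_segment_derivative(lin[1, , drop = FALSE], 1, 4, 1, 1)
  expect_true(all(abs(out1 - 2 * 4 * 5 * 0.01) < 1e-12))
  expect_error(gap_segment_derivative(const[, 1:5], 2, 5, 5, 1), "exhausted")
})

test_that("the identity code 0,0,1,1 and 'None' leave spectra untouched", {
  x <- rand_spectra()
  expect_equal(gap_segment_derivative(x, 0, 0, 1, 1), x, tolerance = 0)
  out <- apply_pretreatment(x, "None 0,0,1,1", mode = "fit")
  expect_identical(out$spectra, x)
  expect_identical(out$wavelengths, attr(x, "wavelengths"))
})

test_that("pretreatment codes parse, serialize and round-trip", {
  for (code in reported_pretreatment_codes()) {
    pc <- parse_pretreatment(code)
    expect_s3_class(pc, "pretreatment_code")
    expect_identical(format(pc), code)
  }
  pc <- parse_pretreatment("SNV+detrend 2,5,5,1")
  expect_identical(pc$scatter_ops, c("SNV", "detrend"))
  expect_identical(c(pc$d, pc$g, pc$s1, pc$s2), c(2L, 5L, 5L, 1L))
  expect_error(parse_pretreatment("bogus"), "cannot parse")
  expect_error(parse_pretreatment("SNV 3,5,5,1"), "order")
  expect_error(parse_pretreatment("SNV 1,0,5,1"), "gap")
})

test_that("every reported code applies to a 216-band matrix with finite output", {
  set.seed(5)
  wl <- seq(950, 1650, by = 3.25)  # 216 bands
  x <- matrix(abs(rnorm(8 * length(wl), 0.5, 0.2)), 8)
  attr(x, "wavelengths") <- wl
  for (code in reported_pretreatment_codes()) {
    out <- apply_pretreatment(x, code, mode = "fit")
    m <- out$spectra
    expect_true(all(is.finite(m)), info = code)
    expect_identical(ncol(m), length(out$wavelengths))
    expect_true(all(out$wavelengths %in% wl), info = code)
  }
})

test_that("SNV invariance propagates through a full code", {
  x <- rand_spectra()
  shifted <- 1.7 * x - 0.3
  attr(shifted, "wavelengths") <- attr(x, "wavelengths")
  a <- apply_pretreatment(x, "SNV 2,5,5,1", mode = "fit")$spectra
  b <- apply_pretreatment(shifted, "SNV 2,5,5,1", mode = "fit")$spectra
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("MSC transform mode requires and reuses the fitted reference", {
  x <- rand_spectra(seed = 2)
  fitted <- apply_pretreatment(x, "MSC 0,0,1,1", mode = "fit")
  expect_false(is.null(fitted$code$msc_reference))
  fresh <- parse_pretreatment("MSC 0,0,1,1")
  expect_error(apply_pretreatment(x, fresh, mode = "transform"), "before fit")
  new_x <- rand_spectra(seed = 3)
  out <- apply_pretreatment(new_x, fitted$code, mode = "transform")$spectra
  # against the stored calibration reference, not new_x's own mean
  ref <- fitted$code$msc_reference
  expect_equal(out, msc(new_x, ref), tolerance = 1e-12)
})
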