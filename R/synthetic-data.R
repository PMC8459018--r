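#' Variety composition profiles for the synthetic generator
#'
#' Turns the long reference-composition table into a list of per-variety
#' profiles consumed by [generate_reference_panel()]. Each profile carries
#' the variety mean and standard error of total fat and of the 16 fatty
#' acids, plus `n_ref`, the number of kernels behind the reported SEs (the
#' per-sample draw SD is `sqrt(n_ref) * SE`, i.e. the sample SD the SE
#' implies).
#'
#' @param reference long tibble as returned by
#'   [walnut_composition_reference()].
#' @param n_ref optional override: single count, or named per-variety vector,
#'   replacing the reference counts.
#' @return A named list of `variety_profile` objects.
#' @export
walnut_variety_profiles <- function(reference = walnut_composition_reference(),
                                    n_ref = NULL) {
  acids <- fatty_acid_families()$acid
  profs <- lapply(split(reference, reference$variety), function(df) {
    fat <- df[df$analyte == "total_fat", ]
    fa <- df[match(acids, df$analyte), ]
    nr <- if (is.null(n_ref)) fat$n_ref
          else if (length(n_ref) == 1L) n_ref
          else n_ref[[fat$variety]]
    p <- list(name = fat$variety,
              mean_total_fat = fat$mean, se_total_fat = fat$se,
              fa_means = setNames(fa$mean, acids),
              fa_ses = setNames(fa$se, acids),
              n_ref = nr)
    class(p) <- "variety_profile"
    validate_variety_profile(p)
  })
  profs[unique(reference$variety)]
}

validate_variety_profile <- function(p) {
  stopifnot(all(p$fa_means >= 0), all(p$fa_ses >= 0), p$se_total_fat >= 0,
            p$mean_total_fat >= 0, length(p$fa_means) == 16L)
  s <- sum(p$fa_means)
  if (s < 95 || s > 105)
    stop("fatty-acid means of '", p$name, "' sum to ", round(s, 2),
         ", outside [95, 105] relative %", call. = FALSE)
  p
}

#' Generate a synthetic reference-chemistry panel
#'
#' Draws per-kernel compositions around the variety means: each of the 16
#' fatty acids is drawn independently as `N(mean, sqrt(n_ref) * SE)`,
#' truncated at zero, then the 16 acids are renormalized to sum exactly to
#' 100 (relative %). Total fat is drawn independently on the same rule.
#' Family totals (SFA/MUFA/PUFA) are computed as sums of member acids after
#' renormalization. The renormalization induces the compositional negative
#' correlation between acids; no further biological correlation is imposed.
#'
#' @param profiles list of variety profiles ([walnut_variety_profiles()]).
#' @param n_per_variety samples per variety: single count or vector, one per
#'   profile.
#' @param seed integer seed for the chemistry stream.
#' @return A tibble with `sample_id`, `variety`, `total_fat`, the 16 acid
#'   columns, and `SFA`, `MUFA`, `PUFA` family totals.
#' @export
generate_reference_panel <- function(profiles = walnut_variety_profiles(),
                                     n_per_variety, seed) {
  if (length(profiles) == 0L) stop("empty profile list", call. = FALSE)
  if (any(n_per_variety < 1)) stop("n_per_variety must be >= 1", call. = FALSE)
  n_per <- rep_len(n_per_variety, length(profiles))
  fam <- fatty_acid_families()
  set.seed(as.integer(seed))
  rows <- purrr::map2_dfr(profiles, n_per, function(p, n) {
    k <- length(p$fa_means)
    sds <- sqrt(p$n_ref) * p$fa_ses
    draws <- matrix(rnorm(n * k, rep(p$fa_means, each = n), rep(sds, each = n)),
                    nrow = n, dimnames = list(NULL, names(p$fa_means)))
    draws[draws < 0] <- 0
    draws <- 100 * draws / rowSums(draws)
    fat <- pmax(0, rnorm(n, p$mean_total_fat, sqrt(p$n_ref) * p$se_total_fat))
    dplyr::bind_cols(tibble::tibble(variety = p$name, total_fat = fat),
                     tibble::as_tibble(draws))
  })
  rows <- dplyr::mutate(rows, sample_id = sprintf("k%03d", dplyr::row_number()),
                        .before = 1)
  family_sums(rows)
}

#' Absorptivity signature library
#'
#' A `signature_set` maps each composition component to an absorptivity
#' spectrum on a common band grid; kernel absorbance is the Beer-Lambert sum
#' `A(lambda) = sum_k c_k * eps_k(lambda)`. The default library places 2-4
#' Gaussian bands per component in the 1150-1500 nm first-overtone region,
#' with heights chosen so typical kernel absorbance falls in roughly
#' `[0.1, 1.2]`. Components: `fat`, `sfa`, `mufa`, `pufa` (fractions of 1)
#' and `moisture`.
#'
#' @param band_grid wavelength grid in nm (default 950-1650 nm, 3.25 nm
#'   steps, the kept analysis subrange).
#' @return A `signature_set`: list with `band_grid` and a named list
#'   `signatures` of non-negative absorptivity vectors.
#' @export
default_signature_set <- function(band_grid = seq(950, 1650, by = 3.25)) {
  gauss <- function(centers, widths, heights) {
    v <- numeric(length(band_grid))
    for (i in seq_along(centers))
      v <- v + heights[i] * exp(-0.5 * ((band_grid - centers[i]) / widths[i])^2)
    v
  }
  sigs <- list(
    fat      = gauss(c(1210, 1392, 1460), c(28, 35, 30), c(0.55, 0.40, 0.25)),
    sfa      = gauss(c(1178, 1360),       c(20, 26),     c(0.80, 0.60)),
    mufa     = gauss(c(1216, 1412),       c(18, 24),     c(0.70, 0.55)),
    pufa     = gauss(c(1160, 1322, 1442), c(22, 30, 26), c(0.35, 0.28, 0.30)),
    moisture = gauss(c(1190, 1452),       c(35, 28),     c(0.30, 0.65))
  )
  signature_set(band_grid, sigs)
}

#' @rdname default_signature_set
#' @param signatures named list of non-negative absorptivity vectors, one per
#'   component, each the length of `band_grid`.
#' @export
signature_set <- function(band_grid, signatures) {
  stopifnot(length(signatures) >= 1, !is.null(names(signatures)))
  for (nm in names(signatures)) {
    s <- signatures[[nm]]
    if (length(s) != length(band_grid))
      stop("signature '", nm, "' length does not match the band grid", call. = FALSE)
    if (any(s < 0)) stop("signature '", nm, "' has negative absorptivity", call. = FALSE)
  }
  structure(list(band_grid = as.numeric(band_grid), signatures = signatures),
            class = "signature_set")
}

#' Noise configuration for the synthetic generator
#'
#' All noise terms the scene and spectrum renderers inject, in the units
#' where they act. Defaults emulate a bench-top push-broom acquisition.
#'
#' @param sensor_sd per-pixel additive absorbance noise SD.
#' @param scatter_sd SD of the per-kernel multiplicative scatter factor
#'   (factor = `1 + N(0, scatter_sd)`), the term SNV/MSC are meant to remove.
#' @param baseline_sd SD of the per-kernel additive absorbance baseline.
#' @param jitter_sd SD of the per-pixel path-length jitter multiplying the
#'   compositional absorbance.
#' @param structured_sd amplitude SD of smooth per-kernel spectral
#'   deviations (a handful of random Gaussian bumps per kernel), emulating
#'   the compositional and physical heterogeneity that gives real kernel
#'   spectra their high intrinsic dimension (about a dozen PCs at 99%
#'   variance rather than the handful the pure mixing model would produce).
#' @param reference_sd SD of the reference-chemistry measurement error (in
#'   analyte units, applied to total fat and family totals by
#'   [add_reference_noise()]); this is the noise floor external prediction
#'   errors are compared against.
#' @return A named list of class `noise_config`.
#' @export
noise_config <- function(sensor_sd = 0.005, scatter_sd = 0.05,
                         baseline_sd = 0.01, jitter_sd = 0.01,
                         structured_sd = 0.006, reference_sd = 0.5) {
  structure(list(sensor_sd = sensor_sd, scatter_sd = scatter_sd,
                 baseline_sd = baseline_sd, jitter_sd = jitter_sd,
                 structured_sd = structured_sd, reference_sd = reference_sd),
            class = "noise_config")
}

#' @rdname noise_config
#' @export
noise_off <- function() noise_config(0, 0, 0, 0, 0, 0)

# smooth per-kernel spectral deviation: a few random Gaussian bumps
structured_deviation <- function(n, wl, sd_amp, n_bumps = 6) {
  if (sd_amp <= 0) return(matrix(0, n, length(wl)))
  out <- matrix(0, n, length(wl))
  rng <- range(wl)
  for (i in seq_len(n)) {
    centers <- runif(n_bumps, rng[1], rng[2])
    widths <- runif(n_bumps, 20, 80)
    amps <- rnorm(n_bumps, 0, sd_amp)
    for (j in seq_len(n_bumps))
      out[i, ] <- out[i, ] + amps[j] * exp(-0.5 * ((wl - centers[j]) / widths[j])^2)
  }
  out
}

# component concentrations (fractions) for a panel row
composition_components <- function(panel) {
  cbind(fat = panel$total_fat / 100,
        sfa = panel$SFA / 100,
        mufa = panel$MUFA / 100,
        pufa = panel$PUFA / 100,
        moisture = (100 - panel$total_fat) / 100)
}

# noiseless Beer-Lambert rendering: rows of `conc` x band grid
render_absorbance <- function(conc, signatures) {
  comp <- colnames(conc)
  missing <- setdiff(comp, names(signatures$signatures))
  if (length(missing))
    stop("no signature for component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  eps <- do.call(rbind, signatures$signatures[comp])  # comp x bands
  conc %*% eps
}

#' Simulate per-kernel mean spectra directly
#'
#' Renders the generator's optical model at the kernel-mean level, without
#' rasterizing image cubes: absorbance = Beer-Lambert sum x per-kernel
#' scatter + baseline + averaged sensor noise. Used where the imaging chain
#' itself is not under test.
#'
#' @param panel reference panel tibble ([generate_reference_panel()]).
#' @param signatures a `signature_set`.
#' @param noise a [noise_config()].
#' @param seed integer seed for the noise stream.
#' @param n_pixels nominal ROI size; sensor noise SD is divided by
#'   `sqrt(n_pixels)` to reflect ROI averaging.
#' @return A spectrum table (see [spectra_table()]).
#' @export
simulate_kernel_spectra <- function(panel, signatures = default_signature_set(),
                                    noise = noise_config(), seed = 1,
                                    n_pixels = 500) {
  conc <- composition_components(panel)
  a0 <- render_absorbance(conc, signatures)
  set.seed(as.integer(seed))
  n <- nrow(a0); b <- ncol(a0)
  scatter <- 1 + rnorm(n, 0, noise$scatter_sd)
  baseline <- rnorm(n, 0, noise$baseline_sd)
  a <- (a0 + structured_deviation(n, signatures$band_grid, noise$structured_sd)) *
    scatter + baseline +
    matrix(rnorm(n * b, 0, noise$sensor_sd / sqrt(n_pixels)), n, b)
  spectra_table(a, signatures$band_grid, id = panel$sample_id,
                variety = panel$variety)
}

#' Add reference-chemistry measurement noise
#'
#' Perturbs the reported reference values (total fat and the three family
#' totals) with independent `N(0, reference_sd)` error, emulating the
#' wet-chemistry measurement error that separates reference values from the
#' composition the spectra encode. The unperturbed truth is retained in
#' `*_true` columns.
#'
#' @inheritParams simulate_kernel_spectra
#' @return The panel with `total_fat`, `SFA`, `MUFA`, `PUFA` perturbed and
#'   `total_fat_true` etc. appended.
#' @export
add_reference_noise <- function(panel, noise = noise_config(), seed = 1) {
  set.seed(as.integer(seed) + 7901L)
  out <- panel
  for (col in c("total_fat", "SFA", "MUFA", "PUFA")) {
    out[[paste0(col, "_true")]] <- out[[col]]
    out[[col]] <- out[[col]] + rnorm(nrow(out), 0, noise$reference_sd)
  }
  out
}

# ---- scene rendering --------------------------------------------------------

#' Render a synthetic two-acquisition hyperspectral scene
#'
#' Renders up to 10 kernels as irregular ellipses on a flat background,
#' encodes kernel reflectance as `R = 10^(-A)` with
#' `A = (sum_k c_k eps_k(lambda)) * (1 + pixel jitter) * kernel scatter +
#' baseline + sensor noise`, and wraps the result in raw counts
#' `raw = dark + R * (white - dark)` so that two-point calibration exactly
#' inverts the encoding. A second acquisition re-renders the same kernels at
#' 180-degree-rotated positions with fresh scatter and noise; `pairing` maps
#' kernel ids between the two truth masks (ids are assigned in reading order
#' of centroids within each acquisition).
#'
#' @param panel_rows reference panel subset, at most 10 rows.
#' @param signatures a `signature_set`.
#' @param noise a [noise_config()].
#' @param seed integer seed for the noise stream.
#' @param layout_seed integer seed for the geometric layout (kept separate so
#'   layout can be held fixed while noise varies; defaults to `seed`).
#' @param dims scene size `c(lines, pixels)`.
#' @param kernel_area admissible kernel area range in pixels.
#' @param background_reflectance flat background reflectance.
#' @return A list with acquisitions `a` and `b` (each `raw`, `dark`, `white`
#'   hypercubes plus `truth = list(mask, compositions)`), and `pairing`, a
#'   tibble `id_a`, `id_b`.
#' @export
generate_scene <- function(panel_rows, signatures = default_signature_set(),
                           noise = noise_config(), seed = 1,
                           layout_seed = seed, dims = c(320, 256),
                           kernel_area = c(300, 900),
                           background_reflectance = 0.85) {
  k <- nrow(panel_rows)
  if (k > 10) stop("at most 10 kernels per scene (got ", k, ")", call. = FALSE)
  wl <- signatures$band_grid
  layout <- scene_layout(k, dims, kernel_area, layout_seed)
  conc <- composition_components(panel_rows)
  a_base <- render_absorbance(conc, signatures)     # kernels x bands

  frames <- reference_frames(dims, wl)
  render_one <- function(masks, noise_seed) {
    set.seed(as.integer(noise_seed))
    nl <- dims[1]; np <- dims[2]; nb <- length(wl)
    label <- masks$label
    a_bg <- -log10(background_reflectance)
    refl <- array(0, c(nl, np, nb))
    bg_idx <- which(label == 0L)
    for (b in seq_len(nb))
      refl[, , b][bg_idx] <- 10^-(a_bg + rnorm(length(bg_idx), 0, noise$sensor_sd))
    dev <- structured_deviation(k, wl, noise$structured_sd)
    for (i in seq_len(k)) {
      idx <- which(label == i)
      scatter <- 1 + rnorm(1, 0, noise$scatter_sd)
      baseline <- rnorm(1, 0, noise$baseline_sd)
      jitter <- 1 + rnorm(length(idx), 0, noise$jitter_sd)
      for (b in seq_len(nb)) {
        a_pix <- (a_base[i, b] + dev[i, b]) * jitter * scatter + baseline +
          rnorm(length(idx), 0, noise$sensor_sd)
        refl[, , b][idx] <- 10^-a_pix
      }
    }
    raw <- frames$dark_arr + refl * (frames$white_arr - frames$dark_arr)
    # reading-order ids for the truth mask
    ord <- order(masks$centroids[, 1], masks$centroids[, 2])
    relabel <- integer(k); relabel[ord] <- seq_len(k)
    mask <- label; mask[label > 0L] <- relabel[label[label > 0L]]
    comps <- tibble::tibble(kernel_id = relabel, sample_id = panel_rows$sample_id,
                            variety = panel_rows$variety) |> dplyr::arrange(.data$kernel_id)
    list(raw = hypercube(raw, wl, "raw"),
         dark = hypercube(frames$dark_arr, wl, "raw"),
         white = hypercube(frames$white_arr, wl, "raw"),
         truth = list(mask = mask, compositions = comps),
         order_map = relabel)
  }

  acq_a <- render_one(layout$a, noise_seed = seed)
  acq_b <- render_one(layout$b, noise_seed = seed + 5000L)
  pairing <- tibble::tibble(id_a = acq_a$order_map, id_b = acq_b$order_map)
  pairing <- dplyr::arrange(pairing, .data$id_a)
  acq_a$order_map <- NULL; acq_b$order_map <- NULL
  list(a = acq_a, b = acq_b, pairing = pairing)
}

# frames constant across lines (so per-column medians reproduce them exactly)
reference_frames <- function(dims, wl) {
  nl <- dims[1]; np <- dims[2]; nb <- length(wl)
  dark_pb <- outer(100 + 0.02 * seq_len(np), 1 + 0.001 * seq_len(nb))
  white_pb <- outer(3000 - 0.5 * seq_len(np) / np,
                    1 - 0.3 * ((seq_len(nb) - nb / 2) / nb)^2)
  expand <- function(pb) aperm(array(rep(pb, each = nl), c(nl, np, nb)), c(1, 2, 3))
  list(dark_arr = expand(dark_pb), white_arr = expand(white_pb))
}

# irregular-ellipse layout on a grid, plus its 180-degree rotation
scene_layout <- function(k, dims, kernel_area, layout_seed) {
  set.seed(as.integer(layout_seed) + 271L)
  nl <- dims[1]; np <- dims[2]
  ncol_grid <- min(5L, k); nrow_grid <- ceiling(k / ncol_grid)
  cell_l <- nl / nrow_grid; cell_p <- np / ncol_grid
  params <- vector("list", k)
  for (i in seq_len(k)) {
    r <- (i - 1) %/% ncol_grid; c <- (i - 1) %% ncol_grid
    area <- runif(1, kernel_area[1], kernel_area[2])
    aspect <- runif(1, 0.75, 1.3)
    a_ax <- sqrt(area * aspect / pi); b_ax <- sqrt(area / aspect / pi)
    cl <- cell_l * (r + 0.5) + runif(1, -0.08, 0.08) * cell_l
    cp <- cell_p * (c + 0.5) + runif(1, -0.08, 0.08) * cell_p
    params[[i]] <- list(cl = cl, cp = cp, a = a_ax, b = b_ax,
                        theta = runif(1, 0, pi),
                        ph = runif(2, 0, 2 * pi), amp = runif(2, 0.02, 0.07))
  }
  rasterize <- function(params, rotated) {
    label <- matrix(0L, nl, np)
    centroids <- matrix(NA_real_, k, 2)
    for (i in seq_len(k)) {
      p <- params[[i]]
      cl <- if (rotated) nl + 1 - p$cl else p$cl
      cp <- if (rotated) np + 1 - p$cp else p$cp
      th <- if (rotated) p$theta + pi else p$theta
      rmax <- max(p$a, p$b) * 1.2
      ll <- max(1L, floor(cl - rmax)):min(nl, ceiling(cl + rmax))
      pp <- max(1L, floor(cp - rmax)):min(np, ceiling(cp + rmax))
      gl <- rep(ll, times = length(pp)); gp <- rep(pp, each = length(ll))
      dl <- gl - cl; dp <- gp - cp
      u <- cos(th) * dl + sin(th) * dp
      v <- -sin(th) * dl + cos(th) * dp
      phi <- atan2(v, u)
      bump <- 1 + p$amp[1] * sin(3 * phi + p$ph[1]) + p$amp[2] * sin(5 * phi + p$ph[2])
      inside <- (u / (p$a * bump))^2 + (v / (p$b * bump))^2 <= 1
      label[cbind(gl[inside], gp[inside])] <- i
      centroids[i, ] <- c(mean(gl[inside]), mean(gp[inside]))
    }
    list(label = label, centroids = centroids)
  }
  list(a = rasterize(params, FALSE), b = rasterize(params, TRUE))
}

#' Write a scene acquisition to disk in the ENVI-style dialect
#'
#' Writes the raw, dark and white cubes next to each other, plus the truth
#' mask as a delimited text matrix and the kernel composition table.
#'
#' @param acq one acquisition from [generate_scene()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return The directory, invisibly.
#' @export
write_scene <- function(acq, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(s) file.path(dir, paste0(prefix, s))
  write_cube(acq$raw, p("_raw.hdr"), p("_raw.bin"))
  write_cube(acq$dark, p("_dark.hdr"), p("_dark.bin"))
  write_cube(acq$white, p("_white.hdr"), p("_white.bin"))
  write.table(acq$truth$mask, p("_mask.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  utils::write.csv(acq$truth$compositions, p("_truth.csv"), row.names = FALSE)
  invisible(dir)
}
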