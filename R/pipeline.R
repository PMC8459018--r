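#' Pipeline configuration
#'
#' Collects and validates every tunable of the end-to-end analysis. The
#' defaults are the analysis conditions used throughout: 950-1650 nm kept
#' subrange, H > 3 spectral-outlier cut, NH < 0.9 grouping, T > 2.5
#' chemistry-outlier cut, alpha = 0.05, and the reported pretreatment-code
#' sweep.
#'
#' @param n_per_variety kernels simulated per variety (default the imaged
#'   counts 31, 29, 32, 35, 38 for Chandler, Franquette, Howard, Lara,
#'   Tulare).
#' @param analytes analytes to model.
#' @param codes pretreatment codes swept per analyte; the model with the
#'   lowest SECV is kept (`best_by = "sep"` switches the criterion).
#' @param band_range kept wavelength subrange (nm).
#' @param selection_code pretreatment for the sample-selection PCA.
#' @param h_threshold,nh_threshold,t_threshold,alpha analysis thresholds.
#' @param n_folds,f_max MPLS cross-validation settings.
#' @param noise a [noise_config()].
#' @param signatures the absorptivity library rendering the synthetic
#'   spectra (default [default_signature_set()]).
#' @param scene_dims,kernel_area scene geometry passed to [generate_scene()].
#' @param use_imaging render full image cubes and run the segmentation chain
#'   (`TRUE`), or simulate kernel-mean spectra directly (`FALSE`).
#' @param best_by model-sweep selection criterion, `"secv"` or `"sep"`.
#' @param seed master seed; all stage streams derive from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_variety = c(31, 29, 32, 35, 38),
                            analytes = c("total_fat", "SFA", "MUFA", "PUFA"),
                            codes = reported_pretreatment_codes(),
                            band_range = c(950, 1650),
                            selection_code = "SNV 2,5,5,1",
                            h_threshold = 3, nh_threshold = 0.9,
                            t_threshold = 2.5, alpha = 0.05,
                            n_folds = 6, f_max = NULL,
                            noise = noise_config(),
                            signatures = default_signature_set(),
                            scene_dims = c(320, 256),
                            kernel_area = c(300, 900),
                            use_imaging = FALSE,
                            best_by = c("secv", "sep"),
                            seed = 1) {
  best_by <- match.arg(best_by)
  if (length(analytes) == 0L) stop("empty analyte list", call. = FALSE)
  stopifnot(band_range[1] < band_range[2], h_threshold > 0, nh_threshold > 0,
            t_threshold > 0, alpha > 0, alpha < 1, n_folds >= 2,
            all(n_per_variety >= 1))
  structure(list(n_per_variety = n_per_variety, analytes = analytes,
                 codes = codes, band_range = band_range,
                 selection_code = selection_code, h_threshold = h_threshold,
                 nh_threshold = nh_threshold, t_threshold = t_threshold,
                 alpha = alpha, n_folds = n_folds, f_max = f_max,
                 noise = noise, signatures = signatures, scene_dims = scene_dims,
                 kernel_area = kernel_area, use_imaging = use_imaging,
                 best_by = best_by, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end screening pipeline
#'
#' Stage order: simulate chemistry (and scenes, if imaging is on) ->
#' radiometric calibration and absorbance -> LDA segmentation, ROI
#' extraction and acquisition merging -> band subrange -> Mahalanobis
#' sample selection -> per-analyte MPLS sweep over the configured
#' pretreatment codes, keeping the best model by SECV -> external
#' validation report -> prediction of the non-selected samples and
#' variety-level composition statistics. Every stage draws from a seed
#' derived deterministically from `config$seed`, so a rerun reproduces the
#' run byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, reports are written as
#'   delimited text / JSON.
#' @return A list: `panel`, `spectra`, `selection`, `models` (per analyte),
#'   `report` (validation-report tibble), `predicted_summary`
#'   (variety-level statistics of the non-selected predictions).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  panel <- generate_reference_panel(n_per_variety = config$n_per_variety,
                                    seed = seed)
  sigs <- config$signatures
  spectra <- if (config$use_imaging) {
    pipeline_imaging_spectra(panel, sigs, config)
  } else {
    simulate_kernel_spectra(panel, sigs, config$noise, seed = seed + 11L)
  }
  panel <- add_reference_noise(panel, config$noise, seed = seed + 23L)

  # band subrange (spectrum-table level)
  wl <- spectra_wavelengths(spectra)
  keep <- wl >= config$band_range[1] & wl <= config$band_range[2]
  spectra <- rebuild_spectra(spectra, spectra_matrix(spectra)[, keep, drop = FALSE],
                             wl[keep])

  sel <- select_samples(spectra, code = config$selection_code,
                        h_threshold = config$h_threshold,
                        nh_threshold = config$nh_threshold)
  cal_ids <- sel$id[sel$set == "CAL"]
  val_ids <- sel$id[sel$set == "VAL"]
  non_ids <- sel$id[sel$set == "NONSEL"]
  split_tbl <- function(ids) spectra[match(ids, spectra_ids(spectra)), , drop = FALSE]
  x_cal <- split_tbl(cal_ids); x_val <- split_tbl(val_ids)
  x_non <- split_tbl(non_ids)

  models <- list(); report <- list()
  for (an in config$analytes) {
    y_cal <- panel[[an]][match(cal_ids, panel$sample_id)]
    y_val <- panel[[an]][match(val_ids, panel$sample_id)]
    sweep_fit <- purrr::map(config$codes, function(cd)
      mpls(x_cal, y_cal, code = cd, f_max = config$f_max,
           n_folds = config$n_folds, t_threshold = config$t_threshold,
           seed = seed + 31L))
    crit <- vapply(sweep_fit, function(m) {
      if (config$best_by == "secv" || length(val_ids) < 3) m$secv
      else sep(y_val, predict(m, x_val))$sep
    }, numeric(1))
    best <- sweep_fit[[which.min(crit)]]
    models[[an]] <- best
    report[[an]] <- if (length(val_ids) >= 3)
      validation_report(best, x_val, y_val, analyte = an)
    else validation_report(best, analyte = an)
  }
  report <- dplyr::bind_rows(report)

  # predict the non-selected samples, summarize per variety
  pred <- tibble::tibble(
    sample_id = non_ids,
    variety = panel$variety[match(non_ids, panel$sample_id)])
  for (an in config$analytes)
    pred[[an]] <- if (length(non_ids)) predict(models[[an]], x_non) else numeric(0)
  has_groups <- length(unique(pred$variety)) >= 2 &&
    any(table(pred$variety) >= 2)
  predicted_summary <- if (nrow(pred)) variety_summary(pred, config$analytes)
                       else tibble::tibble()
  pred_letters <- if (has_groups) purrr::map_dfr(config$analytes, function(an) {
    res <- anova_tukey(pred[[an]], pred$variety, config$alpha)
    dplyr::mutate(res$letters, analyte = an)
  }) else tibble::tibble()

  out <- list(panel = panel, spectra = spectra, selection = sel,
              models = models, report = report, predicted = pred,
              predicted_summary = predicted_summary,
              predicted_letters = pred_letters, config = config)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

# imaging branch: render scenes of up to 10 kernels, calibrate, segment,
# merge the rotated acquisitions, and return kernel-mean spectra keyed back
# to panel sample ids via the scene truth
pipeline_imaging_spectra <- function(panel, sigs, config) {
  groups <- split(seq_len(nrow(panel)), ceiling(seq_len(nrow(panel)) / 10))
  lda <- NULL
  tabs <- list()
  for (gi in seq_along(groups)) {
    rows <- panel[groups[[gi]], , drop = FALSE]
    sc <- generate_scene(rows, sigs, config$noise,
                         seed = config$seed + 101L * gi,
                         dims = config$scene_dims,
                         kernel_area = config$kernel_area)
    abs_of <- function(acq)
      to_absorbance(calibrate_reflectance(acq$raw,
                                          calibration_frames(acq$dark, acq$white)))
    cube_a <- abs_of(sc$a); cube_b <- abs_of(sc$b)
    if (is.null(lda)) lda <- train_scene_lda(cube_a, sc$a$truth$mask, config$seed)
    spec_of <- function(cube, truth) {
      mask <- classify_pixels(lda, cube)
      rois <- extract_objects(mask)
      if (nrow(rois) != nrow(rows))
        stop("segmentation found ", nrow(rois), " kernels, expected ", nrow(rows),
             call. = FALSE)
      ids <- truth$compositions$sample_id[match(rois$kernel_id,
                                                truth$compositions$kernel_id)]
      roi_mean_spectra(cube, rois, ids = ids)
    }
    sa <- spec_of(cube_a, sc$a$truth); sb <- spec_of(cube_b, sc$b$truth)
    pairing <- tibble::tibble(id_a = spectra_ids(sa), id_b = spectra_ids(sa))
    merged <- merge_acquisitions(sa, sb, pairing)
    merged$variety <- rows$variety[match(merged$id, rows$sample_id)]
    tabs[[gi]] <- merged
  }
  out <- dplyr::bind_rows(tabs)
  names(out)[names(out) == "id"] <- "id"
  out
}

# train the pixel classifier from one scene's ground truth
train_scene_lda <- function(cube, truth_mask, seed, n_per_class = 1500) {
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  attr(flat, "wavelengths") <- cube$wavelengths
  is_kernel <- as.vector(truth_mask > 0)
  set.seed(as.integer(seed) + 77L)
  pick <- c(sample(which(is_kernel), min(n_per_class, sum(is_kernel))),
            sample(which(!is_kernel), min(n_per_class, sum(!is_kernel))))
  px <- flat[pick, , drop = FALSE]
  attr(px, "wavelengths") <- cube$wavelengths
  train_stepwise_lda(px, is_kernel[pick])
}

write_pipeline_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  wr(run$report, "validation_report.csv")
  wr(as.data.frame(run$selection), "selection.csv")
  wr(run$predicted_summary, "predicted_summary.csv")
  wr(run$predicted_letters, "predicted_letters.csv")
  jsonlite::write_json(list(seed = run$config$seed,
                            analytes = run$config$analytes,
                            codes = run$config$codes,
                            band_range = run$config$band_range),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (an in names(run$models))
    write_mpls(run$models[[an]], file.path(out_dir, paste0("model_", an, ".json")))
  invisible(out_dir)
}
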