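#' Fatty-acid family membership
#'
#' The 16 fatty acids quantifiable by GC-FID in walnut oil, and the family
#' (SFA, MUFA, PUFA) each belongs to. Family totals are always computed as
#' sums over these fixed memberships: 4 saturated, 8 monounsaturated and 4
#' polyunsaturated acids.
#'
#' @return A tibble with columns `acid` (short code, e.g. `"C18:1w9c"`),
#'   `family` (`"SFA"`, `"MUFA"` or `"PUFA"`) and `common_name`.
#' @export
fatty_acid_families <- function() {
  tibble::tribble(
    ~acid,        ~family, ~common_name,
    "C16:0",      "SFA",   "palmitic",
    "C17:0",      "SFA",   "margaric",
    "C18:0",      "SFA",   "stearic",
    "C21:0",      "SFA",   "heneicosanoic",
    "C16:1w7c",   "MUFA",  "palmitoleic",
    "C16:1w9c",   "MUFA",  "hypogeic",
    "C17:1w7c",   "MUFA",  "cis-10-heptadecenoic",
    "C17:1w9c",   "MUFA",  "civetic",
    "C18:1w9t",   "MUFA",  "elaidic",
    "C18:1w9c",   "MUFA",  "oleic",
    "C18:1w7c",   "MUFA",  "vaccenic",
    "C20:1w9",    "MUFA",  "gondoic",
    "C18:2w6ct",  "PUFA",  "linolelaidic",
    "C18:2w6c",   "PUFA",  "linoleic",
    "C18:3w6",    "PUFA",  "gamma-linolenic",
    "C18:3w3",    "PUFA",  "alpha-linolenic"
  )
}

#' Reference composition of five commercial walnut varieties
#'
#' GC-FID/Soxhlet reference chemistry for the varieties Chandler, Franquette,
#' Howard, Lara and Tulare: per-variety mean and standard error of total fat
#' (% by weight) and of each of the 16 fatty acids (relative % of total fatty
#' acids), together with the number of kernels behind each mean (`n_ref`).
#' These values parameterize the synthetic-data generator and the worked
#' composition-statistics examples.
#'
#' @return A long tibble with columns `variety`, `analyte`, `mean`, `se`,
#'   `n_ref`.
#' @export
walnut_composition_reference <- function() {
  varieties <- c("Chandler", "Franquette", "Howard", "Lara", "Tulare")
  n_ref <- c(Chandler = 12, Franquette = 8, Howard = 4, Lara = 23, Tulare = 16)
  # mean/se per analyte, variety order as above; SFA/MUFA/PUFA are the
  # reported family-total rows (computed from unrounded acid values, so they
  # differ in the last digit from sums of the rounded acid means)
  rows <- list(
    total_fat   = list(m = c(65.58, 68.86, 68.78, 66.91, 66.29), s = c(0.91, 0.68, 2.24, 0.69, 0.95)),
    SFA         = list(m = c(8.87, 10.17, 8.73, 9.78, 9.44),     s = c(0.13, 0.32, 0.37, 0.13, 0.24)),
    MUFA        = list(m = c(14.44, 16.79, 13.78, 13.62, 13.54), s = c(0.38, 0.51, 1.00, 0.34, 0.48)),
    PUFA        = list(m = c(76.69, 73.03, 77.48, 76.60, 77.02), s = c(0.42, 0.56, 1.36, 0.39, 0.63)),
    `C16:0`     = list(m = c(5.96, 7.17, 5.88, 6.76, 6.65),      s = c(0.10, 0.27, 0.30, 0.12, 0.18)),
    `C17:0`     = list(m = c(0.05, 0.06, 0.05, 0.06, 0.06),      s = c(0.00, 0.02, 0.00, 0.00, 0.00)),
    `C18:0`     = list(m = c(2.28, 2.40, 2.25, 2.38, 2.47),      s = c(0.08, 0.09, 0.20, 0.07, 0.11)),
    `C21:0`     = list(m = c(0.57, 0.54, 0.56, 0.58, 0.26),      s = c(0.11, 0.30, 0.28, 0.15, 0.02)),
    `C16:1w7c`  = list(m = c(0.05, 0.07, 0.05, 0.06, 0.06),      s = c(0.00, 0.02, 0.00, 0.01, 0.00)),
    `C16:1w9c`  = list(m = c(0.06, 0.16, 0.06, 0.09, 0.07),      s = c(0.00, 0.05, 0.01, 0.02, 0.00)),
    `C17:1w7c`  = list(m = c(0.02, 0.02, 0.04, 0.03, 0.02),      s = c(0.00, 0.01, 0.02, 0.01, 0.00)),
    `C17:1w9c`  = list(m = c(0.03, 0.03, 0.03, 0.03, 0.03),      s = c(0.00, 0.00, 0.00, 0.00, 0.00)),
    `C18:1w9t`  = list(m = c(0.06, 0.06, 0.06, 0.05, 0.05),      s = c(0.00, 0.01, 0.01, 0.00, 0.00)),
    `C18:1w9c`  = list(m = c(12.98, 14.84, 12.43, 12.16, 12.27), s = c(0.41, 0.63, 0.90, 0.37, 0.48)),
    `C18:1w7c`  = list(m = c(1.08, 1.47, 0.99, 1.01, 0.93),      s = c(0.09, 0.27, 0.09, 0.09, 0.02)),
    `C20:1w9`   = list(m = c(0.14, 0.14, 0.12, 0.17, 0.10),      s = c(0.02, 0.05, 0.03, 0.03, 0.01)),
    `C18:2w6ct` = list(m = c(0.07, 0.09, 0.06, 0.07, 0.06),      s = c(0.01, 0.03, 0.00, 0.01, 0.00)),
    `C18:2w6c`  = list(m = c(62.22, 58.64, 60.36, 63.74, 62.27), s = c(0.51, 0.78, 0.74, 0.58, 0.76)),
    `C18:3w6`   = list(m = c(0.17, 0.18, 0.14, 0.18, 0.09),      s = c(0.04, 0.12, 0.07, 0.05, 0.02)),
    `C18:3w3`   = list(m = c(14.23, 14.12, 16.92, 12.61, 14.60), s = c(0.45, 0.64, 1.25, 0.45, 0.70))
  )
  purrr::imap_dfr(rows, function(v, analyte) {
    tibble::tibble(variety = varieties, analyte = analyte,
                   mean = v$m, se = v$s, n_ref = unname(n_ref[varieties]))
  })
}

#' Example MPLS model descriptor table
#'
#' Reported calibration/validation descriptors for NIR MPLS models of total
#' fat and the three fatty-acid families in walnut kernels (950-1650 nm):
#' best pretreatment code, chemistry (T) outliers removed, selected PLS
#' factors, calibration N, estimated applicability range (mean -/+ 3 SD),
#' SEC, RSQ, SECV and SEP in analyte units. Used to demonstrate the
#' percent-of-range-midpoint reporting convention (see [percent_error()]).
#'
#' @return A tibble, one row per reference parameter.
#' @export
example_model_descriptors <- function() {
  tibble::tribble(
    ~analyte,    ~pretreatment,          ~t_outliers, ~pls_factors, ~n,
    ~est_min, ~sd, ~est_max, ~sec, ~rsq, ~secv, ~sep,
    "total_fat", "MSC 1,5,5,1",          3L, 6L, 40L,
    56.894, 3.417, 77.393, 0.948, 0.923, 1.525, 2.019,
    "SFA",       "SNV+detrend 2,5,5,1",  0L, 6L, 43L,
    6.640, 0.924, 12.186, 0.410, 0.803, 0.750, 0.689,
    "MUFA",      "SNV 2,5,5,1",          1L, 7L, 42L,
    8.644, 1.856, 19.779, 0.835, 0.798, 1.415, 1.860,
    "PUFA",      "MSC 2,10,10,1",        2L, 7L, 41L,
    69.180, 2.404, 83.607, 1.119, 0.784, 1.548, 1.626
  )
}

#' Pretreatment codes of the reported walnut MPLS model sweep
#'
#' The distinct WinISI-style pretreatment code strings used across the
#' reported family and individual fatty-acid models. Useful as a default
#' sweep for [run_pipeline()] and as a parser test vocabulary.
#'
#' @return Character vector of code strings such as `"SNV+detrend 2,5,5,1"`.
#' @export
reported_pretreatment_codes <- function() {
  unique(c(
    "MSC 1,5,5,1", "SNV+detrend 2,5,5,1", "SNV 2,5,5,1", "MSC 2,10,10,1",
    "SNV 0,0,1,1", "MSC 0,0,1,1", "SNV 2,10,10,1", "MSC 2,5,5,1",
    "Detrend 2,10,10,1", "None 0,0,1,1", "SNV 1,5,5,1"
  ))
}
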