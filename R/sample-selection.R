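#' Spectral PCA for sample selection
#'
#' Mean-centred PCA of the pretreated spectra, keeping the smallest number
#' of components whose cumulative explained variance reaches `var_target`
#' (default 99 %). The retained score standard deviations standardize the
#' Mahalanobis distances below.
#'
#' @param spectra spectrum table or matrix.
#' @param var_target cumulative explained-variance target in (0, 1].
#' @return A `spectral_pca` object: `k`, `loadings` (bands x k), `score_sds`,
#'   `center`, `explained_fraction`.
#' @export
fit_spectral_pca <- function(spectra, var_target = 0.99) {
  if (var_target <= 0 || var_target > 1)
    stop("var_target must lie in (0, 1]", call. = FALSE)
  x <- spectra_matrix_or_plain(spectra)
  if (nrow(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= var_target - 1e-12)[1]
  structure(list(k = k,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 score_sds = pc$sdev[seq_len(k)],
                 center = pc$center,
                 explained_fraction = cum[k]),
            class = "spectral_pca")
}

#' @export
print.spectral_pca <- function(x, ...) {
  cat(sprintf("<spectral_pca> k = %d components explaining %.1f%% of variance\n",
              x$k, 100 * x$explained_fraction))
  invisible(x)
}

pca_scores <- function(model, spectra) {
  x <- spectra_matrix_or_plain(spectra)
  sweep(x, 2, model$center) %*% model$loadings
}

#' Standardized global Mahalanobis distance (H)
#'
#' `H = (1/k) * sum_j (t_j / sd_j)^2`: the squared Mahalanobis distance to
#' the spectral centre in PCA score space, divided by the number of
#' components, so that the training-set mean of H is approximately 1
#' (exactly `(N-1)/N`). On this scale the conventional outlier cut `H > 3`
#' is meaningful.
#'
#' @param model a `spectral_pca`.
#' @param spectra spectrum table or matrix of the samples to score.
#' @return Numeric vector of H values.
#' @export
global_h <- function(model, spectra) {
  u <- sweep(pca_scores(model, spectra), 2, model$score_sds, `/`)
  rowMeans(u^2) * ncol(u) / model$k
}

#' Flag spectral outliers
#'
#' @param h_values H values from [global_h()].
#' @param threshold samples with `H > threshold` (strict) are flagged.
#' @param ids optional sample ids.
#' @return The flagged ids (or indices).
#' @export
flag_h_outliers <- function(h_values, threshold = 3.0, ids = NULL) {
  idx <- which(h_values > threshold)
  if (is.null(ids)) idx else ids[idx]
}

# pairwise standardized squared score distances (NH matrix)
nh_matrix <- function(model, spectra) {
  u <- sweep(pca_scores(model, spectra), 2, model$score_sds, `/`)
  as.matrix(stats::dist(u))^2 / model$k
}

#' Neighborhood (NH) grouping
#'
#' Pairs closer than `nh_threshold` in standardized score space are
#' spectrally equivalent; groups are formed greedily: the unassigned sample
#' with the most unassigned neighbours at `NH < nh_threshold` (ties broken
#' by lowest index) becomes a group seed and absorbs those neighbours,
#' until every sample is assigned. Outliers must be removed beforehand.
#'
#' @param model a `spectral_pca`.
#' @param spectra spectrum table or matrix (non-outlier samples).
#' @param nh_threshold grouping radius (default 0.9).
#' @return A list with `groups` (list of member index vectors, seed first),
#'   `seeds` (integer vector) and `nh` (the full NH matrix).
#' @export
neighborhood_groups <- function(model, spectra, nh_threshold = 0.9) {
  nh <- nh_matrix(model, spectra)
  n <- nrow(nh)
  adj <- nh < nh_threshold
  diag(adj) <- FALSE
  assigned <- logical(n)
  groups <- list(); seeds <- integer(0)
  while (!all(assigned)) {
    free <- which(!assigned)
    deg <- vapply(free, function(i) sum(adj[i, free]), numeric(1))
    seed <- free[which.max(deg)]          # which.max breaks ties at lowest index
    members <- c(seed, free[adj[seed, free]])
    members <- unique(members)
    assigned[members] <- TRUE
    groups[[length(groups) + 1L]] <- members
    seeds <- c(seeds, seed)
  }
  list(groups = groups, seeds = seeds, nh = nh)
}

#' Allocate calibration / validation / non-selected sets
#'
#' One sample per NH group — the seed — enters the calibration set; where a
#' group has a second member, the member closest (NH) to the seed enters
#' the validation set; everything else is non-selected (to be predicted
#' only).
#'
#' @param grouping result of [neighborhood_groups()].
#' @return A list of integer index vectors `calibration`, `validation`,
#'   `non_selected`.
#' @export
allocate_sets <- function(grouping) {
  stopifnot(length(grouping$groups) >= 1)
  cal <- grouping$seeds
  val <- integer(0); nonsel <- integer(0)
  for (gi in seq_along(grouping$groups)) {
    g <- grouping$groups[[gi]]
    seed <- grouping$seeds[gi]
    rest <- setdiff(g, seed)
    if (length(rest)) {
      v <- rest[which.min(grouping$nh[seed, rest])]
      val <- c(val, v)
      nonsel <- c(nonsel, setdiff(rest, v))
    }
  }
  list(calibration = sort(cal), validation = sort(val),
       non_selected = sort(nonsel))
}

#' Full spectral sample selection
#'
#' Pretreats the spectra (default `"SNV 2,5,5,1"`), fits the selection PCA,
#' removes `H > h_threshold` outliers, groups the remainder at
#' `NH < nh_threshold`, and allocates calibration / validation /
#' non-selected sets.
#'
#' @param spectra spectrum table (with an `id` column) or matrix.
#' @param code pretreatment code string for the selection space.
#' @param var_target PCA explained-variance target.
#' @param h_threshold global-H outlier cut (strict `>`).
#' @param nh_threshold NH grouping radius.
#' @return A `selection_result` tibble: `id`, `h`, `group` (NA for
#'   outliers), `set` in `CAL`, `VAL`, `NONSEL`, `OUTLIER`; the fitted PCA
#'   and grouping are attached as attributes `pca` and `grouping`.
#' @export
select_samples <- function(spectra, code = "SNV 2,5,5,1", var_target = 0.99,
                           h_threshold = 3.0, nh_threshold = 0.9) {
  ids <- spectra_ids(spectra)
  pre <- apply_pretreatment(spectra, code, mode = "fit")
  x <- spectra_matrix_or_plain(pre$spectra)
  pca <- fit_spectral_pca(x, var_target)
  h <- global_h(pca, x)
  out_idx <- which(h > h_threshold)
  keep <- setdiff(seq_along(ids), out_idx)

  grouping <- neighborhood_groups(pca, x[keep, , drop = FALSE], nh_threshold)
  sets <- allocate_sets(grouping)

  set <- rep("NONSEL", length(ids))
  set[out_idx] <- "OUTLIER"
  set[keep[sets$calibration]] <- "CAL"
  set[keep[sets$validation]] <- "VAL"
  group <- rep(NA_integer_, length(ids))
  for (gi in seq_along(grouping$groups))
    group[keep[grouping$groups[[gi]]]] <- gi

  res <- tibble::tibble(id = ids, h = h, group = group, set = set)
  attr(res, "pca") <- pca
  attr(res, "grouping") <- grouping
  class(res) <- c("selection_result", class(res))
  res
}
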