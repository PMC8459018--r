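#' Fatty-acid family totals
#'
#' Adds (or recomputes) `SFA`, `MUFA` and `PUFA` columns as sums of the
#' member acids over the fixed family memberships (4 saturated, 8
#' monounsaturated, 4 polyunsaturated).
#'
#' @param table per-sample composition tibble holding all 16 acid columns
#'   (relative %).
#' @return The table with family total columns appended/replaced.
#' @export
family_sums <- function(table) {
  fam <- fatty_acid_families()
  missing <- setdiff(fam$acid, names(table))
  if (length(missing))
    stop("missing acid column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (f in c("SFA", "MUFA", "PUFA")) {
    cols <- fam$acid[fam$family == f]
    table[[f]] <- rowSums(as.matrix(table[cols]))
  }
  table
}

#' Variety-level composition summary
#'
#' Per-variety mean and standard error (`SE = SD / sqrt(n)`) for each
#' analyte. With a single sample in a variety the SE is reported as `NA`.
#'
#' @param table per-sample composition tibble with a `variety` column.
#' @param analytes analyte columns to summarize (default: total fat, the 16
#'   acids and the three family totals, whichever are present).
#' @return A long tibble `variety`, `analyte`, `n`, `mean`, `se`.
#' @export
variety_summary <- function(table, analytes = NULL) {
  analytes <- analytes %||%
    intersect(c("total_fat", fatty_acid_families()$acid, "SFA", "MUFA", "PUFA"),
              names(table))
  stopifnot(length(analytes) > 0, "variety" %in% names(table))
  table |>
    dplyr::select(dplyr::all_of(c("variety", analytes))) |>
    tidyr::pivot_longer(-"variety", names_to = "analyte", values_to = "value") |>
    dplyr::group_by(.data$variety, .data$analyte) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
                     .groups = "drop") |>
    dplyr::mutate(analyte = factor(.data$analyte, levels = analytes)) |>
    dplyr::arrange(.data$analyte, .data$variety) |>
    dplyr::mutate(analyte = as.character(.data$analyte))
}

#' Grand means across varieties
#'
#' The unweighted average of the variety means, per analyte (the convention
#' under which summary shares and ratios are quoted).
#'
#' @param summary a [variety_summary()] tibble.
#' @return A tibble `analyte`, `grand_mean`.
#' @export
grand_means <- function(summary) {
  summary |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(grand_mean = mean(.data$mean), .groups = "drop")
}

#' MUFA/PUFA ratio of a variety
#'
#' Ratio of the variety's mean MUFA to mean PUFA total — an oxidative
#' stability indicator (higher = more stable oil).
#'
#' @param summary a [variety_summary()] tibble containing `MUFA` and `PUFA`.
#' @param variety variety name.
#' @return A single numeric ratio.
#' @export
mufa_pufa_ratio <- function(summary, variety) {
  get1 <- function(an) {
    v <- summary$mean[summary$variety == variety & summary$analyte == an]
    if (length(v) != 1) stop("no ", an, " summary for variety ", variety, call. = FALSE)
    v
  }
  den <- get1("PUFA")
  if (den == 0) stop("zero PUFA denominator", call. = FALSE)
  get1("MUFA") / den
}

#' Share of an acid within its family
#'
#' `100 * grand-mean(acid) / grand-mean(family total)`, using unweighted
#' variety grand means.
#'
#' @param summary a [variety_summary()] tibble.
#' @param acid acid column name (e.g. `"C18:1w9c"`).
#' @return Percent of the family total.
#' @export
family_share <- function(summary, acid) {
  fam <- fatty_acid_families()
  family <- fam$family[fam$acid == acid]
  if (length(family) != 1) stop("unknown acid: ", acid, call. = FALSE)
  gm <- grand_means(summary)
  num <- gm$grand_mean[gm$analyte == acid]
  den <- gm$grand_mean[gm$analyte == family]
  if (length(num) != 1 || length(den) != 1)
    stop("summary lacks ", acid, " or ", family, call. = FALSE)
  if (den == 0) stop("zero family denominator", call. = FALSE)
  100 * num / den
}

#' One-way ANOVA with Tukey grouping letters
#'
#' One-way ANOVA of an analyte on variety, followed by Tukey-Kramer
#' pairwise comparisons (valid under unequal group sizes) and a compact
#' letter display: groups share a letter exactly when they are not
#' significantly different at `alpha`. Letters are derived from the maximal
#' cliques of the non-significance graph (exact and deterministic for the
#' handful of varieties compared here), ordered by group mean. When all
#' values are identical the F statistic is undefined and every group shares
#' one letter.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param alpha significance level (default 0.05).
#' @return A list with `f_value`, `p_value`, and `letters`, a tibble
#'   `group`, `mean`, `letters`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  stopifnot(nlevels(g) >= 2, any(table(g) >= 2))
  means <- tapply(values, g, mean)
  if (var(values) == 0) {
    return(list(f_value = NA_real_, p_value = NA_real_,
                letters = tibble::tibble(group = levels(g), mean = as.numeric(means),
                                         letters = "a")))
  }
  fit <- aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  lev <- levels(g)
  nsig <- diag(TRUE, nlevels(g))
  dimnames(nsig) <- list(lev, lev)
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    ok <- tk[r, "p adj"] >= alpha
    nsig[pair[1], pair[2]] <- nsig[pair[2], pair[1]] <- ok
  }
  letters <- cld_letters(nsig, order(means, decreasing = TRUE))
  list(f_value = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
       letters = tibble::tibble(group = lev, mean = as.numeric(means),
                                letters = letters))
}

# compact letter display from a non-significance adjacency matrix:
# maximal cliques by subset enumeration (k groups, 2^k subsets), one letter
# per clique, letters assigned in decreasing order of the clique's top mean
cld_letters <- function(nsig, mean_order) {
  k <- nrow(nsig)
  stopifnot(k <= 16)
  subsets <- list()
  for (code in seq_len(2^k - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    if (all(nsig[members, members])) subsets[[length(subsets) + 1L]] <- members
  }
  is_max <- vapply(subsets, function(s)
    !any(vapply(subsets, function(t) length(t) > length(s) && all(s %in% t),
                logical(1))), logical(1))
  cliques <- subsets[is_max]
  rank_of <- order(mean_order)  # position of each group in the mean ordering
  cliques <- cliques[order(vapply(cliques, function(s) min(rank_of[s]), numeric(1)))]
  out <- character(k)
  for (i in seq_along(cliques))
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  out
}

#' Composition report across varieties
#'
#' Applies [variety_summary()] and [anova_tukey()] to every analyte,
#' producing the familiar variety-column mean +/- SE table with Tukey
#' superscript letters.
#'
#' @param table per-sample composition tibble with `variety`.
#' @param analytes analytes to report (default as in [variety_summary()]).
#' @param alpha significance level.
#' @return A tibble `analyte`, `variety`, `n`, `mean`, `se`, `letters`.
#' @export
composition_report <- function(table, analytes = NULL, alpha = 0.05) {
  summ <- variety_summary(table, analytes)
  letts <- summ |>
    dplyr::distinct(.data$analyte) |>
    dplyr::pull() |>
    purrr::map_dfr(function(an) {
      res <- anova_tukey(table[[an]], table$variety, alpha)
      dplyr::mutate(res$letters, analyte = an, group = as.character(.data$group))
    })
  dplyr::left_join(summ, dplyr::select(letts, "analyte", variety = "group", "letters"),
                   by = c("variety", "analyte"))
}
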