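# Systemic interindividual variation (SIV) screening on individuals x tissues
# panels, negative-control selection, and the pyrosequencing-style
# inter-tissue correlation call.

check_sample_map <- function(sample_map) {
  need <- c("sample_id", "individual_id", "tissue_id")
  if (!is.data.frame(sample_map) || !all(need %in% names(sample_map))) {
    abort_format(sprintf("`sample_map` must have columns: %s.",
                         paste(need, collapse = ", ")))
  }
  if (anyDuplicated(sample_map[c("individual_id", "tissue_id")])) {
    abort_format("Each (individual, tissue) cell may occur at most once.")
  }
  if (length(unique(sample_map$individual_id)) < 2 ||
      length(unique(sample_map$tissue_id)) < 2) {
    abort_format("Panel needs at least 2 individuals and 2 tissues.")
  }
  invisible(sample_map)
}

# Range of group means per probe. `groups` is a factor aligned with the
# columns of `m`. complete_case = TRUE excludes probes with ANY missing value
# (mirroring an all-samples completeness filter); otherwise each group mean
# uses the tissues available, and probes where a group is fully missing are
# excluded.
range_of_group_means <- function(m, groups, complete_case = TRUE) {
  groups <- as.factor(groups)
  gm <- sapply(levels(groups), function(g) {
    rowMeans(m[, groups == g, drop = FALSE], na.rm = !complete_case)
  })
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1)
  keep <- rowSums(is.na(gm) | is.nan(gm)) == 0
  rng <- apply(gm, 1, function(x) max(x) - min(x))
  rng[!keep] <- NA_real_
  rng
}

#' Interindividual variation across a tissue panel
#'
#' For each probe, take the mean beta across each individual's tissues, then
#' the range (max - min) of these per-individual means. Large values mean the
#' individuals differ consistently, whatever the tissue.
#'
#' @param beta Beta tibble.
#' @param sample_map Data frame mapping `sample_id` to `individual_id` and
#'   `tissue_id`.
#' @param complete_case If `TRUE` (default) probes with any missing value in
#'   the panel are excluded (`NA`), mirroring a strict all-samples filter;
#'   if `FALSE`, per-individual means use the tissues available and only
#'   probes with a fully missing individual are excluded.
#' @return Tibble with `probe_id` and `interindividual_var`.
#' @export
interindividual_variation <- function(beta, sample_map, complete_case = TRUE) {
  check_beta_tbl(beta)
  check_sample_map(sample_map)
  check_samples_present(beta, sample_map$sample_id)
  m <- beta_matrix(beta)[, sample_map$sample_id, drop = FALSE]
  if (complete_case) m[rowSums(is.na(m)) > 0, ] <- NA_real_
  tibble::tibble(
    probe_id = beta$probe_id,
    interindividual_var = unname(range_of_group_means(m, sample_map$individual_id,
                                                      complete_case))
  )
}

#' Tissue-specific variation across a tissue panel
#'
#' The mirror image of [interindividual_variation()]: the range of per-tissue
#' means (each taken over all individuals). Large values mean the tissues
#' differ consistently, whoever the individual.
#'
#' @inheritParams interindividual_variation
#' @return Tibble with `probe_id` and `tissue_var`.
#' @export
tissue_variation <- function(beta, sample_map, complete_case = TRUE) {
  check_beta_tbl(beta)
  check_sample_map(sample_map)
  check_samples_present(beta, sample_map$sample_id)
  m <- beta_matrix(beta)[, sample_map$sample_id, drop = FALSE]
  if (complete_case) m[rowSums(is.na(m)) > 0, ] <- NA_real_
  tibble::tibble(
    probe_id = beta$probe_id,
    tissue_var = unname(range_of_group_means(m, sample_map$tissue_id,
                                             complete_case))
  )
}

#' Classify probes as systemically interindividually variable (SIV)
#'
#' A probe is SIV when its interindividual variation strictly exceeds
#' `inter_min` and its tissue-specific variation is strictly below
#' `tissue_ratio_max` times the interindividual variation -- i.e. individuals
#' differ a lot and tissues hardly at all.
#'
#' @param records Data frame with columns `interindividual_var`, `tissue_var`.
#' @param inter_min Minimum interindividual delta-beta range (default 0.2).
#' @param tissue_ratio_max Maximum tissue/interindividual ratio (default 1/3).
#' @return Logical vector.
#' @export
classify_siv <- function(records, inter_min = 0.2, tissue_ratio_max = 1 / 3) {
  need <- c("interindividual_var", "tissue_var")
  if (!all(need %in% names(records))) {
    abort_format(sprintf("`records` must have columns: %s.",
                         paste(need, collapse = ", ")))
  }
  out <- records$interindividual_var > inter_min &
    records$tissue_var < tissue_ratio_max * records$interindividual_var
  out[is.na(out)] <- FALSE
  out
}

#' Run the full SIV screen on a tissue panel
#'
#' @inheritParams interindividual_variation
#' @inheritParams classify_siv
#' @return Tibble with `probe_id`, `interindividual_var`, `tissue_var`,
#'   `is_siv`.
#' @seealso [classify_siv()], [plot_siv_screen()]
#' @export
siv_screen <- function(beta, sample_map, inter_min = 0.2,
                       tissue_ratio_max = 1 / 3, complete_case = TRUE) {
  inter <- interindividual_variation(beta, sample_map, complete_case)
  tis <- tissue_variation(beta, sample_map, complete_case)
  records <- dplyr::inner_join(inter, tis, by = "probe_id")
  records$is_siv <- classify_siv(records, inter_min, tissue_ratio_max)
  records
}

#' Select negative-control probes
#'
#' Negative controls have interindividual variation comparable to ESS probes
#' but show neither twin supersimilarity nor systemic behaviour: beta range
#' above `range_min`, MZ/RZ normalized MSE above `norm_mz_min` (discordant
#' even within MZ pairs), and tissue-specific variation at least
#' `tissue_factor` times the interindividual variation.
#'
#' @param twin_records Screen records from [ess_screen()] (needs `probe_id`,
#'   `beta_range`, `norm_mz`).
#' @param siv_records Records from [siv_screen()] (needs `probe_id`,
#'   `interindividual_var`, `tissue_var`).
#' @param range_min,norm_mz_min,tissue_factor Selection thresholds.
#' @return Character vector of negative-control probe IDs.
#' @export
select_negative_controls <- function(twin_records, siv_records,
                                     range_min = 0.4, norm_mz_min = 0.5,
                                     tissue_factor = 2) {
  joined <- dplyr::inner_join(
    twin_records[c("probe_id", "beta_range", "norm_mz")],
    siv_records[c("probe_id", "interindividual_var", "tissue_var")],
    by = "probe_id"
  )
  sel <- joined$beta_range > range_min &
    joined$norm_mz > norm_mz_min &
    joined$tissue_var >= tissue_factor * joined$interindividual_var
  sel[is.na(sel)] <- FALSE
  joined$probe_id[sel]
}

#' Inter-tissue correlation SIV call for one assayed region
#'
#' The validation-style SIV call used with targeted bisulfite pyrosequencing:
#' region-average methylation is measured in several tissues of each of `n`
#' individuals, and the region is called SIV when the inter-tissue Pearson
#' correlations (computed across individuals) satisfy `r^2 > r2_min`. By
#' default all tissue pairs must pass (`all_pairs = TRUE`): systemic
#' variation should be concordant across every germ layer; set
#' `all_pairs = FALSE` to require only one passing pair. A tissue with zero
#' variance yields an undefined correlation and a negative call.
#'
#' @param data Long data frame with columns `individual_id`, `tissue_id`,
#'   `value` (region-average methylation).
#' @param r2_min Squared-correlation threshold (default 0.50, i.e.
#'   `|r| > 0.71`).
#' @param all_pairs Require every tissue pair to pass?
#' @return A list of class `siv_call` with `pairs` (tibble of `tissue_a`,
#'   `tissue_b`, `r`, `r_squared`, `pass`), `is_siv`, `n_individuals` and
#'   `undefined` (any zero-variance tissue).
#' @export
intertissue_correlation_call <- function(data, r2_min = 0.5, all_pairs = TRUE) {
  need <- c("individual_id", "tissue_id", "value")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    abort_format(sprintf("`data` must have columns: %s.",
                         paste(need, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(data[need], names_from = "tissue_id",
                             values_from = "value")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 3) {
    rlang::abort("Need at least 3 individuals with all tissues measured.",
                 class = "essiv_error_argument")
  }
  tissues <- setdiff(names(wide), "individual_id")
  combos <- utils::combn(tissues, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    a <- wide[[combos[1, j]]]
    b <- wide[[combos[2, j]]]
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
    tibble::tibble(tissue_a = combos[1, j], tissue_b = combos[2, j],
                   r = r, r_squared = r^2)
  })
  pairs$pass <- !is.na(pairs$r_squared) & pairs$r_squared > r2_min
  undefined <- anyNA(pairs$r)
  is_siv <- if (all_pairs) all(pairs$pass) else any(pairs$pass)
  structure(list(pairs = pairs, is_siv = is_siv,
                 n_individuals = nrow(wide), undefined = undefined),
            class = "siv_call")
}

#' @export
print.siv_call <- function(x, ...) {
  cat(sprintf("Inter-tissue SIV call over %d individuals: %s\n",
              x$n_individuals, if (x$is_siv) "POSITIVE" else "negative"))
  print(x$pairs)
  invisible(x)
}
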