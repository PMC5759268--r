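# Probe-set enrichment machinery: fold enrichment, chi-squared and Fisher
# tests on 2x2 tables, genomic-feature flags, Benjamini-Hochberg FDR.

check_counts <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  counts <- cbind(rep_len(a, n), rep_len(b, n), rep_len(c, n), rep_len(d, n))
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_value("Counts must be non-negative integers.")
  }
  counts
}

#' Fold enrichment of a feature in a probe set
#'
#' `(a / (a + b)) / (c / (c + d))`: the feature rate in the set divided by
#' the feature rate in the background. Vectorized over tables.
#'
#' @param a,b Feature-positive and feature-negative counts in the set.
#' @param c,d Feature-positive and feature-negative counts in the background.
#' @return Numeric vector of folds; `Inf` when the background rate is zero
#'   but the set rate is not, `0` when `a` is zero.
#' @examples
#' fold_enrichment(20, 80, 20, 980) # 10
#' @export
fold_enrichment <- function(a, b, c, d) {
  counts <- check_counts(a, b, c, d)
  if (any(rowSums(counts[, 3:4, drop = FALSE]) == 0)) {
    abort_value("Background must be non-empty.")
  }
  set_rate <- counts[, 1] / (counts[, 1] + counts[, 2])
  bg_rate <- counts[, 3] / (counts[, 3] + counts[, 4])
  out <- set_rate / bg_rate
  out[bg_rate == 0 & set_rate > 0] <- Inf
  out[set_rate == 0] <- 0
  out
}

#' Pearson chi-squared enrichment test on a 2x2 table
#'
#' Without continuity correction (counts in the intended uses are large);
#' warns and recommends Fisher's exact test when any expected cell count is
#' below 1.
#'
#' @inheritParams fold_enrichment
#' @return Tibble with `statistic` and `p_value` per table.
#' @export
chisq_enrichment <- function(a, b, c, d) {
  counts <- check_counts(a, b, c, d)
  if (any(rowSums(counts[, 1:2, drop = FALSE]) == 0) ||
      any(rowSums(counts[, 3:4, drop = FALSE]) == 0) ||
      any(counts[, 1] + counts[, 3] == 0 & counts[, 2] + counts[, 4] == 0)) {
    abort_value("Both table margins must be positive.")
  }
  res <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    tab <- matrix(counts[i, ], 2, 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      rlang::warn("Expected cell count below 1; consider fisher_enrichment().")
    }
    if (any(expected == 0)) {
      return(tibble::tibble(statistic = 0, p_value = 1))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
  })
  res
}

#' Fisher's exact enrichment test on a 2x2 table
#'
#' Hypergeometric-exact p-value; one-sided "greater" by default, the usual
#' direction for enrichment of a feature in a set.
#'
#' @inheritParams fold_enrichment
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`.
#' @return Numeric vector of p-values.
#' @examples
#' fisher_enrichment(3, 1, 1, 3) # 17/70
#' @export
fisher_enrichment <- function(a, b, c, d, alternative = "greater") {
  counts <- check_counts(a, b, c, d)
  alternative <- match.arg(alternative, c("greater", "less", "two.sided"))
  vapply(seq_len(nrow(counts)), function(i) {
    tab <- matrix(counts[i, ], 2, 2, byrow = TRUE)
    stats::fisher.test(tab, alternative = alternative)$p.value
  }, numeric(1))
}

#' High-level probe-set enrichment test
#'
#' Cross-tabulates a probe set against a feature within an explicit
#' background universe (no implicit universe is ever assumed) and reports the
#' fold enrichment together with chi-squared and Fisher p-values. The
#' chi-squared and Fisher tests always partition the background into set and
#' non-set probes; the fold can be taken either against the non-set
#' complement (`fold_base = "complement"`, as when a set is compared with
#' "all other probes meeting the same filter") or against the whole
#' background including the set (`fold_base = "background"`, as when a set is
#' compared with "all probes on the array").
#'
#' @param set Character vector of probe IDs in the set.
#' @param feature Character vector of feature-positive probe IDs.
#' @param background Character vector of all probes in the universe; must
#'   contain `set`.
#' @param fold_base Denominator population for the fold (see above).
#' @return One-row tibble with `a`, `b`, `c`, `d` (test table counts),
#'   `fold`, `chisq_p`, `fisher_p`.
#' @export
enrich_test <- function(set, feature, background,
                        fold_base = c("complement", "background")) {
  fold_base <- match.arg(fold_base)
  if (length(set) == 0) {
    rlang::abort("`set` must be non-empty.", class = "essiv_error_argument")
  }
  if (!all(set %in% background)) {
    abort_value("`set` must be a subset of `background`.")
  }
  set <- unique(set)
  background <- unique(background)
  feature <- unique(feature)
  rest <- setdiff(background, set)
  a <- sum(set %in% feature)
  b <- length(set) - a
  c_rest <- sum(rest %in% feature)
  d_rest <- length(rest) - c_rest
  fold <- if (fold_base == "complement") {
    fold_enrichment(a, b, c_rest, d_rest)
  } else {
    bg_f <- sum(background %in% feature)
    fold_enrichment(a, b, bg_f, length(background) - bg_f)
  }
  if (length(rest) == 0) {
    chi_p <- NA_real_
    fis_p <- NA_real_
  } else {
    chi_p <- chisq_enrichment(a, b, c_rest, d_rest)$p_value
    fis_p <- fisher_enrichment(a, b, c_rest, d_rest)
  }
  tibble::tibble(a = a, b = b, c = c_rest, d = d_rest,
                 fold = fold, chisq_p = chi_p, fisher_p = fis_p)
}

#' Flag probes in subtelomeric regions
#'
#' A probe is subtelomeric when it lies strictly within `window` base pairs
#' of either chromosome end.
#'
#' @param annotation Probe annotation data frame with `chrom` and `position`.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window Distance from a chromosome end (default 2 Mb).
#' @return Logical vector, one element per annotation row.
#' @export
subtelomeric_flag <- function(annotation, chrom_lengths, window = 2e6) {
  if (!all(c("chrom", "position") %in% names(annotation))) {
    abort_format("`annotation` must have `chrom` and `position` columns.")
  }
  unknown <- setdiff(unique(annotation$chrom), names(chrom_lengths))
  if (length(unknown)) {
    abort_value(sprintf("Chromosome length missing for: %s.",
                        paste(unknown, collapse = ", ")))
  }
  len <- unname(chrom_lengths[annotation$chrom])
  annotation$position < window | annotation$position > len - window
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR-adjusted q-values (monotone in p-rank, never below
#' the raw p, never above 1). Missing p-values propagate as `NA`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    abort_value("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p_values, method = "BH")
}
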