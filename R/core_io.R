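# Readers/writers for tabular methylation data and the beta <-> M transforms.

#' Read a probes-by-samples methylation beta matrix
#'
#' Reads a delimited text file whose first column holds probe IDs and whose
#' header row holds sample IDs, and validates it as a beta table: all
#' non-missing values must lie in \[0, 1\] (within `tol`), and probe and
#' sample IDs must be unique. Out-of-range values are an error, never clipped;
#' values within `tol` of the bounds are snapped onto them.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Field delimiter. `NULL` (default) guesses from the file
#'   extension: `","` for `.csv`, tab otherwise.
#' @param tol Numerical tolerance for the \[0, 1\] bound check.
#' @return A tibble with a `probe_id` character column followed by one numeric
#'   column per sample ("beta tibble"); this is the input format accepted by
#'   every screening function in the package.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("probe_id\ts1\ts2", "cg01\t0.1\t0.9", "cg02\t0.5\t0.4"), tf)
#' read_beta_matrix(tf)
#' @export
read_beta_matrix <- function(path, delim = NULL, tol = 1e-9) {
  if (!file.exists(path)) abort_value(sprintf("File not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         na = c("", "NA"), progress = FALSE)
  names(x)[1] <- "probe_id"
  x$probe_id <- as.character(x$probe_id)
  check_beta_tbl(x, tol = tol)
  smp <- setdiff(names(x), "probe_id")
  x[smp] <- lapply(x[smp], function(v) pmin(pmax(v, 0), 1))
  tibble::as_tibble(x)
}

#' Read a sample sheet
#'
#' A sample sheet is a delimited table with one row per sample and a
#' `sample_id` column; optional grouping columns (`pair_id`, `twin_role`,
#' `case_control`, `cancer_type`, `tissue`, `individual_id`, `season`,
#' `genotype`) and numeric covariates are carried through unchanged.
#' Sample IDs must be unique, and when `pair_id` is present every pair
#' must occur exactly twice.
#'
#' @inheritParams read_beta_matrix
#' @return A tibble.
#' @export
read_sample_sheet <- function(path, delim = NULL) {
  if (!file.exists(path)) abort_value(sprintf("File not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         na = c("", "NA"), progress = FALSE)
  if (!"sample_id" %in% names(x)) {
    abort_format("Sample sheet must have a `sample_id` column.")
  }
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) abort_format("Duplicated sample IDs in sample sheet.")
  if ("pair_id" %in% names(x)) {
    counts <- table(x$pair_id[!is.na(x$pair_id)])
    if (any(counts != 2L)) {
      abort_format("Every `pair_id` in a sample sheet must occur exactly twice.")
    }
  }
  tibble::as_tibble(x)
}

#' Read a BED-derived probe annotation table
#'
#' Expected columns: `chrom`, `start` (0-based position, stored as
#' `position`), `probe_id`, and optionally `cpg_island` (logical),
#' `gene`, `h2` (externally supplied narrow-sense heritability) and
#' `beta_snp` (externally supplied fraction of methylation variance
#' explained by neighbouring SNPs).
#'
#' @inheritParams read_beta_matrix
#' @return A tibble with columns `probe_id`, `chrom`, `position` and any
#'   optional annotation columns present.
#' @export
read_probe_annotation <- function(path, delim = NULL) {
  if (!file.exists(path)) abort_value(sprintf("File not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         na = c("", "NA"), progress = FALSE)
  need <- c("chrom", "start", "probe_id")
  if (!all(need %in% names(x))) {
    abort_format(sprintf("Probe annotation must have columns: %s.",
                         paste(need, collapse = ", ")))
  }
  x <- dplyr::rename(x, position = "start")
  x$probe_id <- as.character(x$probe_id)
  if (anyDuplicated(x$probe_id)) abort_format("Duplicated probe IDs in annotation.")
  if (any(x$position < 0, na.rm = TRUE)) abort_value("Probe positions must be >= 0.")
  for (col in intersect(c("h2", "beta_snp"), names(x))) {
    v <- x[[col]]
    if (any(!is.na(v) & (!is.finite(v) | v < 0))) {
      abort_value(sprintf("`%s` values must be finite and non-negative.", col))
    }
  }
  dplyr::relocate(tibble::as_tibble(x), "probe_id", "chrom", "position")
}

#' Convert beta values to M-values
#'
#' `M = log2(beta / (1 - beta))`. Beta values of exactly 0 or 1 have no finite
#' M-value; with `clamp = TRUE` (default) they are clamped to
#' `[eps, 1 - eps]` first, otherwise they raise an error.
#'
#' @param beta Numeric vector of methylation fractions in \[0, 1\].
#' @param clamp Clamp boundary values into the open interval?
#' @param eps Clamping epsilon.
#' @return Numeric vector of M-values.
#' @seealso [m_to_beta()]
#' @examples
#' beta_to_m(c(0.5, 0.8)) # 0 and 2
#' @export
beta_to_m <- function(beta, clamp = TRUE, eps = 1e-6) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1))) {
    abort_value("Beta values must lie in [0, 1].")
  }
  if (!clamp && any(beta %in% c(0, 1))) {
    abort_value("Beta values of exactly 0 or 1 have no finite M-value; enable `clamp`.")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`.
#'
#' @param m Numeric vector of M-values.
#' @return Numeric vector of beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

# Canonical column order for probe screen tables.
screen_table_cols <- c(
  "probe_id", "mse_mz", "mse_dz", "mse_rz", "norm_mz", "norm_dz",
  "variance", "beta_range", "n_complete_mz", "n_complete_dz",
  "is_top_variance", "is_low_support", "is_ess", "is_negative_control"
)

#' Write a probe screen table
#'
#' Writes per-probe screen records (as produced by [ess_screen()]) to a TSV
#' with a deterministic column order, so that written files re-read with
#' [read_screen_table()] compare equal.
#'
#' @param records Data frame of probe screen records.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_screen_table <- function(records, path) {
  if (!is.data.frame(records)) abort_format("`records` must be a data frame.")
  if (!"probe_id" %in% names(records)) {
    abort_format("Screen records must have a `probe_id` column.")
  }
  known <- intersect(screen_table_cols, names(records))
  extra <- sort(setdiff(names(records), screen_table_cols))
  out <- records[, c(known, extra), drop = FALSE]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(records)
}

#' Read a probe screen table written by [write_screen_table()]
#'
#' @param path Path to a screen table TSV.
#' @return A tibble of probe screen records.
#' @export
read_screen_table <- function(path) {
  if (!file.exists(path)) abort_value(sprintf("File not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"),
                       progress = FALSE)
  if (!"probe_id" %in% names(x)) abort_format("Screen table lacks `probe_id`.")
  x$probe_id <- as.character(x$probe_id)
  for (col in intersect(c("is_top_variance", "is_low_support", "is_ess",
                          "is_negative_control"), names(x))) {
    x[[col]] <- as.logical(x[[col]])
  }
  tibble::as_tibble(x)
}
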