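# Season-of-conception EWAS: robust per-probe regression with covariates,
# FDR-based SoC-DMP calls, and enrichment of probe sets for SoC-DMPs.

#' Assign a Gambian season of conception
#'
#' Maps conception dates to the peak dry season (February-April), the peak
#' rainy season (July-September), or `OUT_OF_WINDOW` (excluded from
#' analysis). When only birth dates are available, conception is imputed as
#' `gestation_days` (default 280, a full term) before birth.
#'
#' @param dates `Date` vector, or strings parseable as `%Y-%m-%d`.
#' @param from_birth Are `dates` birth dates? If so the gestation offset is
#'   subtracted first.
#' @param gestation_days Gestation offset in days (default 280).
#' @return Character vector with values `"DRY"`, `"RAINY"`,
#'   `"OUT_OF_WINDOW"`.
#' @examples
#' assign_season(as.Date("2010-08-01")) # RAINY
#' assign_season("2011-01-15", from_birth = TRUE) # conceived 2010-04-10, DRY
#' @export
assign_season <- function(dates, from_birth = FALSE, gestation_days = 280) {
  d <- tryCatch(as.Date(dates), error = function(e) {
    abort_value("Could not parse `dates` as dates.")
  })
  if (any(is.na(d) & !is.na(dates))) abort_value("Could not parse some `dates`.")
  if (from_birth) d <- d - gestation_days
  mon <- as.integer(format(d, "%m"))
  out <- rep("OUT_OF_WINDOW", length(d))
  out[mon %in% 2:4] <- "DRY"
  out[mon %in% 7:9] <- "RAINY"
  out[is.na(d)] <- NA_character_
  out
}

#' Robust (Huber M-estimation) linear fit for one probe
#'
#' Iteratively reweighted least squares with the Huber loss (tuning constant
#' 1.345 times the MAD-based robust scale, the standard 95%-efficiency
#' default), via [MASS::rlm()]. Accounts for heteroscedasticity and
#' influential outliers in per-probe methylation regressions. Coefficient
#' p-values use a normal reference on the robust t-statistics. A constant
#' response returns zero for every non-intercept coefficient with `NA`
#' p-values; non-convergence is flagged, not an error.
#'
#' @param y Numeric response (per-sample beta at one probe).
#' @param x Numeric design matrix of covariates, without intercept (one is
#'   added).
#' @param maxit Maximum IRLS iterations (default 50).
#' @param acc Convergence tolerance on the coefficient updates.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, and a logical `converged` attribute.
#' @export
robust_fit <- function(y, x, maxit = 50, acc = 1e-8) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  keep <- stats::complete.cases(cbind(y, x))
  y <- y[keep]
  x <- x[keep, , drop = FALSE]
  n <- length(y)
  p <- ncol(x) + 1L
  if (n <= p + 2) {
    rlang::abort("Need more observations than coefficients + 2.",
                 class = "essiv_error_argument")
  }
  xmat <- cbind(`(Intercept)` = 1, x)
  if (stats::sd(y) == 0) {
    # Degenerate response: OLS limit, all non-intercept coefficients zero.
    out <- tibble::tibble(
      term = colnames(xmat),
      estimate = c(y[1], rep(0, p - 1L)),
      std_error = NA_real_, statistic = NA_real_, p_value = NA_real_
    )
    attr(out, "converged") <- TRUE
    return(out)
  }
  fit <- MASS::rlm(xmat, y, psi = MASS::psi.huber, k = 1.345,
                   maxit = maxit, acc = acc)
  sm <- summary(fit, method = "XtX")$coefficients
  est <- sm[, "Value"]
  se <- sm[, "Std. Error"]
  stat <- est / se
  out <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(stat),
    p_value = 2 * stats::pnorm(-abs(unname(stat)))
  )
  attr(out, "converged") <- fit$converged
  out
}

# Build the season + covariate design matrix from a design tibble.
soc_design_matrix <- function(design) {
  if (!all(c("sample_id", "season") %in% names(design))) {
    abort_format("`design` must have `sample_id` and `season` columns.")
  }
  if (anyNA(design$season)) abort_value("`season` must be non-missing.")
  if (!all(design$season %in% c("DRY", "RAINY"))) {
    abort_value("`season` must be DRY or RAINY (drop OUT_OF_WINDOW samples first).")
  }
  covs <- setdiff(names(design), c("sample_id", "season"))
  x <- cbind(season = as.numeric(design$season == "RAINY"),
             as.matrix(design[covs]))
  storage.mode(x) <- "double"
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1L) {
    abort_degenerate("Design (season + covariates) is not of full rank.")
  }
  x
}

#' Season-of-conception EWAS scan
#'
#' Fits, for every probe, a robust linear regression of beta on season of
#' conception adjusted for every other column of `design` (sex, principal
#' components, cell-type proportions, ...), then applies Benjamini-Hochberg
#' FDR across all tested probes. Probes with adjusted `q < fdr` are called
#' season-of-conception differentially methylated probes (SoC-DMPs). The
#' `effect` column is the adjusted RAINY-minus-DRY difference in beta.
#'
#' @param beta Beta tibble.
#' @param design Data frame with `sample_id`, `season` (`"DRY"`/`"RAINY"`),
#'   and numeric covariate columns; must cover the samples of `beta`.
#' @param fdr SoC-DMP threshold on the adjusted q-value (default 0.10).
#' @return Tibble with `probe_id`, `effect`, `std_error`, `statistic`,
#'   `p_value`, `q_value`, `is_dmp`, `converged`.
#' @seealso [robust_fit()], [soc_enrichment()]
#' @export
soc_scan <- function(beta, design, fdr = 0.10) {
  check_beta_tbl(beta)
  samples <- setdiff(names(beta), "probe_id")
  if (!all(samples %in% design$sample_id)) {
    abort_value("Every sample in `beta` must appear in `design`.")
  }
  design <- design[match(samples, design$sample_id), , drop = FALSE]
  x <- soc_design_matrix(design)
  m <- beta_matrix(beta)
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    fit <- robust_fit(m[i, ], x)
    row <- fit[fit$term == "season", ]
    tibble::tibble(effect = row$estimate, std_error = row$std_error,
                   statistic = row$statistic, p_value = row$p_value,
                   converged = attr(fit, "converged"))
  })
  res <- dplyr::bind_cols(tibble::tibble(probe_id = beta$probe_id), res)
  res$p_value[!res$converged] <- NA_real_
  res$q_value <- bh_fdr(res$p_value)
  res$is_dmp <- !is.na(res$q_value) & res$q_value < fdr
  res
}

#' Enrichment of a probe set for SoC-DMPs
#'
#' Tests whether a probe set (e.g. ESS or SIV probes) contains more SoC-DMPs
#' than expected given the DMP rate in a caller-specified background
#' universe. The fold is taken against the whole background ("relative to
#' all probes"); the Fisher p-value partitions the background into set and
#' non-set probes.
#'
#' @param results Output of [soc_scan()] (needs `probe_id`, `is_dmp`).
#' @param probe_set Character vector of probe IDs; must be a subset of
#'   `background`.
#' @param background Character vector of all eligible probe IDs.
#' @return One-row tibble with the table counts, `fold` and `fisher_p`.
#' @export
soc_enrichment <- function(results, probe_set, background) {
  if (length(probe_set) == 0) {
    rlang::abort("`probe_set` must be non-empty.", class = "essiv_error_argument")
  }
  dmp <- results$probe_id[results$is_dmp]
  out <- enrich_test(probe_set, dmp, background, fold_base = "background")
  out[c("a", "b", "c", "d", "fold", "fisher_p")]
}
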