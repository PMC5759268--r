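# Genotype-methylation association: mQTL regression, Bartlett
# variance-heterogeneity testing, and the substantial-mQTL flag.

#' Methylation-on-genotype linear regression (mQTL)
#'
#' Ordinary least squares of locus-average methylation on additively coded
#' allele count (0/1/2). The model R-squared is the internally estimated
#' fraction of methylation variance explained by the genotype, comparable to
#' (but labelled distinctly from) an externally supplied `beta_snp`.
#'
#' @param data Data frame with a numeric allele-count column and a
#'   methylation column in \[0, 1\].
#' @param genotype,methylation Column names (default `"genotype"`,
#'   `"avg_methylation"`).
#' @return An object of class `mqtl_fit` with elements `slope`, `intercept`,
#'   `p_value`, `r_squared`, `n`, and the underlying `lm` fit. Has
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()]
#'   methods.
#' @export
mqtl_regression <- function(data, genotype = "genotype",
                            methylation = "avg_methylation") {
  if (!is.data.frame(data) || !all(c(genotype, methylation) %in% names(data))) {
    abort_format(sprintf("`data` must have columns `%s` and `%s`.",
                         genotype, methylation))
  }
  g <- data[[genotype]]
  y <- data[[methylation]]
  keep <- !is.na(g) & !is.na(y)
  g <- as.numeric(g[keep])
  y <- y[keep]
  if (length(y) < 3) {
    rlang::abort("Need at least 3 samples.", class = "essiv_error_argument")
  }
  if (any(y < 0 | y > 1)) abort_value("Methylation values must lie in [0, 1].")
  if (length(unique(g)) < 2) {
    abort_degenerate("All samples share one genotype class; regression is degenerate.")
  }
  fit <- stats::lm(y ~ g)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    p_value = unname(sm$coefficients[2, 4]),
    r_squared = sm$r.squared,
    n = length(y),
    fit = fit,
    data = tibble::tibble(genotype = g, methylation = y)
  ), class = "mqtl_fit")
}

#' @export
print.mqtl_fit <- function(x, ...) {
  cat(sprintf("mQTL regression (n = %d): slope %.4f, R^2 = %.3f, p = %.3g\n",
              x$n, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' Variance heterogeneity between genotype classes (Bartlett's test)
#'
#' Tests whether interindividual methylation variance differs between
#' genotype classes -- the signature of genotype-dependent metastability,
#' where one haplotype permits the stochastic epigenotype and another pins
#' it. By default all classes present are compared; pass `classes` to
#' restrict, e.g. to the two homozygote classes.
#'
#' @inheritParams mqtl_regression
#' @param classes Optional subset of genotype classes to compare.
#' @return One-row tibble with `statistic` (Bartlett's K-squared), `df`,
#'   `p_value`, `n_groups`.
#' @export
variance_heterogeneity <- function(data, genotype = "genotype",
                                   methylation = "avg_methylation",
                                   classes = NULL) {
  if (!is.data.frame(data) || !all(c(genotype, methylation) %in% names(data))) {
    abort_format(sprintf("`data` must have columns `%s` and `%s`.",
                         genotype, methylation))
  }
  g <- data[[genotype]]
  y <- data[[methylation]]
  keep <- !is.na(g) & !is.na(y)
  g <- g[keep]
  y <- y[keep]
  if (!is.null(classes)) {
    keep <- g %in% classes
    g <- g[keep]
    y <- y[keep]
  }
  g <- factor(g)
  if (nlevels(g) < 2) {
    rlang::abort("Need at least 2 genotype classes.",
                 class = "essiv_error_argument")
  }
  sizes <- tapply(y, g, length)
  vars <- tapply(y, g, stats::var)
  if (any(sizes < 2)) {
    rlang::abort("Every genotype class needs at least 2 observations.",
                 class = "essiv_error_argument")
  }
  if (any(vars == 0)) {
    abort_degenerate(paste(
      "Zero within-class variance; Bartlett's test is undefined.",
      "Consider a non-parametric alternative (e.g. Fligner-Killeen)."
    ))
  }
  bt <- stats::bartlett.test(y, g)
  tibble::tibble(
    statistic = unname(bt$statistic),
    df = unname(bt$parameter),
    p_value = bt$p.value,
    n_groups = nlevels(g)
  )
}

#' Flag substantial mQTL from externally supplied variance explained
#'
#' A probe shows substantial mQTL when the externally estimated fraction of
#' methylation variance explained by neighbouring SNPs strictly exceeds the
#' threshold. Missing values yield `NA` (neither positive nor negative).
#'
#' @param beta_snp Numeric vector of variance-explained fractions in \[0, 1\].
#' @param threshold Strict threshold (default 0.33).
#' @return Logical vector (with `NA` where `beta_snp` is missing).
#' @export
flag_substantial_mqtl <- function(beta_snp, threshold = 0.33) {
  if (any(!is.na(beta_snp) & (beta_snp < 0 | beta_snp > 1))) {
    abort_value("`beta_snp` values must lie in [0, 1].")
  }
  beta_snp > threshold
}
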