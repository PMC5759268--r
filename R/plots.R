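# ggplot2 visualisations of the screen and association results.

#' Plot the twin concordance screen
#'
#' Normalized DZ MSE against normalized MZ MSE, one point per probe, with the
#' `y = ratio_min * x` classification line; ESS probes fall to its left.
#'
#' @param records Screen records from [ess_screen()].
#' @param ratio_min Slope of the classification line (default 2).
#' @return A ggplot object.
#' @export
plot_ess_screen <- function(records, ratio_min = 2) {
  records <- records[!is.na(records$norm_mz) & !is.na(records$norm_dz), ]
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$norm_mz, y = .data$norm_dz,
                               colour = .data$is_ess)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = ratio_min, intercept = 0,
                         colour = "darkgreen", linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 name = "ESS") +
    ggplot2::labs(x = "Normalized MZ MSE (MZ/RZ)",
                  y = "Normalized DZ MSE (DZ/RZ)") +
    ggplot2::theme_minimal()
}

#' Plot the SIV screen
#'
#' Tissue-specific against interindividual variation with the two cutoff
#' lines; SIV probes fall in the lower-right region.
#'
#' @param records Records from [siv_screen()].
#' @param inter_min,tissue_ratio_max Cutoffs to draw (defaults 0.2 and 1/3).
#' @return A ggplot object.
#' @export
plot_siv_screen <- function(records, inter_min = 0.2, tissue_ratio_max = 1 / 3) {
  records <- records[!is.na(records$interindividual_var), ]
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$interindividual_var,
                               y = .data$tissue_var,
                               colour = .data$is_siv)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = inter_min, colour = "darkgreen", linetype = 2) +
    ggplot2::geom_abline(slope = tissue_ratio_max, intercept = 0,
                         colour = "darkgreen", linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "royalblue"),
                                 name = "SIV") +
    ggplot2::labs(x = "Interindividual variation (delta-beta)",
                  y = "Tissue-specific variation (delta-beta)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a season-of-conception scan
#'
#' Adjusted RAINY-minus-DRY effect against -log10 p, DMPs highlighted.
#'
#' @param results Output of [soc_scan()].
#' @return A ggplot object.
#' @export
plot_soc_results <- function(results) {
  results <- results[!is.na(results$p_value), ]
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$effect,
                               y = -log10(.data$p_value),
                               colour = .data$is_dmp)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "darkorange"),
                                 name = "SoC-DMP") +
    ggplot2::labs(x = "Effect of rainy-season conception (delta-beta)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Signed Manhattan-style plot of per-probe case-control associations
#'
#' Plots sign(coefficient) * -log10(p) by genomic position for each cancer
#' type, the standard display for cluster-level methylation-risk scans.
#'
#' @param x A `cluster_perm` object (or its `probe_results` tibble).
#' @param annotation Probe annotation with `probe_id`, `chrom`, `position`.
#' @return A ggplot object.
#' @export
plot_cluster_manhattan <- function(x, annotation) {
  pr <- if (inherits(x, "cluster_perm")) x$probe_results else x
  df <- dplyr::inner_join(pr, annotation[c("probe_id", "chrom", "position")],
                          by = "probe_id")
  df <- df[!is.na(df$p_value), ]
  df$signed_logp <- sign(df$estimate) * -log10(pmax(df$p_value, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$signed_logp)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::facet_grid(.data$cancer_type ~ .data$chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (bp)",
                  y = expression(sign(beta) %.% -log[10](p))) +
    ggplot2::theme_minimal()
}

#' @rdname mqtl_regression
#' @param object An `mqtl_fit` object.
#' @param ... Unused.
#' @export
autoplot.mqtl_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$genotype, y = .data$methylation)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::scale_x_continuous(breaks = 0:2) +
    ggplot2::labs(x = "Allele count", y = "Average methylation (beta)") +
    ggplot2::theme_minimal()
}
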