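# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an mQTL regression
#'
#' @param x An `mqtl_fit` object.
#' @param ... Unused.
#' @return One row per model term with `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @export
tidy.mqtl_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "genotype"),
    estimate = unname(sm[, 1]),
    std_error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p_value = unname(sm[, 4])
  )
}

#' Glance at an mQTL regression
#'
#' @inheritParams tidy.mqtl_fit
#' @return One-row tibble with `r_squared`, `p_value`, `n`.
#' @export
glance.mqtl_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value, n = x$n)
}

#' Tidy a conditional logistic regression fit
#'
#' @param x A `clr_fit` object.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`).
#' @export
tidy.clr_fit <- function(x, ...) {
  x$coefficients
}

#' Glance at a conditional logistic regression fit
#'
#' @inheritParams tidy.clr_fit
#' @return One-row tibble with `n_pairs`, `n_informative`, `converged`,
#'   `separated`.
#' @export
glance.clr_fit <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, n_informative = x$n_informative,
                 converged = x$converged, separated = x$separated)
}

#' Tidy a cluster permutation test
#'
#' @param x A `cluster_perm` object.
#' @param ... Unused.
#' @return The per-cluster results tibble.
#' @export
tidy.cluster_perm <- function(x, ...) {
  x$cluster_results
}

#' Glance at a cluster permutation test
#'
#' @inheritParams tidy.cluster_perm
#' @return One-row tibble with `n_clusters`, `n_cancer_types`,
#'   `n_permutations`, `alpha`, `seed`.
#' @export
glance.cluster_perm <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_cancer_types = length(unique(x$cluster_results$cancer_type)),
    n_permutations = x$n_perm,
    alpha = x$alpha,
    seed = x$seed
  )
}

#' Tidy an inter-tissue SIV call
#'
#' @param x A `siv_call` object.
#' @param ... Unused.
#' @return The pairwise correlation tibble.
#' @export
tidy.siv_call <- function(x, ...) {
  x$pairs
}
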