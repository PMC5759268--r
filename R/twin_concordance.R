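# The ESS screen: per-probe twin-pair MSE, randomized-pair (RZ) normalization,
# variance/range filters, ESS classification and the normalized-MSE
# distribution statistics.

check_pairs <- function(pairs) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0) {
    rlang::abort("`pairs` must be a non-empty data frame.",
                 class = "essiv_error_argument")
  }
  if (!all(c("sample_a", "sample_b") %in% names(pairs))) {
    abort_format("`pairs` must have `sample_a` and `sample_b` columns.")
  }
  ids <- c(pairs$sample_a, pairs$sample_b)
  if (anyDuplicated(ids)) {
    abort_format("A sample appears more than once within a pair set.")
  }
  invisible(pairs)
}

#' Per-probe mean squared error between pair members
#'
#' For each probe, the mean over pairs of the squared within-pair beta
#' difference -- the deviation of the pairs from the line of identity, a
#' direct measure of twin discordance. A pair contributes to a probe only
#' when both members are observed; probes with no complete pair get `NA`.
#'
#' @param beta Beta tibble (`probe_id` + one column per sample).
#' @param pairs Data frame with `sample_a`, `sample_b` columns naming samples
#'   present in `beta`.
#' @return Tibble with `probe_id`, `mse`, and `n_complete` (pairs with both
#'   members observed).
#' @examples
#' b <- tibble::tibble(probe_id = "cg1", s1 = 0.2, s2 = 0.2, s3 = 0.4, s4 = 0.6)
#' p <- tibble::tibble(sample_a = c("s1", "s3"), sample_b = c("s2", "s4"))
#' pair_mse(b, p) # (0 + 0.04) / 2 = 0.02
#' @export
pair_mse <- function(beta, pairs) {
  check_beta_tbl(beta)
  check_pairs(pairs)
  check_samples_present(beta, c(pairs$sample_a, pairs$sample_b))
  m <- beta_matrix(beta)
  d2 <- (m[, pairs$sample_a, drop = FALSE] - m[, pairs$sample_b, drop = FALSE])^2
  n_complete <- rowSums(!is.na(d2))
  mse <- rowMeans(d2, na.rm = TRUE)
  mse[n_complete == 0] <- NA_real_
  tibble::tibble(probe_id = beta$probe_id, mse = unname(mse),
                 n_complete = as.integer(n_complete))
}

#' Randomly pair samples to simulate unrelated individuals (RZ pairs)
#'
#' Draws a perfect matching on a random permutation of the pooled samples;
#' with an odd number of samples the left-over sample is dropped. Used to
#' normalize twin MSEs against the pairwise MSE expected in the general
#' population.
#'
#' @param sample_ids Character vector of at least two sample IDs.
#' @param seed Integer seed; the pairing is deterministic per seed.
#' @return Tibble with `pair_id`, `sample_a`, `sample_b`, `pair_class = "RZ"`.
#' @export
make_randomized_pairs <- function(sample_ids, seed) {
  if (length(sample_ids) < 2) {
    rlang::abort("Need at least two samples to form randomized pairs.",
                 class = "essiv_error_argument")
  }
  with_seed(seed, {
    perm <- sample(sample_ids)
    n <- length(perm) %/% 2
    tibble::tibble(
      pair_id = sprintf("rz%03d", seq_len(n)),
      sample_a = perm[2 * seq_len(n) - 1],
      sample_b = perm[2 * seq_len(n)],
      pair_class = "RZ"
    )
  })
}

#' Select the highest-variance probes
#'
#' Returns the probes whose population variance (over all samples, pairwise
#' complete) ranks within the top `ceiling(fraction * P)`, ties broken by
#' probe ID in lexicographic order. All-missing probes are excluded with a
#' warning.
#'
#' @inheritParams pair_mse
#' @param fraction Fraction of probes to keep, in (0, 1\]; default 0.1, the
#'   conventional "top 10% by interindividual variance" screen.
#' @return Character vector of selected probe IDs.
#' @export
top_variance_filter <- function(beta, fraction = 0.1) {
  check_beta_tbl(beta)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort_config("`fraction` must be in (0, 1].")
  }
  m <- beta_matrix(beta)
  v <- apply(m, 1, pop_var)
  if (anyNA(v)) {
    rlang::warn(sprintf("%d all-missing probe(s) excluded from variance ranking.",
                        sum(is.na(v))))
  }
  keep <- !is.na(v)
  ids <- beta$probe_id[keep]
  v <- v[keep]
  k <- ceiling(fraction * length(ids))
  ord <- order(-v, ids)
  sort(ids[ord[seq_len(min(k, length(ids)))]])
}

#' Classify probes as epigenetically supersimilar (ESS)
#'
#' A probe is ESS when its DZ/MZ normalized-MSE ratio exceeds `ratio_min`
#' (strictly), its interindividual beta range exceeds `range_min` (strictly),
#' and its MZ/RZ normalized MSE does not exceed `mz_rz_max` (probes above
#' that are too discordant even within MZ pairs to be meaningful). A probe
#' with `norm_mz == 0` and `norm_dz > 0` is maximal ESS (infinite ratio);
#' a probe with both zero carries no discordance signal and is not flagged.
#'
#' @param records Data frame with columns `norm_mz`, `norm_dz`, `beta_range`
#'   (e.g. from [ess_screen()]).
#' @param ratio_min Minimum DZ/MZ normalized-MSE ratio (default 2: twice the
#'   similarity genetic identity alone predicts).
#' @param range_min Minimum interindividual beta range (default 0.4).
#' @param mz_rz_max Maximum MZ/RZ normalized MSE (default 0.5).
#' @return Logical vector, one element per record row.
#' @export
classify_ess <- function(records, ratio_min = 2, range_min = 0.4, mz_rz_max = 0.5) {
  need <- c("norm_mz", "norm_dz", "beta_range")
  if (!all(need %in% names(records))) {
    abort_format(sprintf("`records` must have columns: %s.",
                         paste(need, collapse = ", ")))
  }
  ratio <- records$norm_dz / records$norm_mz
  ratio[records$norm_mz == 0 & records$norm_dz > 0] <- Inf
  out <- ratio > ratio_min &
    records$beta_range > range_min &
    records$norm_mz <= mz_rz_max
  out[is.na(out) | is.nan(ratio)] <- FALSE
  out
}

#' Run the full per-probe twin concordance (ESS) screen
#'
#' Computes MZ, DZ and RZ mean squared errors per probe, normalizes the twin
#' MSEs by the RZ MSE, computes the pooled-population variance and beta range,
#' flags the top-variance subset, and classifies ESS probes. The RZ pairing
#' pools all MZ and DZ samples; set `k_rz > 1` to average the RZ MSE over
#' several independent re-pairings for variance reduction.
#'
#' @inheritParams pair_mse
#' @param pairs Data frame with `sample_a`, `sample_b` and a `pair_class`
#'   column containing `"MZ"` and `"DZ"`.
#' @param rz_seed Seed for the randomized pairing.
#' @param k_rz Number of RZ re-pairings to average (default 1, a single
#'   randomization).
#' @param top_fraction Fraction for [top_variance_filter()].
#' @param min_pairs Probes with fewer complete pairs than this in any twin
#'   class are flagged `is_low_support`.
#' @inheritParams classify_ess
#' @return A tibble of per-probe screen records with columns `probe_id`,
#'   `mse_mz`, `mse_dz`, `mse_rz`, `norm_mz`, `norm_dz`, `variance`,
#'   `beta_range`, `n_complete_mz`, `n_complete_dz`, `is_top_variance`,
#'   `is_low_support`, `is_ess`.
#' @seealso [classify_ess()], [plot_ess_screen()], [select_negative_controls()]
#' @export
ess_screen <- function(beta, pairs, rz_seed, k_rz = 1,
                       top_fraction = 0.1, ratio_min = 2, range_min = 0.4,
                       mz_rz_max = 0.5, min_pairs = 10) {
  check_beta_tbl(beta)
  check_pairs(pairs)
  if (!"pair_class" %in% names(pairs)) {
    abort_format("`pairs` must have a `pair_class` column with MZ and DZ pairs.")
  }
  mz <- pairs[pairs$pair_class == "MZ", , drop = FALSE]
  dz <- pairs[pairs$pair_class == "DZ", , drop = FALSE]
  if (nrow(mz) == 0 || nrow(dz) == 0) {
    rlang::abort("Need at least one MZ and one DZ pair.",
                 class = "essiv_error_argument")
  }
  pooled <- c(mz$sample_a, mz$sample_b, dz$sample_a, dz$sample_b)
  check_samples_present(beta, pooled)

  res_mz <- pair_mse(beta, mz)
  res_dz <- pair_mse(beta, dz)
  mse_rz <- rep(0, nrow(beta))
  for (k in seq_len(k_rz)) {
    rz <- make_randomized_pairs(pooled, seed = rz_seed + (k - 1L))
    mse_rz <- mse_rz + pair_mse(beta, rz)$mse / k_rz
  }

  m <- beta_matrix(beta)[, pooled, drop = FALSE]
  variance <- apply(m, 1, pop_var)
  rng <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else max(x) - min(x)
  })

  records <- tibble::tibble(
    probe_id = beta$probe_id,
    mse_mz = res_mz$mse, mse_dz = res_dz$mse, mse_rz = mse_rz,
    norm_mz = ifelse(mse_rz > 0, res_mz$mse / mse_rz, NA_real_),
    norm_dz = ifelse(mse_rz > 0, res_dz$mse / mse_rz, NA_real_),
    variance = unname(variance),
    beta_range = unname(rng),
    n_complete_mz = res_mz$n_complete,
    n_complete_dz = res_dz$n_complete
  )
  top <- top_variance_filter(beta, top_fraction)
  records$is_top_variance <- records$probe_id %in% top
  records$is_low_support <- records$n_complete_mz < min_pairs |
    records$n_complete_dz < min_pairs
  records$is_ess <- classify_ess(records, ratio_min = ratio_min,
                                 range_min = range_min, mz_rz_max = mz_rz_max)
  records
}

#' Locus-average DZ/MZ MSE fold
#'
#' The ratio of the DZ to the MZ mean squared error, each averaged over the
#' probes of a locus -- the locus-level discordance fold shown alongside
#' candidate metastable epialleles.
#'
#' @inheritParams pair_mse
#' @param probe_ids Probes constituting the locus.
#' @param mz_pairs,dz_pairs Pair tables for the two twin classes.
#' @return A single positive number; `Inf` when the MZ MSE is zero.
#' @export
locus_mse_fold <- function(beta, probe_ids, mz_pairs, dz_pairs) {
  if (length(probe_ids) < 1) {
    rlang::abort("`probe_ids` must name at least one probe.",
                 class = "essiv_error_argument")
  }
  sub <- beta[beta$probe_id %in% probe_ids, , drop = FALSE]
  if (nrow(sub) != length(unique(probe_ids))) {
    abort_value("Some `probe_ids` are not present in the methylation data.")
  }
  mz <- mean(pair_mse(sub, mz_pairs)$mse, na.rm = TRUE)
  dz <- mean(pair_mse(sub, dz_pairs)$mse, na.rm = TRUE)
  if (mz == 0) return(Inf)
  dz / mz
}

# D'Agostino (1970) transformation of sample skewness to an approximately
# standard normal statistic.
dagostino_z <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  delta * asinh(y / alpha)
}

#' Moments, left-skew test and per-value z-scores of normalized MSEs
#'
#' Under a purely genetic model of twin concordance the normalized MSEs
#' should be approximately normal; an excess of probes far below the mean
#' (left skew) is the population-level signature of epigenetic
#' supersimilarity. The skewness test is the moment-based D'Agostino
#' transformation, evaluated one-sided against the left-skew alternative
#' (small p means skewed left).
#'
#' @param values Numeric vector of normalized MSE values (at least 8, the
#'   minimum for the skewness approximation).
#' @return A list of class `mse_dist_stats` with elements `mean`, `sd`
#'   (sample sd), `skewness` (sample g1), `statistic` (D'Agostino z),
#'   `p_value` (one-sided, left), and `z` (per-value standard scores).
#' @export
mse_distribution_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 8) {
    rlang::abort("Need at least 8 values for the skewness test.",
                 class = "essiv_error_argument")
  }
  s <- stats::sd(values)
  if (s == 0) abort_degenerate("Degenerate distribution: all values identical.")
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  z_stat <- dagostino_z(values)
  structure(list(
    mean = mu,
    sd = s,
    skewness = m3 / m2^1.5,
    statistic = z_stat,
    p_value = stats::pnorm(z_stat),
    z = (values - mu) / s
  ), class = "mse_dist_stats")
}

#' @export
print.mse_dist_stats <- function(x, ...) {
  cat(sprintf("Normalized MSE: mean %.3f, sd %.3f, skewness %.3f\n",
              x$mean, x$sd, x$skewness))
  cat(sprintf("Left-skew test: z = %.3f, one-sided p = %.3g\n",
              x$statistic, x$p_value))
  cat(sprintf("%d values; %d more than 5 sd below the mean\n",
              length(x$z), sum(x$z < -5)))
  invisible(x)
}
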