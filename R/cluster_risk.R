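# Prospective cancer-risk framework: probe clustering, rank-normalized
# M-values, conditional logistic regression on 1:1 matched pairs,
# cluster-level events, permutation testing and FDR selection.

#' Group probes into positional clusters
#'
#' Single-linkage chaining along each chromosome: consecutive probes at most
#' `max_gap` bp apart (inclusive: "within 500 bp") join one cluster; chains
#' shorter than `min_size` probes are dropped.
#'
#' @param annotation Data frame with `probe_id`, `chrom`, `position`.
#' @param max_gap Maximum gap between consecutive cluster members (bp).
#' @param min_size Minimum probes per cluster (default 2).
#' @return Tibble with one row per cluster: `cluster_id`, `chrom`, `start`,
#'   `end`, `span`, `n_probes` and a `probe_ids` list-column ordered by
#'   position.
#' @export
build_clusters <- function(annotation, max_gap = 500, min_size = 2) {
  need <- c("probe_id", "chrom", "position")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation))) {
    abort_format(sprintf("`annotation` must have columns: %s.",
                         paste(need, collapse = ", ")))
  }
  ann <- dplyr::arrange(tibble::as_tibble(annotation[need]),
                        .data$chrom, .data$position, .data$probe_id)
  ann <- dplyr::group_by(ann, .data$chrom)
  ann <- dplyr::mutate(ann, new_chain = c(TRUE, diff(.data$position) > max_gap))
  ann <- dplyr::ungroup(ann)
  ann$chain <- cumsum(ann$new_chain)
  out <- dplyr::summarise(
    dplyr::group_by(ann, .data$chain),
    chrom = .data$chrom[1],
    start = min(.data$position),
    end = max(.data$position),
    n_probes = dplyr::n(),
    probe_ids = list(.data$probe_id),
    .groups = "drop"
  )
  out <- out[out$n_probes >= min_size, , drop = FALSE]
  tibble::tibble(
    cluster_id = sprintf("%s:%d-%d", out$chrom, out$start, out$end),
    chrom = out$chrom, start = out$start, end = out$end,
    span = out$end - out$start,
    n_probes = out$n_probes,
    probe_ids = out$probe_ids
  )
}

#' Rank-normalize a vector in ascending order
#'
#' Plain ascending ranks 1..N with average ranks for ties (no quantile
#' mapping), the distribution-free transform applied to per-probe M-values
#' across all samples before conditional logistic regression.
#'
#' @param values Numeric vector (at least 2 non-missing values).
#' @return Numeric vector of ranks (`NA` preserved).
#' @export
rank_normalize <- function(values) {
  if (sum(!is.na(values)) < 2) {
    rlang::abort("Need at least 2 non-missing values to rank.",
                 class = "essiv_error_argument")
  }
  rank(values, ties.method = "average", na.last = "keep")
}

# Core conditional-logistic fitter for 1:1 matched pairs: maximise the
# conditional likelihood, equivalent to intercept-free logistic regression of
# a constant positive outcome on the within-pair (case - control) covariate
# differences. Newton-Raphson; X is the n_pairs x p difference matrix.
# Returns estimates, standard errors and flags without ever erroring on
# degenerate inputs (the permutation engine must press on).
fit_clr_core <- function(x, maxit = 50, tol = 1e-10) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  informative <- rowSums(abs(x) > 0) > 0
  if (!any(informative)) {
    return(list(coef = rep(0, p), se = rep(NA_real_, p), converged = TRUE,
                separated = FALSE, n_informative = 0L))
  }
  # Standardize columns to unit max-abs for conditioning; Newton-Raphson is
  # affine-equivariant so the unscaled solution is recovered exactly.
  sc <- apply(abs(x), 2, max)
  sc[sc == 0] <- 1
  xs <- sweep(x, 2, sc, `/`)
  beta <- rep(0, p)
  converged <- FALSE
  info <- NULL
  mu <- rep(0.5, n)
  for (it in seq_len(maxit)) {
    eta <- drop(xs %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(xs, 1 - mu))
    info <- crossprod(xs * w, xs)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    step <- pmin(pmax(step, -5), 5) # damp huge steps near separation
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  # Separation: the conditional likelihood is maximized in the limit where
  # every informative pair is predicted perfectly (all fitted values -> 1).
  separated <- min(mu[informative]) > 1 - 1e-6 ||
    (!converged && any(abs(beta) > 20))
  se <- if (is.null(info)) rep(NA_real_, p) else {
    v <- tryCatch(diag(solve(info)), error = function(e) rep(NA_real_, p))
    sqrt(pmax(v, 0))
  }
  list(coef = beta / sc, se = se / sc, converged = converged,
       separated = separated, n_informative = sum(informative))
}

as_named_values <- function(exposure) {
  if (is.data.frame(exposure)) {
    if (!all(c("sample_id", "value") %in% names(exposure))) {
      abort_format("`exposure` data frame must have `sample_id` and `value`.")
    }
    stats::setNames(exposure$value, exposure$sample_id)
  } else if (!is.null(names(exposure))) {
    exposure
  } else {
    abort_format("`exposure` must be a named vector or a sample_id/value data frame.")
  }
}

# Within-pair (case - control) differences of the within-pair-varying columns
# of a covariate table. Zero-variance difference columns are dropped (they
# carry no conditional information).
covariate_diffs <- function(pairs, covariates) {
  if (is.null(covariates)) return(NULL)
  if (!"sample_id" %in% names(covariates)) {
    abort_format("`covariates` must have a `sample_id` column.")
  }
  cols <- setdiff(names(covariates), "sample_id")
  cm <- as.matrix(covariates[cols])
  storage.mode(cm) <- "double"
  rownames(cm) <- covariates$sample_id
  miss <- setdiff(c(pairs$case_id, pairs$control_id), rownames(cm))
  if (length(miss)) {
    abort_value(sprintf("Covariates missing for %d sample(s).", length(miss)))
  }
  d <- cm[pairs$case_id, , drop = FALSE] - cm[pairs$control_id, , drop = FALSE]
  keep <- apply(d, 2, function(v) any(v != 0))
  d <- d[, keep, drop = FALSE]
  if (ncol(d) == 0) return(NULL)
  # Drop linearly dependent columns (e.g. cell proportions summing to one),
  # keeping the pivoted-QR basis; dependent columns carry no extra information.
  qd <- qr(d)
  if (qd$rank < ncol(d)) {
    d <- d[, sort(qd$pivot[seq_len(qd$rank)]), drop = FALSE]
  }
  d
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximizes the conditional likelihood of case status given pair membership.
#' For 1:1 matching this is exactly intercept-free logistic regression of a
#' constant positive outcome on the within-pair (case minus control)
#' differences of the exposure and of any within-pair-varying covariates;
#' covariates constant within every pair (the matching variables) drop out of
#' the likelihood and are removed. Wald p-values use a normal reference.
#' With a single binary exposure the estimate is the classic
#' `log(n10 / n01)` of discordant-pair counts.
#'
#' @param pairs Data frame with `case_id` and `control_id` columns.
#' @param exposure Per-sample exposure: a named numeric vector or a data
#'   frame with `sample_id` and `value` (typically rank-normalized M-values
#'   at one probe).
#' @param covariates Optional per-sample covariate data frame (`sample_id` +
#'   numeric columns).
#' @param min_informative Minimum number of pairs with any within-pair
#'   difference (default 10) before the fit is attempted without a warning.
#' @return Object of class `clr_fit`: a list with `coefficients` (tibble of
#'   `term`, `estimate`, `std_error`, `statistic`, `p_value`), `n_pairs`,
#'   `n_informative`, `separated`, `converged`. Exposure identical within
#'   every pair yields a zero coefficient with p = 1; separation yields `NA`
#'   estimates/p-values with `separated = TRUE`.
#' @export
clr_fit <- function(pairs, exposure, covariates = NULL, min_informative = 10) {
  if (!is.data.frame(pairs) || !all(c("case_id", "control_id") %in% names(pairs))) {
    abort_format("`pairs` must have `case_id` and `control_id` columns.")
  }
  ids <- c(pairs$case_id, pairs$control_id)
  if (anyDuplicated(ids)) abort_format("Each sample may belong to exactly one pair.")
  ev <- as_named_values(exposure)
  miss <- setdiff(ids, names(ev))
  if (length(miss)) abort_value("Exposure values missing for some pair members.")
  d_exp <- unname(ev[pairs$case_id] - ev[pairs$control_id])
  d_cov <- covariate_diffs(pairs, covariates)
  x <- cbind(exposure = d_exp, d_cov)
  informative <- sum(rowSums(abs(x) > 0) > 0)
  if (informative == 0 && nrow(pairs) > 0 && all(d_exp == 0) && is.null(d_cov)) {
    # exposure identical within every pair: no conditional information
    co <- tibble::tibble(term = "exposure", estimate = 0, std_error = NA_real_,
                         statistic = NA_real_, p_value = 1)
    return(structure(list(coefficients = co, n_pairs = nrow(pairs),
                          n_informative = 0L, separated = FALSE,
                          converged = TRUE),
                     class = "clr_fit"))
  }
  if (informative < min_informative) {
    rlang::warn(sprintf("Only %d informative pair(s); estimates may be unstable.",
                        informative))
  }
  fit <- fit_clr_core(x)
  est <- unname(fit$coef)
  se <- unname(fit$se)
  if (fit$separated) {
    est <- rep(NA_real_, length(est))
    se <- rep(NA_real_, length(se))
  }
  stat <- est / se
  co <- tibble::tibble(
    term = colnames(x),
    estimate = est,
    std_error = se,
    statistic = stat,
    p_value = 2 * stats::pnorm(-abs(stat))
  )
  structure(list(coefficients = co, n_pairs = nrow(pairs),
                 n_informative = fit$n_informative,
                 separated = fit$separated, converged = fit$converged),
            class = "clr_fit")
}

#' @export
print.clr_fit <- function(x, ...) {
  cat(sprintf("Conditional logistic regression: %d pairs (%d informative)%s\n",
              x$n_pairs, x$n_informative,
              if (x$separated) " [separated]" else ""))
  print(x$coefficients)
  invisible(x)
}

# Lean internal version of cluster_events over plain vectors, used inside the
# permutation loop: returns per-cluster concordant significant counts and
# minimum p-values.
events_from_vectors <- function(estimate, p, probe_index, alpha) {
  n_sig <- integer(length(probe_index))
  p_min <- rep(NA_real_, length(probe_index))
  for (ci in seq_along(probe_index)) {
    idx <- probe_index[[ci]]
    pv <- p[idx]
    ev <- estimate[idx]
    ok <- !is.na(pv)
    if (any(ok)) p_min[ci] <- min(pv[ok])
    sig <- ok & pv < alpha
    n_sig[ci] <- max(sum(sig & ev > 0, na.rm = TRUE),
                     sum(sig & ev < 0, na.rm = TRUE))
  }
  list(n_sig = n_sig, p_min = p_min)
}

#' Cluster-level events from per-probe association results
#'
#' `n_sig` is the number of significant probes (p below `alpha`) with
#' concordant coefficients, operationalized as the larger of the two
#' same-sign counts among significant probes; `p_min` is the minimum
#' probe-level p in the cluster. All-missing p-values yield `n_sig = 0` and
#' `p_min = NA`.
#'
#' @param probe_results Data frame with `estimate` and `p_value` for the
#'   probes of one cluster.
#' @param alpha Probe-level significance threshold (default 0.05).
#' @return One-row tibble with `n_sig` and `p_min`.
#' @export
cluster_events <- function(probe_results, alpha = 0.05) {
  p <- probe_results$p_value
  est <- probe_results$estimate
  ok <- !is.na(p)
  sig <- ok & p < alpha
  n_sig <- max(sum(sig & est > 0, na.rm = TRUE),
               sum(sig & est < 0, na.rm = TRUE))
  p_min <- if (any(ok)) min(p[ok]) else NA_real_
  tibble::tibble(n_sig = as.integer(n_sig), p_min = p_min)
}

#' Recurrence of a cluster across cancer types
#'
#' The number of cancer types in which the cluster contains at least
#' `min_probes` significant probes with concordant coefficients.
#'
#' @param n_by_type Integer vector of per-type concordant significant-probe
#'   counts (`n_sig` from [cluster_events()]).
#' @param min_probes Minimum count per type (default 2).
#' @return A single integer.
#' @export
recurrence <- function(n_by_type, min_probes = 2) {
  if (length(n_by_type) == 0) {
    rlang::abort("Need at least one cancer type.", class = "essiv_error_argument")
  }
  sum(n_by_type >= min_probes, na.rm = TRUE)
}

# Rao score test of the conditional likelihood for the exposure of every
# probe at once, at exposure coefficient zero with nuisance (covariate)
# coefficients profiled out under the null. `e_diff` is pairs x probes,
# `d_cov` pairs x p or NULL, `s` the per-pair case/control sign flips.
# Always defined (unlike the Wald test under separation), which makes it the
# probe-level statistic of the permutation engine; asymptotically equivalent
# to the Wald test away from separation.
clr_score_stats <- function(e_diff, d_cov, s) {
  if (is.null(d_cov)) {
    u <- drop(crossprod(e_diff, s)) / 2
    v <- colSums(e_diff^2) / 4
  } else {
    ds <- d_cov * s
    f0 <- fit_clr_core(ds)
    mu0 <- stats::plogis(drop(ds %*% f0$coef))
    w0 <- mu0 * (1 - mu0)
    if (all(w0 < 1e-12)) {
      # covariates alone predict perfectly: no residual information
      n <- ncol(e_diff)
      return(list(z = rep(NA_real_, n), p = rep(NA_real_, n)))
    }
    u <- drop(crossprod(e_diff, s * (1 - mu0)))
    v_diag <- drop(crossprod(e_diff^2, w0))
    a <- crossprod(d_cov, w0 * e_diff)         # p x probes (sign flips cancel)
    m <- crossprod(d_cov, w0 * d_cov)
    ma <- tryCatch(solve(m, a), error = function(e) {
      # near-separated null fits can make the nuisance information singular;
      # fall back to the Moore-Penrose pseudo-inverse
      sv <- svd(m)
      pos <- sv$d > max(sv$d) * 1e-12
      sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% a) / sv$d[pos])
    })
    corr <- colSums(a * ma)
    v <- pmax(v_diag - corr, 0)
  }
  z <- ifelse(v > 1e-12, u / sqrt(v), ifelse(u == 0, 0, NA_real_))
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.na(z) & v <= 1e-12] <- 1
  list(z = z, p = p)
}

# Per-probe CLR scan for one cancer type: rank-normalized M-values against
# case status. Returns the difference matrix (pairs x probes) for reuse by
# the permutation engine, plus observed per-probe results carrying both the
# Wald fit (NA under separation) and the score test used for cluster events.
probe_scan_type <- function(beta, pairs, covariates, rank = TRUE) {
  samples <- c(pairs$case_id, pairs$control_id)
  check_samples_present(beta, samples)
  m <- beta_matrix(beta)[, samples, drop = FALSE]
  m <- beta_to_m(m)
  dim(m) <- c(nrow(beta), length(samples))
  rownames(m) <- beta$probe_id
  colnames(m) <- samples
  if (rank) m <- t(apply(m, 1, rank_normalize))
  e_diff <- t(m[, pairs$case_id, drop = FALSE] - m[, pairs$control_id, drop = FALSE])
  d_cov <- covariate_diffs(pairs, covariates)
  wald <- purrr::map_dfr(seq_len(ncol(e_diff)), function(j) {
    all_zero <- all(e_diff[, j] == 0)
    fit <- fit_clr_core(cbind(e_diff[, j], d_cov))
    est <- if (fit$separated) NA_real_ else fit$coef[1]
    se <- if (fit$separated) NA_real_ else fit$se[1]
    tibble::tibble(
      estimate = if (all_zero) 0 else est,
      std_error = se,
      wald_p = if (all_zero) 1 else 2 * stats::pnorm(-abs(est / se)),
      separated = fit$separated
    )
  })
  sc <- clr_score_stats(e_diff, d_cov, rep(1, nrow(e_diff)))
  res <- dplyr::bind_cols(
    tibble::tibble(probe_id = beta$probe_id),
    wald,
    tibble::tibble(score_z = sc$z, p_value = sc$p)
  )
  list(results = res, e_diff = e_diff, d_cov = d_cov)
}

#' Per-probe matched case-control associations
#'
#' Conditional logistic regression of case status on rank-normalized
#' per-probe M-values, adjusted for within-pair-varying covariates, for one
#' or several cancer types (a `cancer_type` column in `pairs`).
#'
#' @param beta Beta tibble covering all case and control samples.
#' @param pairs Data frame with `case_id`, `control_id` and optionally
#'   `cancer_type`.
#' @param covariates Optional per-sample covariate data frame.
#' @param rank Rank-normalize the M-values across samples within each cancer
#'   type (default `TRUE`)?
#' @return Tibble with `cancer_type`, `probe_id`, `estimate`, `std_error`,
#'   `wald_p`, `separated` (the conditional-logistic Wald fit, `NA` under
#'   separation) plus `score_z` and `p_value` (the always-defined Rao score
#'   test of the same conditional likelihood, used for cluster events).
#' @export
probe_associations <- function(beta, pairs, covariates = NULL, rank = TRUE) {
  check_beta_tbl(beta)
  if (!"cancer_type" %in% names(pairs)) pairs$cancer_type <- "all"
  purrr::map_dfr(split(pairs, pairs$cancer_type), function(pp) {
    scan <- probe_scan_type(beta, pp, covariates, rank = rank)
    dplyr::bind_cols(tibble::tibble(cancer_type = pp$cancer_type[1]),
                     scan$results)
  })
}

#' Cluster-level permutation test for matched case-control methylation
#'
#' The full cluster framework: per-probe conditional logistic regression on
#' rank-normalized M-values, cluster events, and a within-pair label-swap
#' permutation null. Each permutation keeps the pairing but independently
#' swaps the case/control status of every pair with probability 1/2
#' (equivalently, flips the sign of that pair's difference row), re-evaluates
#' every cluster probe, and recomputes the events. Probe-level significance
#' (observed and permuted alike) uses the Rao score test of the conditional
#' likelihood with covariates profiled out under the null: it is always
#' defined -- the Wald test degenerates under separation, which strong
#' cluster effects routinely produce -- and asymptotically equivalent to the
#' Wald test away from separation. The events are:
#'
#' * event i (per cluster and cancer type): the permuted assignment has at
#'   least as many significant concordant probes *and* at least as small a
#'   minimum p as observed;
#' * event ii (per cluster): the permuted recurrence across cancer types is
#'   at least the observed recurrence.
#'
#' Permutation p-values use the add-one estimator `(r + 1) / (n_perm + 1)`.
#'
#' @inheritParams probe_associations
#' @param clusters Cluster table from [build_clusters()], or a probe
#'   annotation data frame (then clusters are built with the defaults).
#' @param n_perm Number of permutations (default 20000).
#' @param alpha Probe-level significance threshold for the events.
#' @param seed Integer seed; required, so results are reproducible.
#' @return Object of class `cluster_perm`: list with `cluster_results`
#'   (tibble: `cluster_id`, `cancer_type`, `n_probes`, `n_obs`, `pmin_obs`,
#'   `recurrence_obs`, `p_event_i`, `p_event_ii`, `n_permutations`),
#'   `probe_results`, `clusters`, `alpha`, `n_perm`, `seed`.
#' @export
cluster_permutation_test <- function(beta, pairs, clusters, covariates = NULL,
                                     n_perm = 20000, alpha = 0.05, seed,
                                     rank = TRUE) {
  check_beta_tbl(beta)
  if (missing(seed) || is.null(seed)) {
    rlang::abort("A `seed` is required: permutation results must be reproducible.",
                 class = "essiv_error_config")
  }
  if (n_perm < 100) rlang::warn("Fewer than 100 permutations is very coarse.")
  if (is.data.frame(clusters) && !"probe_ids" %in% names(clusters)) {
    clusters <- build_clusters(clusters)
  }
  if (nrow(clusters) == 0) {
    rlang::abort("`clusters` is empty.", class = "essiv_error_argument")
  }
  if (!"cancer_type" %in% names(pairs)) pairs$cancer_type <- "all"
  types <- unique(pairs$cancer_type)
  cluster_probes <- unique(unlist(clusters$probe_ids))
  missing_probes <- setdiff(cluster_probes, beta$probe_id)
  if (length(missing_probes)) {
    abort_value(sprintf("%d cluster probe(s) absent from the methylation data.",
                        length(missing_probes)))
  }
  beta_cl <- beta[match(cluster_probes, beta$probe_id), , drop = FALSE]
  probe_index <- lapply(clusters$probe_ids, match, table = cluster_probes)

  # Observed scan per type, caching the signed-difference machinery. Pairs
  # are sorted canonically so permutation p-values do not depend on the
  # order in which pairs are supplied.
  scans <- lapply(types, function(ct) {
    pp <- pairs[pairs$cancer_type == ct, , drop = FALSE]
    pp <- pp[order(pp$case_id), , drop = FALSE]
    probe_scan_type(beta_cl, pp, covariates, rank = rank)
  })
  names(scans) <- types

  obs_events <- lapply(types, function(ct) {
    res <- scans[[ct]]$results
    events_from_vectors(res$score_z, res$p_value, probe_index, alpha)
  })
  names(obs_events) <- types
  n_obs <- sapply(obs_events, function(e) e$n_sig) # clusters x types
  pmin_obs <- sapply(obs_events, function(e) e$p_min)
  if (is.null(dim(n_obs))) {
    n_obs <- matrix(n_obs, nrow = nrow(clusters))
    pmin_obs <- matrix(pmin_obs, nrow = nrow(clusters))
  }
  rec_obs <- apply(n_obs >= 2, 1, sum)

  n_cl <- nrow(clusters)
  n_ty <- length(types)
  # Permuted events, filled per type: N_rnd and Pmin_rnd as [cluster, type, perm].
  n_rnd <- array(NA_integer_, c(n_cl, n_ty, n_perm))
  pmin_rnd <- array(NA_real_, c(n_cl, n_ty, n_perm))

  with_seed(seed, {
    for (t_i in seq_along(types)) {
      sc <- scans[[t_i]]
      np <- nrow(sc$e_diff)
      npr <- ncol(sc$e_diff)
      signs <- matrix(sample(c(-1, 1), np * n_perm, replace = TRUE), np, n_perm)
      if (is.null(sc$d_cov)) {
        # Exposure-only: the score information is invariant under sign flips,
        # so all permutations reduce to one matrix product.
        v <- colSums(sc$e_diff^2)
        zmat <- crossprod(sc$e_diff, signs) / sqrt(ifelse(v > 0, v, Inf))
        zmat[v == 0, ] <- 0
        pmat <- 2 * stats::pnorm(-abs(zmat))
        pmat[v == 0, ] <- 1
        for (perm in seq_len(n_perm)) {
          ev <- events_from_vectors(zmat[, perm], pmat[, perm], probe_index, alpha)
          n_rnd[, t_i, perm] <- ev$n_sig
          pmin_rnd[, t_i, perm] <- ev$p_min
        }
      } else {
        for (perm in seq_len(n_perm)) {
          st <- clr_score_stats(sc$e_diff, sc$d_cov, signs[, perm])
          ev <- events_from_vectors(st$z, st$p, probe_index, alpha)
          n_rnd[, t_i, perm] <- ev$n_sig
          pmin_rnd[, t_i, perm] <- ev$p_min
        }
      }
    }
  })

  hits_i <- matrix(0L, n_cl, n_ty)
  hits_ii <- rep(0L, n_cl)
  for (perm in seq_len(n_perm)) {
    nr <- n_rnd[, , perm, drop = FALSE]
    dim(nr) <- c(n_cl, n_ty)
    pm <- pmin_rnd[, , perm, drop = FALSE]
    dim(pm) <- c(n_cl, n_ty)
    hit_i <- nr >= n_obs & (pm <= pmin_obs | (is.na(pmin_obs) & is.na(pm)))
    hit_i[is.na(hit_i)] <- FALSE
    hits_i <- hits_i + hit_i
    rec_rnd <- rowSums(nr >= 2, na.rm = TRUE)
    hits_ii <- hits_ii + as.integer(rec_rnd >= rec_obs)
  }

  cluster_results <- purrr::map_dfr(seq_along(types), function(t_i) {
    tibble::tibble(
      cluster_id = clusters$cluster_id,
      cancer_type = types[t_i],
      n_probes = clusters$n_probes,
      n_obs = n_obs[, t_i],
      pmin_obs = pmin_obs[, t_i],
      recurrence_obs = rec_obs,
      p_event_i = (hits_i[, t_i] + 1) / (n_perm + 1),
      p_event_ii = (hits_ii + 1) / (n_perm + 1),
      n_permutations = n_perm
    )
  })
  probe_results <- purrr::map_dfr(types, function(ct) {
    dplyr::bind_cols(tibble::tibble(cancer_type = ct), scans[[ct]]$results)
  })
  structure(list(cluster_results = cluster_results,
                 probe_results = probe_results,
                 clusters = clusters, alpha = alpha, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "cluster_perm")
}

#' @export
print.cluster_perm <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %d cluster(s), %d permutation(s), seed %d\n",
              nrow(x$clusters), x$n_perm, x$seed))
  print(x$cluster_results)
  invisible(x)
}

#' Select significant clusters among the most CpG-rich
#'
#' Restricts to the `top_k` clusters by probe count (ties broken by cluster
#' ID), Benjamini-Hochberg-adjusts the event-i permutation p-values within
#' each cancer type, and flags clusters with `q < fdr`.
#'
#' @param results Cluster results tibble from [cluster_permutation_test()]
#'   (or the `cluster_perm` object itself).
#' @param top_k Number of most CpG-rich clusters to evaluate (default 10).
#' @param fdr FDR threshold (default 0.25).
#' @return The restricted tibble with `q_value` and `is_significant` added.
#' @export
select_significant_clusters <- function(results, top_k = 10, fdr = 0.25) {
  if (inherits(results, "cluster_perm")) results <- results$cluster_results
  need <- c("cluster_id", "cancer_type", "n_probes", "p_event_i")
  if (!all(need %in% names(results))) {
    abort_format(sprintf("`results` must have columns: %s.",
                         paste(need, collapse = ", ")))
  }
  ranked <- dplyr::distinct(results[c("cluster_id", "n_probes")])
  ranked <- dplyr::arrange(ranked, dplyr::desc(.data$n_probes), .data$cluster_id)
  keep_ids <- utils::head(ranked$cluster_id, top_k)
  out <- results[results$cluster_id %in% keep_ids, , drop = FALSE]
  out <- dplyr::group_by(out, .data$cancer_type)
  out <- dplyr::mutate(out, q_value = bh_fdr(.data$p_event_i))
  out <- dplyr::ungroup(out)
  out$is_significant <- !is.na(out$q_value) & out$q_value < fdr
  out
}
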