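test_that("positional clustering chains probes within the gap", {
  ann <- tibble::tibble(probe_id = sprintf("cg%d", 1:6), chrom = "chr1",
                        position = c(100, 550, 900, 5000, 5200, 9000))
  cl <- build_clusters(ann)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$probe_ids[[1]], c("cg1", "cg2", "cg3"))
  expect_equal(cl$probe_ids[[2]], c("cg4", "cg5"))
  expect_equal(cl$n_probes, c(3L, 2L))

  # gap of exactly 500 joins ("within 500 bp" is inclusive)
  ann2 <- tibble::tibble(probe_id = c("a", "b"), chrom = "chr1",
                         position = c(100, 600))
  expect_equal(nrow(build_clusters(ann2)), 1L)
  # everything farther apart: no clusters
  ann3 <- tibble::tibble(probe_id = c("a", "b"), chrom = "chr1",
                         position = c(100, 601))
  expect_equal(nrow(build_clusters(ann3)), 0L)
  # chromosomes never chain together
  ann4 <- tibble::tibble(probe_id = c("a", "b"), chrom = c("chr1", "chr2"),
                         position = c(100, 200))
  expect_equal(nrow(build_clusters(ann4)), 0L)
})

test_that("rank normalization uses ascending average ranks", {
  expect_equal(rank_normalize(c(0.5, 0.1, 0.9)), c(2, 1, 3))
  expect_equal(rank_normalize(c(0.5, 0.5)), c(1.5, 1.5))
  x <- runif(30)
  expect_equal(rank_normalize(x), rank_normalize(qlogis(x))) # monotone invariance
  expect_error(rank_normalize(0.3), class = "essiv_error_argument")
})

test_that("the matched-pair CLR hits the discordant-count closed form", {
  # 6 pairs case-exposed-only, 3 control-exposed-only: estimate = ln 2
  pairs <- tibble::tibble(case_id = sprintf("c%d", 1:9),
                          control_id = sprintf("k%d", 1:9))
  expo <- stats::setNames(c(rep(1, 6), rep(0, 3), rep(0, 6), rep(1, 3)),
                          c(pairs$case_id, pairs$control_id))
  fit <- suppressWarnings(clr_fit(pairs, expo))
  expect_equal(tidy(fit)$estimate, log(2), tolerance = 1e-6)

  # exposure identical within every pair: no information
  expo0 <- stats::setNames(rep(c(1, 1), each = 9),
                           c(pairs$case_id, pairs$control_id))
  fit0 <- clr_fit(pairs, expo0)
  expect_equal(tidy(fit0)$estimate, 0)
  expect_equal(tidy(fit0)$p_value, 1)
  expect_equal(glance(fit0)$n_informative, 0L)
})

test_that("the CLR fitter agrees with survival::clogit", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  set.seed(71)
  n <- 80
  pairs <- tibble::tibble(case_id = sprintf("c%d", 1:n),
                          control_id = sprintf("k%d", 1:n))
  ids <- c(pairs$case_id, pairs$control_id)
  expo <- stats::setNames(rnorm(2 * n), ids)
  covs <- tibble::tibble(sample_id = ids, bmi = rnorm(2 * n),
                         smoke = rbinom(2 * n, 1, 0.4))
  fit <- clr_fit(pairs, expo, covs)
  df <- data.frame(y = rep(c(1, 0), each = n), x = expo[ids],
                   bmi = covs$bmi, smoke = covs$smoke, strat = rep(1:n, 2))
  ref <- survival::clogit(y ~ x + bmi + smoke + survival::strata(strat),
                          data = df)
  expect_equal(tidy(fit)$estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(tidy(fit)$std_error,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("relabeling pair members flips the coefficient, not the evidence", {
  set.seed(72)
  n <- 40
  pairs <- tibble::tibble(case_id = sprintf("c%d", 1:n),
                          control_id = sprintf("k%d", 1:n))
  expo <- stats::setNames(rnorm(2 * n), c(pairs$case_id, pairs$control_id))
  fit <- clr_fit(pairs, expo)
  swapped <- tibble::tibble(case_id = pairs$control_id,
                            control_id = pairs$case_id)
  fit_sw <- clr_fit(swapped, expo)
  expect_equal(tidy(fit_sw)$estimate, -tidy(fit)$estimate, tolerance = 1e-8)
  expect_equal(tidy(fit_sw)$p_value, tidy(fit)$p_value, tolerance = 1e-8)
})

test_that("separation is flagged with NA estimates", {
  pairs <- tibble::tibble(case_id = sprintf("c%d", 1:12),
                          control_id = sprintf("k%d", 1:12))
  expo <- stats::setNames(c(rep(1, 12), rep(0, 12)),
                          c(pairs$case_id, pairs$control_id))
  fit <- clr_fit(pairs, expo)
  expect_true(glance(fit)$separated)
  expect_true(is.na(tidy(fit)$estimate))
})

test_that("cluster events count concordant significant probes", {
  pr <- tibble::tibble(estimate = c(1, 0.5, -0.2), p_value = c(0.01, 0.03, 0.2))
  ev <- cluster_events(pr)
  expect_equal(ev$n_sig, 2L)
  expect_equal(ev$p_min, 0.01)
  # opposite signs split the count
  pr2 <- tibble::tibble(estimate = c(1, -1), p_value = c(0.01, 0.02))
  expect_equal(cluster_events(pr2)$n_sig, 1L)
  # nothing significant: count 0, p_min still reported
  pr3 <- tibble::tibble(estimate = c(1, 1), p_value = c(0.2, 0.4))
  expect_equal(cluster_events(pr3)$n_sig, 0L)
  expect_equal(cluster_events(pr3)$p_min, 0.2)
  # all-missing p
  pr4 <- tibble::tibble(estimate = c(NA_real_), p_value = c(NA_real_))
  expect_equal(cluster_events(pr4)$n_sig, 0L)
  expect_true(is.na(cluster_events(pr4)$p_min))
})

test_that("recurrence counts cancer types with two concordant hits", {
  expect_equal(recurrence(c(3, 2, 1, 0, 2, 0, 0)), 3)
  expect_equal(recurrence(rep(0, 7)), 0)
  expect_equal(recurrence(rep(2, 7)), 7)
  expect_error(recurrence(integer()), class = "essiv_error_argument")
})

test_that("permutation p-values are reproducible and pair-order invariant", {
  co <- simulate_matched_casecontrol(n_pairs = 16, n_clusters = 3,
                                     n_affected_clusters = 1, delta = 1,
                                     seed = 73)
  cl <- build_clusters(co$annotation)
  p1 <- cluster_permutation_test(co$beta, co$pairs, cl, n_perm = 300, seed = 74)
  p2 <- cluster_permutation_test(co$beta, co$pairs, cl, n_perm = 300, seed = 74)
  expect_identical(tidy(p1), tidy(p2))
  shuffled <- co$pairs[sample(nrow(co$pairs)), ]
  p3 <- cluster_permutation_test(co$beta, shuffled, cl, n_perm = 300, seed = 74)
  expect_equal(tidy(p1)$p_event_i, tidy(p3)$p_event_i)
  expect_error(cluster_permutation_test(co$beta, co$pairs, cl, n_perm = 300),
               class = "essiv_error_config")
})

test_that("Monte-Carlo event-i p matches exhaustive enumeration on a toy study", {
  co <- simulate_matched_casecontrol(n_pairs = 6, n_clusters = 1,
                                     probes_per_cluster = 2,
                                     n_affected_clusters = 1, delta = 0.8,
                                     cov_effect_sd = 0, seed = 75)
  cl <- build_clusters(co$annotation)
  res <- cluster_permutation_test(co$beta, co$pairs, cl, n_perm = 4000,
                                  seed = 76)

  # independent enumeration of all 2^6 assignments with the closed-form
  # score statistic z = sum(x) / sqrt(sum(x^2))
  m <- beta_to_m(as.matrix(co$beta[, -1]))
  rk <- t(apply(m, 1, rank))
  colnames(rk) <- colnames(m)
  pp <- co$pairs[order(co$pairs$case_id), ]
  d <- t(rk[, pp$case_id] - rk[, pp$control_id]) # pairs x probes
  event_stats <- function(x) {
    z <- apply(x, 2, score_z_oracle)
    p <- 2 * pnorm(-abs(z))
    sig <- p < 0.05
    n <- max(sum(sig & z > 0), sum(sig & z < 0))
    c(n = n, pmin = min(p))
  }
  obs <- event_stats(d)
  hits <- 0
  for (mask in 0:(2^6 - 1)) {
    s <- ifelse(bitwAnd(mask, 2^(0:5)) > 0, -1, 1)
    st <- event_stats(d * s)
    if (st["n"] >= obs["n"] && st["pmin"] <= obs["pmin"]) hits <- hits + 1
  }
  p_exact <- hits / 64
  p_mc <- tidy(res)$p_event_i[1]
  tol <- 2.58 * sqrt(p_exact * (1 - p_exact) / 4000) + 1 / 4001
  expect_lt(abs(p_mc - p_exact), tol + 1e-12)
  # observed events agree with the oracle
  expect_equal(tidy(res)$n_obs[1], unname(obs["n"]))
  expect_equal(tidy(res)$pmin_obs[1], unname(obs["pmin"]), tolerance = 1e-12)
})

test_that("an affected cluster reaches the permutation floor", {
  co <- simulate_matched_casecontrol(n_pairs = 40, n_clusters = 4,
                                     n_affected_clusters = 1, delta = 2,
                                     seed = 77)
  cl <- build_clusters(co$annotation)
  res <- cluster_permutation_test(co$beta, co$pairs, cl,
                                  covariates = co$covariates,
                                  n_perm = 999, seed = 78)
  out <- tidy(res)
  affected <- out$cluster_id == cl$cluster_id[1]
  expect_equal(out$p_event_i[affected], 1 / 1000)
  expect_true(all(out$p_event_i[!affected] > 0.05))
})

test_that("recurrence event spans cancer types sharing affected clusters", {
  co <- simulate_matched_casecontrol(n_pairs = 30, n_clusters = 3,
                                     n_affected_clusters = 1, delta = 1.5,
                                     cancer_types = c("colon", "lung"),
                                     seed = 79)
  cl <- build_clusters(co$annotation)
  res <- cluster_permutation_test(co$beta, co$pairs, cl,
                                  covariates = co$covariates,
                                  n_perm = 499, seed = 80)
  out <- tidy(res)
  affected <- out$cluster_id == cl$cluster_id[1]
  expect_true(all(out$recurrence_obs[affected] == 2))
  expect_true(all(out$p_event_ii[affected] < 0.05))
})

test_that("cluster selection restricts to the most CpG-rich and applies FDR", {
  res <- tibble::tibble(
    cluster_id = sprintf("cl%02d", 1:12),
    cancer_type = "all",
    n_probes = c(12:2, 2L),
    p_event_i = c(0.001, rep(0.9, 11))
  )
  out <- select_significant_clusters(res, top_k = 10, fdr = 0.25)
  expect_equal(nrow(out), 10L)
  expect_equal(out$q_value[out$cluster_id == "cl01"], 0.01)
  expect_equal(sum(out$is_significant), 1L)
  res$p_event_i <- 1
  expect_equal(sum(select_significant_clusters(res)$is_significant), 0L)
})
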