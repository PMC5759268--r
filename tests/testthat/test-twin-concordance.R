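test_that("pair_mse matches direct evaluation and the brute-force oracle", {
  b <- as_beta_tbl(matrix(c(0.2, 0.2, 0.4, 0.6), nrow = 1),
                   sample_ids = c("s1", "s2", "s3", "s4"))
  p <- tibble::tibble(sample_a = c("s1", "s3"), sample_b = c("s2", "s4"))
  expect_equal(pair_mse(b, p)$mse, 0.02)

  # identical co-twins give exactly zero
  b2 <- as_beta_tbl(matrix(runif(20), 5, 4), sample_ids = c("s1", "s2", "s3", "s4"))
  b2$s2 <- b2$s1
  b2$s4 <- b2$s3
  expect_equal(pair_mse(b2, p)$mse, rep(0, 5))

  # random instances with missing values vs the double-loop oracle
  set.seed(21)
  for (rep in 1:15) {
    np <- sample(5:40, 1)
    npair <- sample(3:15, 1)
    m <- matrix(runif(np * 2 * npair), np, 2 * npair)
    m[sample(length(m), length(m) %/% 10)] <- NA
    beta <- as_beta_tbl(m)
    ids <- setdiff(names(beta), "probe_id")
    pairs <- tibble::tibble(sample_a = ids[seq(1, 2 * npair, 2)],
                            sample_b = ids[seq(2, 2 * npair, 2)])
    expect_equal(pair_mse(beta, pairs)$mse, brute_mse(beta, pairs),
                 tolerance = 1e-12)
  }
})

test_that("pair_mse validates its inputs", {
  b <- as_beta_tbl(matrix(0.5, 1, 4), sample_ids = c("s1", "s2", "s3", "s4"))
  expect_error(pair_mse(b, tibble::tibble(sample_a = character(),
                                          sample_b = character())),
               class = "essiv_error_argument")
  expect_error(pair_mse(b, tibble::tibble(sample_a = c("s1", "s1"),
                                          sample_b = c("s2", "s3"))),
               class = "essiv_error_format")
  expect_error(pair_mse(b, tibble::tibble(sample_a = "s1", sample_b = "zz")),
               class = "essiv_error_value")
})

test_that("randomized pairing is a deterministic perfect matching", {
  rz <- make_randomized_pairs(letters[1:4], seed = 5)
  expect_equal(nrow(rz), 2L)
  expect_setequal(c(rz$sample_a, rz$sample_b), letters[1:4])
  expect_identical(rz, make_randomized_pairs(letters[1:4], seed = 5))
  # odd sample dropped
  expect_equal(nrow(make_randomized_pairs(letters[1:5], seed = 5)), 2L)
  expect_error(make_randomized_pairs("a", seed = 1), class = "essiv_error_argument")
})

test_that("randomized pairing is uniform over the three matchings of 4 samples", {
  keys <- vapply(1:1000, function(s) {
    rz <- make_randomized_pairs(c("a", "b", "c", "d"), seed = s)
    paste(sort(paste(pmin(rz$sample_a, rz$sample_b),
                     pmax(rz$sample_a, rz$sample_b))), collapse = "|")
  }, character(1))
  freq <- table(keys) / 1000
  expect_equal(length(freq), 3L)
  expect_true(all(abs(freq - 1 / 3) < 0.05))
})

test_that("top-variance filter matches brute-force ranking", {
  set.seed(22)
  m <- matrix(runif(200), 20, 10)
  m[3, ] <- 0.5 # constant probe
  beta <- as_beta_tbl(m)
  v <- apply(m, 1, function(x) mean((x - mean(x))^2))
  ord <- order(-v, beta$probe_id)
  expect_setequal(top_variance_filter(beta, 0.1), beta$probe_id[ord[1:2]])
  expect_setequal(top_variance_filter(beta, 1), beta$probe_id)
  expect_false(beta$probe_id[3] %in% top_variance_filter(beta, 0.5))
  expect_error(top_variance_filter(beta, 0), class = "essiv_error_config")
})

test_that("ESS classification applies strict thresholds and the MZ/RZ exclusion", {
  rec <- tibble::tibble(
    norm_mz = c(0.2, 0.25, 0.6, 0, 0, 0.2),
    norm_dz = c(0.5, 0.50, 1.8, 0.4, 0, 0.5),
    beta_range = c(0.5, 0.5, 0.6, 0.5, 0.5, 0.3)
  )
  # ratio 2.5 passes; ratio exactly 2 fails (strict); MZ/RZ > 0.5 excluded;
  # zero MZ MSE with discordant DZ is maximal ESS; zero/zero is no signal;
  # range at or below 0.4 fails
  expect_equal(classify_ess(rec), c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("the twin screen recovers early-stochastic loci from simulation", {
  loci <- locus_panel(n_early = 40, n_late = 160, n_genetic = 30)
  co <- simulate_twin_cohort(loci, n_mz = 60, n_dz = 90, seed = 23)
  rec <- ess_screen(co$beta, co$pairs, rz_seed = 23)
  early <- co$truth$locus_class == "EARLY_STOCHASTIC"
  late <- co$truth$locus_class == "LATE_STOCHASTIC"
  expect_gte(mean(rec$is_ess[early]), 0.9)
  expect_lte(mean(rec$is_ess[late]), 0.05)
  # record invariants
  expect_true(all(rec$mse_mz >= 0 & rec$mse_dz >= 0 & rec$mse_rz >= 0))
  expect_true(all(rec$beta_range >= 0 & rec$beta_range <= 1))
  expect_equal(rec$norm_mz, rec$mse_mz / rec$mse_rz)
  expect_equal(sum(rec$is_top_variance), ceiling(0.1 * nrow(rec)))
})

test_that("noise monotonically raises MZ MSE at early-stochastic loci", {
  mse_at_noise <- function(sd) {
    loci <- locus_panel(n_early = 50, noise_sd = sd)
    co <- simulate_twin_cohort(loci, n_mz = 60, n_dz = 60, seed = 24)
    mz <- co$pairs[co$pairs$pair_class == "MZ", ]
    mean(pair_mse(co$beta, mz)$mse)
  }
  m <- vapply(c(0, 0.03, 0.08), mse_at_noise, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("locus-average MSE fold behaves on constructed loci", {
  # DZ discordance 10x the MZ discordance at every probe
  m <- matrix(c(0.5, 0.5 + 0.1, 0.5, 0.5 + sqrt(0.1)), nrow = 1)
  b <- as_beta_tbl(rbind(m, m), sample_ids = c("m1", "m2", "d1", "d2"))
  mzp <- tibble::tibble(sample_a = "m1", sample_b = "m2")
  dzp <- tibble::tibble(sample_a = "d1", sample_b = "d2")
  expect_equal(locus_mse_fold(b, b$probe_id, mzp, dzp), 10, tolerance = 1e-10)

  # identical concordance in both classes
  b2 <- as_beta_tbl(matrix(c(0.2, 0.3, 0.6, 0.7), 1),
                    sample_ids = c("m1", "m2", "d1", "d2"))
  expect_equal(locus_mse_fold(b2, b2$probe_id, mzp, dzp), 1)

  # perfectly concordant MZ: infinite fold
  b3 <- as_beta_tbl(matrix(c(0.2, 0.2, 0.6, 0.7), 1),
                    sample_ids = c("m1", "m2", "d1", "d2"))
  expect_identical(locus_mse_fold(b3, b3$probe_id, mzp, dzp), Inf)

  # simulated early-stochastic locus: fold far above the ESS threshold
  loci <- locus_panel(n_early = 5)
  co <- simulate_twin_cohort(loci, n_mz = 60, n_dz = 90, seed = 25)
  fold <- locus_mse_fold(co$beta, co$beta$probe_id,
                         co$pairs[co$pairs$pair_class == "MZ", ],
                         co$pairs[co$pairs$pair_class == "DZ", ])
  expect_gt(fold, 2)
})

test_that("distribution statistics match the moment-based skewness oracle", {
  # frozen against an independent implementation of the D'Agostino transform
  x1 <- c(round(seq(0.1, 1.0, length.out = 40), 6), 0.01, 0.02, 0.03)
  s1 <- mse_distribution_stats(x1)
  expect_equal(s1$statistic, -0.123418949073, tolerance = 1e-9)
  expect_equal(s1$p_value, 0.450887676298, tolerance = 1e-9)
  x2 <- round(sin(1:30) * 0.3 + 0.5, 6)
  s2 <- mse_distribution_stats(x2)
  expect_equal(s2$statistic, -0.081887832646, tolerance = 1e-9)
  expect_equal(s2$p_value, 0.467367955042, tolerance = 1e-9)
})

test_that("distribution statistics behave at symmetry and flag extreme values", {
  sym <- seq(-1, 1, length.out = 25)
  s <- mse_distribution_stats(sym)
  expect_equal(s$skewness, 0, tolerance = 1e-12)
  expect_gte(s$p_value, 0.5 - 1e-12) # no evidence of left skew
  # a value 6 sd below the bulk scores z < -5
  set.seed(26)
  x <- rnorm(200, 0.6, 0.05)
  x[1] <- 0.6 - 6 * sd(x)
  s2 <- mse_distribution_stats(x)
  expect_lt(s2$z[1], -5)
  expect_error(mse_distribution_stats(rep(0.5, 20)), class = "essiv_error_degenerate")
  expect_error(mse_distribution_stats(runif(5)), class = "essiv_error_argument")
})

test_that("the left-skew test is calibrated under a Gaussian null", {
  set.seed(27)
  ps <- replicate(200, mse_distribution_stats(rnorm(500))$p_value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
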