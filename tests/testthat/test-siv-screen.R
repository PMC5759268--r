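make_panel <- function(m, n_ind, n_tis) {
  sample_ids <- as.vector(outer(sprintf("t%d", seq_len(n_tis)),
                                sprintf("i%d", seq_len(n_ind)),
                                function(t, i) paste(i, t, sep = "_")))
  beta <- as_beta_tbl(m, sample_ids = sample_ids)
  map <- tibble::tibble(sample_id = sample_ids,
                        individual_id = rep(sprintf("i%d", seq_len(n_ind)),
                                            each = n_tis),
                        tissue_id = rep(sprintf("t%d", seq_len(n_tis)), n_ind))
  list(beta = beta, map = map)
}

test_that("variation measures match arithmetic and the brute-force oracle", {
  # individual means 0.1, 0.2, 0.3, 0.6 -> range 0.5 (constant across tissues)
  m <- matrix(rep(c(0.1, 0.2, 0.3, 0.6), each = 3), nrow = 1)
  p <- make_panel(m, 4, 3)
  expect_equal(interindividual_variation(p$beta, p$map)$interindividual_var, 0.5)
  expect_equal(tissue_variation(p$beta, p$map)$tissue_var, 0)

  # tissue means 0.2, 0.2, 0.8 -> range 0.6
  m2 <- matrix(rep(c(0.2, 0.2, 0.8), 4), nrow = 1)
  p2 <- make_panel(m2, 4, 3)
  expect_equal(tissue_variation(p2$beta, p2$map)$tissue_var, 0.6)
  expect_equal(interindividual_variation(p2$beta, p2$map)$interindividual_var, 0)

  # random panels vs explicit range-of-means loops
  set.seed(31)
  for (rep in 1:10) {
    n_ind <- sample(3:6, 1)
    n_tis <- sample(2:4, 1)
    mm <- matrix(runif(8 * n_ind * n_tis), 8, n_ind * n_tis)
    pp <- make_panel(mm, n_ind, n_tis)
    inter <- interindividual_variation(pp$beta, pp$map)$interindividual_var
    tis <- tissue_variation(pp$beta, pp$map)$tissue_var
    for (i in 1:8) {
      expect_equal(inter[i],
                   brute_range_of_means(mm[i, ], pp$map$individual_id),
                   tolerance = 1e-12)
      expect_equal(tis[i],
                   brute_range_of_means(mm[i, ], pp$map$tissue_id),
                   tolerance = 1e-12)
    }
  }
})

test_that("individual and tissue roles are exchangeable under transposition", {
  set.seed(32)
  m <- matrix(runif(5 * 12), 5, 12)
  p <- make_panel(m, 4, 3)
  swapped <- p$map
  names(swapped)[2:3] <- c("tissue_id", "individual_id")
  expect_equal(interindividual_variation(p$beta, p$map)$interindividual_var,
               tissue_variation(p$beta, swapped)$tissue_var)
})

test_that("missing values exclude probes under the complete-case rule", {
  m <- matrix(runif(24), 2, 12)
  m[1, 5] <- NA
  p <- make_panel(m, 4, 3)
  inter <- interindividual_variation(p$beta, p$map)
  expect_true(is.na(inter$interindividual_var[1]))
  expect_false(is.na(inter$interindividual_var[2]))
  # relaxed rule averages over available tissues
  inter2 <- interindividual_variation(p$beta, p$map, complete_case = FALSE)
  expect_false(is.na(inter2$interindividual_var[1]))
})

test_that("SIV classification applies the strict cutoffs", {
  rec <- tibble::tibble(
    interindividual_var = c(0.5, 0.3, 0.2, 0.25),
    tissue_var = c(0.1, 0.15, 0.01, 0.08)
  )
  # 0.1 < 0.5/3 passes; 0.15 >= 0.3/3 fails; inter exactly 0.2 fails (strict);
  # 0.08 < 0.25/3 passes
  expect_equal(classify_siv(rec), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("the SIV screen recovers systemic loci from the default panel", {
  p <- simulate_multitissue_panel(seed = 33)
  rec <- siv_screen(p$beta, p$samples)
  sys <- p$truth$locus_class == "SYSTEMIC"
  tis <- p$truth$locus_class == "TISSUE_SPECIFIC"
  expect_gte(mean(rec$is_siv[sys]), 0.9)
  expect_lte(mean(rec$is_siv[tis]), 0.05)
  expect_true(all(rec$interindividual_var >= 0 & rec$interindividual_var <= 1,
                  na.rm = TRUE))
})

test_that("negative controls demand discordant MZ twins and tissue dominance", {
  twin <- tibble::tibble(
    probe_id = c("cg1", "cg2", "cg3", "cg4"),
    beta_range = c(0.5, 0.5, 0.3, 0.5),
    norm_mz = c(0.6, 0.4, 0.7, 0.6)
  )
  siv <- tibble::tibble(
    probe_id = c("cg1", "cg2", "cg3", "cg4"),
    interindividual_var = c(0.1, 0.1, 0.1, 0.3),
    tissue_var = c(0.4, 0.4, 0.4, 0.3)
  )
  # cg2 fails norm_mz, cg3 fails range, cg4 fails tissue >= 2x inter
  expect_equal(select_negative_controls(twin, siv), "cg1")
})

test_that("negative-control selection is dominated by tissue-specific loci", {
  p <- simulate_multitissue_panel(seed = 34)
  rec <- siv_screen(p$beta, p$samples)
  # twin-screen behaviour consistent with the panel truth: structured loci
  # vary between people (range > 0.4) but are not supersimilar in MZ twins
  twin <- tibble::tibble(
    probe_id = rec$probe_id,
    beta_range = ifelse(p$truth$locus_class == "NONE", 0.1, 0.5),
    norm_mz = 0.7
  )
  neg <- select_negative_controls(twin, rec)
  truth <- p$truth$locus_class[match(neg, p$truth$probe_id)]
  expect_gt(length(neg), 20)
  expect_gte(mean(truth == "TISSUE_SPECIFIC"), 0.9)
})

test_that("the inter-tissue correlation call enforces the R^2 threshold", {
  # identical vectors: all r = 1, positive call
  v <- runif(17)
  d <- tibble::tibble(
    individual_id = rep(sprintf("i%d", 1:17), 3),
    tissue_id = rep(c("liver", "kidney", "brain"), each = 17),
    value = rep(v, 3)
  )
  call <- intertissue_correlation_call(d)
  expect_true(call$is_siv)
  expect_equal(call$pairs$r, rep(1, 3))

  # constructed correlations just above and just below the threshold
  make_pair <- function(r, seed) {
    set.seed(seed)
    x <- rnorm(17)
    e <- rnorm(17)
    e <- residuals(lm(e ~ x))
    y <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
    tibble::tibble(
      individual_id = rep(sprintf("i%d", 1:17), 2),
      tissue_id = rep(c("a", "b"), each = 17),
      value = c(scale(x)[, 1], y) / 10 + 0.5
    )
  }
  expect_true(intertissue_correlation_call(make_pair(0.72, 35))$is_siv)
  expect_false(intertissue_correlation_call(make_pair(0.70, 35))$is_siv)

  # an independent tissue breaks the all-pairs call
  set.seed(36)
  d2 <- d
  d2$value[d2$tissue_id == "brain"] <- runif(17)
  expect_false(intertissue_correlation_call(d2)$is_siv)
  # ... but not the any-pair relaxation
  expect_true(intertissue_correlation_call(d2, all_pairs = FALSE)$is_siv)

  # zero-variance tissue: undefined correlation, negative call
  d3 <- d
  d3$value[d3$tissue_id == "brain"] <- 0.5
  call3 <- intertissue_correlation_call(d3)
  expect_false(call3$is_siv)
  expect_true(call3$undefined)

  expect_error(intertissue_correlation_call(d[d$individual_id %in% c("i1", "i2"), ]),
               class = "essiv_error_argument")
})
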