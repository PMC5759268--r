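# Synthetic cohort generators embodying the early-embryo establishment model.
#
# The central idea: at a metastable locus, a methylation state is drawn from a
# small set of preferred levels (trimodal by default) in the cleavage-stage
# embryo. If the draw happens before cleavage, monozygotic (MZ) co-twins
# inherit the same state; dizygotic (DZ) co-twins, arising from two zygotes,
# always draw independently. Genetically determined loci instead map a diploid
# genotype to a level, and genotype-dependent metastability lets one genotype
# class suppress the stochastic draw entirely.

locus_classes <- c("EARLY_STOCHASTIC", "LATE_STOCHASTIC", "GENETIC",
                   "GENETIC_METASTABLE")

#' Define a simulated locus
#'
#' Builds a one-row locus specification for the twin-cohort generator.
#'
#' @param locus_class One of `"EARLY_STOCHASTIC"` (state drawn once per
#'   zygote before cleavage), `"LATE_STOCHASTIC"` (every individual draws
#'   independently), `"GENETIC"` (level is an additive function of a diploid
#'   genotype), `"GENETIC_METASTABLE"` (genotype controls the variance of the
#'   state distribution).
#' @param state_levels Preferred methylation states, strictly increasing
#'   fractions in \[0, 1\]. Default `c(0.1, 0.5, 0.9)`, the trimodal pattern
#'   typical of bistable epialleles in a two-allele population.
#' @param state_probs Simplex weights over `state_levels` for stochastic
#'   draws; must sum to 1.
#' @param allele_freq Reference-allele frequency for the genetic classes.
#' @param noise_sd Gaussian measurement noise on the beta scale, added after
#'   state assignment and clipped to \[0, 1\]. Default 0.03.
#' @return A one-row tibble with list-columns `state_levels`, `state_probs`.
#' @seealso [locus_panel()], [simulate_twin_cohort()]
#' @export
locus_spec <- function(locus_class,
                       state_levels = c(0.1, 0.5, 0.9),
                       state_probs = c(0.25, 0.5, 0.25),
                       allele_freq = 0.5,
                       noise_sd = 0.03) {
  locus_class <- match.arg(locus_class, locus_classes)
  if (length(state_levels) != length(state_probs)) {
    abort_config("`state_levels` and `state_probs` must have equal length.")
  }
  if (any(diff(state_levels) <= 0)) {
    abort_config("`state_levels` must be strictly increasing.")
  }
  if (any(state_levels < 0 | state_levels > 1)) {
    abort_config("`state_levels` must lie in [0, 1].")
  }
  if (abs(sum(state_probs) - 1) > 1e-12 || any(state_probs < 0)) {
    abort_config("`state_probs` must be non-negative and sum to 1.")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort_config("`noise_sd` must be >= 0.")
  if (allele_freq < 0 || allele_freq > 1) abort_config("`allele_freq` must be in [0, 1].")
  tibble::tibble(
    locus_class = locus_class,
    state_levels = list(as.numeric(state_levels)),
    state_probs = list(as.numeric(state_probs)),
    allele_freq = allele_freq,
    noise_sd = noise_sd
  )
}

#' Build a panel of loci by class counts
#'
#' Convenience wrapper around [locus_spec()] producing `n_early + n_late +
#' n_genetic + n_metastable` loci with shared state and noise settings.
#'
#' @param n_early,n_late,n_genetic,n_metastable Locus counts per class.
#' @inheritParams locus_spec
#' @return A tibble of locus specifications, one row per locus.
#' @export
locus_panel <- function(n_early = 0, n_late = 0, n_genetic = 0, n_metastable = 0,
                        state_levels = c(0.1, 0.5, 0.9),
                        state_probs = c(0.25, 0.5, 0.25),
                        allele_freq = 0.5,
                        noise_sd = 0.03) {
  counts <- c(EARLY_STOCHASTIC = n_early, LATE_STOCHASTIC = n_late,
              GENETIC = n_genetic, GENETIC_METASTABLE = n_metastable)
  if (sum(counts) == 0) abort_config("Locus panel must contain at least one locus.")
  dplyr::bind_rows(lapply(rep(names(counts), counts), function(cl) {
    locus_spec(cl, state_levels = state_levels, state_probs = state_probs,
               allele_freq = allele_freq, noise_sd = noise_sd)
  }))
}

new_sim_cohort <- function(...) {
  structure(list(...), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", nrow(x$beta), "probes x",
      ncol(x$beta) - 1L, "samples; seed", x$seed, "\n")
  if (!is.null(x$truth) && "locus_class" %in% names(x$truth)) {
    print(table(x$truth$locus_class))
  } else if (!is.null(x$truth)) {
    utils::str(x$truth, max.level = 1)
  }
  invisible(x)
}

add_noise <- function(x, sd) {
  if (sd > 0) x <- x + stats::rnorm(length(x), 0, sd)
  pmin(pmax(x, 0), 1)
}

draw_states <- function(n, levels, probs) {
  levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
}

# Additive genotype -> level map: allele count g in 0:2 spans the state range.
genotype_level <- function(g, levels) {
  lo <- min(levels)
  hi <- max(levels)
  lo + g * (hi - lo) / 2
}

#' Simulate a twin methylation cohort
#'
#' Generates beta values for MZ and DZ twin pairs at loci of the four
#' establishment classes, with per-locus ground-truth labels. The generator is
#' the package's model of how epigenetic supersimilarity arises:
#' `EARLY_STOCHASTIC` loci draw one state per zygote (MZ co-twins share it, DZ
#' co-twins do not), `LATE_STOCHASTIC` loci draw per individual, `GENETIC`
#' loci map a diploid genotype additively onto the state range (MZ share the
#' genotype; DZ share each haplotype independently with probability 1/2), and
#' `GENETIC_METASTABLE` loci behave stochastically except in the major-allele
#' homozygote, which is pinned at the top state.
#'
#' @param loci Tibble of locus specifications from [locus_spec()] /
#'   [locus_panel()].
#' @param n_mz,n_dz Numbers of MZ and DZ twin pairs (defaults 100 and 160,
#'   matching a twin panel of 97 MZ / 162 DZ pairs in round numbers).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A `sim_cohort` list: `beta` (beta tibble), `samples` (sample
#'   sheet), `pairs` (pair table with `pair_class` MZ/DZ), `truth` (per-probe
#'   locus class), `genotypes` (allele counts for genetic loci, else `NA`),
#'   `dz_allele_share` (loci x DZ-pair matrix of shared-haplotype counts),
#'   and `seed`.
#' @export
simulate_twin_cohort <- function(loci, n_mz = 100, n_dz = 160, seed) {
  if (!is.data.frame(loci) || nrow(loci) == 0) {
    abort_config("`loci` must be a non-empty locus specification table.")
  }
  if (n_mz <= 0 || n_dz <= 0) abort_config("`n_mz` and `n_dz` must be positive.")
  n_mz <- as.integer(n_mz)
  n_dz <- as.integer(n_dz)
  probe_ids <- sprintf("cg%05d", seq_len(nrow(loci)))

  mz_a <- sprintf("mz%03d_a", seq_len(n_mz))
  mz_b <- sprintf("mz%03d_b", seq_len(n_mz))
  dz_a <- sprintf("dz%03d_a", seq_len(n_dz))
  dz_b <- sprintf("dz%03d_b", seq_len(n_dz))
  sample_ids <- c(rbind(mz_a, mz_b), rbind(dz_a, dz_b))
  n_samples <- length(sample_ids)

  with_seed(seed, {
    beta <- matrix(NA_real_, nrow(loci), n_samples,
                   dimnames = list(probe_ids, sample_ids))
    geno <- matrix(NA_integer_, nrow(loci), n_samples,
                   dimnames = list(probe_ids, sample_ids))
    share <- matrix(NA_integer_, nrow(loci), n_dz,
                    dimnames = list(probe_ids, sprintf("dz%03d", seq_len(n_dz))))

    for (i in seq_len(nrow(loci))) {
      cls <- loci$locus_class[i]
      lv <- loci$state_levels[[i]]
      pr <- loci$state_probs[[i]]
      f <- loci$allele_freq[i]
      sd_i <- loci$noise_sd[i]
      vals <- numeric(n_samples)

      if (cls == "EARLY_STOCHASTIC") {
        s_mz <- draw_states(n_mz, lv, pr)
        vals[seq_len(2 * n_mz)] <- rep(s_mz, each = 2)
        vals[2 * n_mz + seq_len(2 * n_dz)] <- draw_states(2 * n_dz, lv, pr)
      } else if (cls == "LATE_STOCHASTIC") {
        vals <- draw_states(n_samples, lv, pr)
      } else { # GENETIC or GENETIC_METASTABLE
        g_mz <- stats::rbinom(n_mz, 2, f)
        a1 <- stats::rbinom(n_dz, 1, f)
        a2 <- stats::rbinom(n_dz, 1, f)
        h1 <- stats::rbinom(n_dz, 1, 0.5) # haplotype 1 co-inherited?
        h2 <- stats::rbinom(n_dz, 1, 0.5)
        b1 <- ifelse(h1 == 1, a1, stats::rbinom(n_dz, 1, f))
        b2 <- ifelse(h2 == 1, a2, stats::rbinom(n_dz, 1, f))
        g_dz_a <- a1 + a2
        g_dz_b <- b1 + b2
        share[i, ] <- as.integer(h1 + h2)
        g_all <- c(rep(g_mz, each = 2),
                   as.vector(rbind(g_dz_a, g_dz_b)))
        geno[i, ] <- as.integer(g_all)
        if (cls == "GENETIC") {
          vals <- genotype_level(g_all, lv)
        } else {
          # Metastable: establishment is an early (per-zygote) draw unless the
          # genotype pins the state. MZ co-twins share one draw; DZ draw per twin.
          z_mz <- draw_states(n_mz, lv, pr)
          z_dz_a <- draw_states(n_dz, lv, pr)
          z_dz_b <- draw_states(n_dz, lv, pr)
          z_all <- c(rep(z_mz, each = 2), as.vector(rbind(z_dz_a, z_dz_b)))
          vals <- ifelse(g_all == 2L, max(lv), z_all)
        }
      }
      beta[i, ] <- add_noise(vals, sd_i)
    }

    samples <- tibble::tibble(
      sample_id = sample_ids,
      pair_id = rep(c(sprintf("mz%03d", seq_len(n_mz)),
                      sprintf("dz%03d", seq_len(n_dz))), each = 2),
      twin_role = rep(c("a", "b"), n_mz + n_dz),
      zygosity = rep(c("MZ", "DZ"), c(2 * n_mz, 2 * n_dz))
    )
    pairs <- tibble::tibble(
      pair_id = c(sprintf("mz%03d", seq_len(n_mz)), sprintf("dz%03d", seq_len(n_dz))),
      sample_a = c(mz_a, dz_a),
      sample_b = c(mz_b, dz_b),
      pair_class = rep(c("MZ", "DZ"), c(n_mz, n_dz))
    )
    truth <- tibble::tibble(
      probe_id = probe_ids,
      locus_class = loci$locus_class,
      noise_sd = loci$noise_sd
    )
    new_sim_cohort(
      beta = tibble::as_tibble(cbind(tibble::tibble(probe_id = probe_ids),
                                     as.data.frame(beta))),
      samples = samples, pairs = pairs, truth = truth,
      genotypes = tibble::as_tibble(cbind(tibble::tibble(probe_id = probe_ids),
                                          as.data.frame(geno))),
      dz_allele_share = share,
      seed = as.integer(seed)
    )
  })
}

#' Simulate a multi-individual, multi-tissue methylation panel
#'
#' Emulates the design used to detect systemic interindividual variation:
#' a small number of individuals each contribute one sample per tissue
#' (representing the three germ layers). `SYSTEMIC` loci carry an
#' individual-level offset shared across that individual's tissues;
#' `TISSUE_SPECIFIC` loci carry a tissue-level offset shared across
#' individuals; `NONE` loci carry neither. Offsets are an evenly spaced,
#' randomly permuted grid spanning `effect`, so `effect` is the noise-free
#' range of the relevant means.
#'
#' @param n_individuals,n_tissues Panel dimensions (defaults 4 and 3).
#' @param n_systemic,n_tissue_specific,n_null Locus counts per class.
#' @param effect Delta-beta range carried by the structured classes
#'   (default 0.4).
#' @param noise_sd Measurement noise on the beta scale (default 0.02).
#' @param seed Integer seed.
#' @return A `sim_cohort` with `beta`, `samples` (with `individual_id` and
#'   `tissue_id`), `truth` (locus class) and `seed`.
#' @export
simulate_multitissue_panel <- function(n_individuals = 4, n_tissues = 3,
                                       n_systemic = 100, n_tissue_specific = 100,
                                       n_null = 300, effect = 0.4,
                                       noise_sd = 0.02, seed) {
  if (n_individuals < 2 || n_tissues < 2) {
    abort_config("Need at least 2 individuals and 2 tissues.")
  }
  if (effect < 0 || effect > 1) abort_config("`effect` must be in [0, 1].")
  n_loci <- n_systemic + n_tissue_specific + n_null
  if (n_loci == 0) abort_config("Panel must contain at least one locus.")
  probe_ids <- sprintf("cg%05d", seq_len(n_loci))
  classes <- rep(c("SYSTEMIC", "TISSUE_SPECIFIC", "NONE"),
                 c(n_systemic, n_tissue_specific, n_null))
  tissues <- sprintf("t%d", seq_len(n_tissues))
  inds <- sprintf("ind%d", seq_len(n_individuals))
  sample_ids <- as.vector(outer(tissues, inds, function(t, i) paste(i, t, sep = "_")))
  ind_of <- rep(inds, each = n_tissues)
  tis_of <- rep(tissues, n_individuals)

  with_seed(seed, {
    beta <- matrix(NA_real_, n_loci, length(sample_ids),
                   dimnames = list(probe_ids, sample_ids))
    for (i in seq_len(n_loci)) {
      base <- stats::runif(1, 0.05, max(0.05, 0.95 - effect))
      vals <- rep(base, length(sample_ids))
      if (classes[i] == "SYSTEMIC") {
        off <- sample(seq(0, effect, length.out = n_individuals))
        vals <- vals + off[match(ind_of, inds)]
      } else if (classes[i] == "TISSUE_SPECIFIC") {
        off <- sample(seq(0, effect, length.out = n_tissues))
        vals <- vals + off[match(tis_of, tissues)]
      }
      beta[i, ] <- add_noise(vals, noise_sd)
    }
    new_sim_cohort(
      beta = tibble::as_tibble(cbind(tibble::tibble(probe_id = probe_ids),
                                     as.data.frame(beta))),
      samples = tibble::tibble(sample_id = sample_ids,
                               individual_id = ind_of, tissue_id = tis_of),
      truth = tibble::tibble(probe_id = probe_ids, locus_class = classes),
      seed = as.integer(seed)
    )
  })
}

#' Simulate a two-season conception cohort
#'
#' Generates blood methylation for children conceived at the peak of the dry
#' or the rainy season. A subset of loci responds to season of conception:
#' rainy-conceived samples are shifted up by `seasonal_delta` in mean beta.
#' Infant sex and `n_covariates` continuous nuisance covariates (standing in
#' for methylation principal components / cell composition) are generated and
#' recorded, with small per-locus effects, so the EWAS stage has something to
#' adjust for.
#'
#' @param n Cohort size (default 128; half conceived in each season).
#' @param n_loci,n_affected Total and season-responsive locus counts.
#' @param seasonal_delta Mean beta increase in rainy-conceived samples at
#'   affected loci (default 0.05).
#' @param resid_sd Residual interindividual + technical standard deviation on
#'   the beta scale (default 0.08; unrelated individuals at variably
#'   methylated CpGs differ far more than array noise alone).
#' @param sex_effect_sd,covariate_effect_sd Standard deviation of per-locus
#'   nuisance effect sizes.
#' @param n_covariates Number of continuous nuisance covariates.
#' @param seed Integer seed.
#' @return A `sim_cohort` with `beta`, `design` (sample sheet with `season`,
#'   `sex` and covariate columns), `truth` (`is_affected` per probe), `seed`.
#' @export
simulate_soc_cohort <- function(n = 128, n_loci = 1000, n_affected = 50,
                                seasonal_delta = 0.05, resid_sd = 0.08,
                                sex_effect_sd = 0.01, covariate_effect_sd = 0.01,
                                n_covariates = 2, seed) {
  if (n_affected > n_loci) abort_config("`n_affected` must be <= `n_loci`.")
  if (n < 4) abort_config("`n` must be at least 4.")
  probe_ids <- sprintf("cg%05d", seq_len(n_loci))
  sample_ids <- sprintf("s%03d", seq_len(n))
  season <- rep(c("DRY", "RAINY"), length.out = n)

  with_seed(seed, {
    sex <- stats::rbinom(n, 1, 0.5)
    covs <- matrix(stats::rnorm(n * n_covariates), n, n_covariates,
                   dimnames = list(NULL, if (n_covariates > 0)
                     sprintf("pc%d", seq_len(n_covariates)) else NULL))
    rainy <- as.numeric(season == "RAINY")
    affected <- seq_len(n_loci) <= n_affected
    beta <- matrix(NA_real_, n_loci, n, dimnames = list(probe_ids, sample_ids))
    for (i in seq_len(n_loci)) {
      base <- stats::runif(1, 0.1, 0.8)
      b_sex <- stats::rnorm(1, 0, sex_effect_sd)
      b_cov <- if (n_covariates > 0) stats::rnorm(n_covariates, 0, covariate_effect_sd) else numeric(0)
      mu <- base + b_sex * sex +
        (if (n_covariates > 0) drop(covs %*% b_cov) else 0) +
        seasonal_delta * rainy * affected[i]
      beta[i, ] <- add_noise(mu, resid_sd)
    }
    design <- tibble::as_tibble(cbind(
      tibble::tibble(sample_id = sample_ids, season = season, sex = sex),
      as.data.frame(covs)
    ))
    new_sim_cohort(
      beta = tibble::as_tibble(cbind(tibble::tibble(probe_id = probe_ids),
                                     as.data.frame(beta))),
      design = design,
      truth = tibble::tibble(probe_id = probe_ids, is_affected = affected),
      seed = as.integer(seed)
    )
  })
}

#' Simulate matched case-control methylation with cluster-level effects
#'
#' Generates one or more 1:1 matched case-control studies over a shared set of
#' probe clusters. Probes live on a latent M-value scale; within affected
#' clusters every probe of a case is shifted up by `delta` (concordant sign
#' across the cluster), then mapped back to beta. Matching covariates that
#' vary within pairs (BMI, smoking, alcohol, six leukocyte proportions) are
#' generated per sample with per-probe nuisance effects of scale
#' `cov_effect_sd` on the latent scale.
#'
#' @param n_pairs Matched pairs per cancer type (default 50).
#' @param n_clusters,probes_per_cluster Cluster layout (default 10 clusters of
#'   3 probes, 100 bp apart within a cluster, clusters 10 kb apart).
#' @param n_affected_clusters Number of clusters carrying a true effect
#'   (default 2; the first clusters).
#' @param delta Case shift on the latent M scale at affected-cluster probes
#'   (default 1).
#' @param cov_effect_sd Scale of per-probe covariate nuisance effects
#'   (default 0.25).
#' @param cancer_types Character vector of cancer types; each gets its own
#'   independent set of matched pairs over the same probes.
#' @param seed Integer seed.
#' @return A `sim_cohort` with `beta`, `pairs` (`pair_id`, `case_id`,
#'   `control_id`, `cancer_type`), `covariates` (per sample), `annotation`
#'   (probe positions for [build_clusters()]), `truth` (`cluster_index`,
#'   `is_affected` per probe) and `seed`.
#' @export
simulate_matched_casecontrol <- function(n_pairs = 50, n_clusters = 10,
                                         probes_per_cluster = 3,
                                         n_affected_clusters = 2, delta = 1,
                                         cov_effect_sd = 0.25,
                                         cancer_types = "cancer", seed) {
  if (n_affected_clusters > n_clusters) {
    abort_config("`n_affected_clusters` must be <= `n_clusters`.")
  }
  if (n_pairs < 2) abort_config("`n_pairs` must be at least 2.")
  n_probes <- n_clusters * probes_per_cluster
  probe_ids <- sprintf("cg%05d", seq_len(n_probes))
  cluster_index <- rep(seq_len(n_clusters), each = probes_per_cluster)
  position <- 10000L * cluster_index + 100L * (seq_len(n_probes) -
                                                 (cluster_index - 1L) * probes_per_cluster)
  affected <- cluster_index <= n_affected_clusters

  cell_names <- c("bcell", "gran", "mono", "nk", "cd4t", "cd8t")
  cell_shape <- c(4, 60, 8, 5, 15, 8)

  with_seed(seed, {
    all_beta <- list()
    all_pairs <- list()
    all_cov <- list()
    for (ct in cancer_types) {
      n_s <- 2L * n_pairs
      ids <- sprintf("%s_s%03d", ct, seq_len(n_s))
      case_id <- ids[seq(1, n_s, by = 2)]
      control_id <- ids[seq(2, n_s, by = 2)]
      is_case <- rep(c(1, 0), n_pairs)

      g <- matrix(stats::rgamma(n_s * 6, shape = rep(cell_shape, each = n_s)), n_s, 6)
      cells <- g / rowSums(g)
      colnames(cells) <- cell_names
      covariates <- tibble::as_tibble(cbind(
        tibble::tibble(
          sample_id = ids,
          bmi = stats::rnorm(n_s, 26, 4),
          smoking = stats::rbinom(n_s, 1, 0.3),
          alcohol = pmax(stats::rnorm(n_s, 10, 8), 0)
        ),
        as.data.frame(cells)
      ))
      # standardized covariate matrix driving nuisance effects
      cz <- scale(cbind(covariates$bmi, covariates$smoking, covariates$alcohol,
                        cells[, c("bcell", "mono", "nk", "cd4t", "cd8t")]))
      cz[is.nan(cz)] <- 0

      z <- matrix(NA_real_, n_probes, n_s, dimnames = list(probe_ids, ids))
      for (i in seq_len(n_probes)) {
        mu <- stats::rnorm(1, 0, 1.5)
        b <- stats::rnorm(ncol(cz), 0, cov_effect_sd)
        z[i, ] <- mu + drop(cz %*% b) + stats::rnorm(n_s) +
          delta * affected[i] * is_case
      }
      all_beta[[ct]] <- m_to_beta(z)
      all_pairs[[ct]] <- tibble::tibble(
        pair_id = sprintf("%s_p%03d", ct, seq_len(n_pairs)),
        case_id = case_id, control_id = control_id, cancer_type = ct
      )
      all_cov[[ct]] <- covariates
    }
    beta <- do.call(cbind, all_beta)
    new_sim_cohort(
      beta = tibble::as_tibble(cbind(tibble::tibble(probe_id = probe_ids),
                                     as.data.frame(beta))),
      pairs = dplyr::bind_rows(all_pairs),
      covariates = dplyr::bind_rows(all_cov),
      annotation = tibble::tibble(probe_id = probe_ids, chrom = "chr1",
                                  position = position),
      truth = tibble::tibble(probe_id = probe_ids,
                             cluster_index = cluster_index,
                             is_affected = affected),
      seed = as.integer(seed)
    )
  })
}
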