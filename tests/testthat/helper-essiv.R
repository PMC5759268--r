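# Shared fixtures and independent oracles for the test suite. Oracles are
# written as plainly as possible (double loops, enumeration) and never reuse
# the implementation they check.

# Build a beta tibble from a plain matrix.
as_beta_tbl <- function(m, probe_ids = NULL, sample_ids = NULL) {
  probe_ids <- probe_ids %||% sprintf("cg%03d", seq_len(nrow(m)))
  sample_ids <- sample_ids %||% sprintf("s%02d", seq_len(ncol(m)))
  colnames(m) <- sample_ids
  tibble::as_tibble(cbind(tibble::tibble(probe_id = probe_ids),
                          as.data.frame(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force per-probe pair MSE: explicit double loop.
brute_mse <- function(beta, pairs) {
  m <- as.matrix(beta[, -1])
  rownames(m) <- beta$probe_id
  out <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    total <- 0
    count <- 0
    for (j in seq_len(nrow(pairs))) {
      a <- m[i, pairs$sample_a[j]]
      b <- m[i, pairs$sample_b[j]]
      if (!is.na(a) && !is.na(b)) {
        total <- total + (a - b)^2
        count <- count + 1
      }
    }
    if (count > 0) out[i] <- total / count
  }
  out
}

# Brute-force range of per-group means for one probe row.
brute_range_of_means <- function(values, groups) {
  means <- c()
  for (g in unique(groups)) {
    means <- c(means, mean(values[groups == g]))
  }
  max(means) - min(means)
}

# Independent Benjamini-Hochberg step-up implementation.
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

# One-sided-greater Fisher p by direct hypergeometric enumeration.
fisher_enum_greater <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  total <- choose(m1 + m2, k)
  ks <- max(0, k - m2):min(k, m1)
  probs <- choose(m1, ks) * choose(m2, k - ks) / total
  sum(probs[ks >= a])
}

# Exposure-only conditional-likelihood score test: z = sum(x) / sqrt(sum(x^2)).
score_z_oracle <- function(x) {
  if (all(x == 0)) return(0)
  sum(x) / sqrt(sum(x^2))
}

# Simple matched-pair generator with a continuous exposure and known
# conditional log-odds: within each pair, two exposure values are drawn and
# the case is chosen with the conditional-logistic probability.
simulate_clr_pairs <- function(n_pairs, log_odds, seed) {
  set.seed(seed)
  case_id <- sprintf("case%03d", seq_len(n_pairs))
  control_id <- sprintf("ctrl%03d", seq_len(n_pairs))
  x1 <- stats::rnorm(n_pairs)
  x2 <- stats::rnorm(n_pairs)
  p_first <- stats::plogis(log_odds * (x1 - x2))
  first_is_case <- stats::rbinom(n_pairs, 1, p_first) == 1
  x_case <- ifelse(first_is_case, x1, x2)
  x_ctrl <- ifelse(first_is_case, x2, x1)
  list(
    pairs = tibble::tibble(case_id = case_id, control_id = control_id),
    exposure = stats::setNames(c(x_case, x_ctrl), c(case_id, control_id))
  )
}
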