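# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

abort_value <- function(msg, ...) rlang::abort(msg, class = "essiv_error_value", ...)
abort_format <- function(msg, ...) rlang::abort(msg, class = "essiv_error_format", ...)
abort_config <- function(msg, ...) rlang::abort(msg, class = "essiv_error_config", ...)
abort_degenerate <- function(msg, ...) rlang::abort(msg, class = "essiv_error_degenerate", ...)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are reproducible without clobbering the global
#' random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_config("`seed` must be a single non-missing integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Convert a beta tibble (probe_id + one numeric column per sample) to a
# numeric matrix with probe rownames. Validation is assumed done upstream.
beta_matrix <- function(beta) {
  m <- as.matrix(beta[, setdiff(names(beta), "probe_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- beta$probe_id
  m
}

# Assert that `x` looks like a beta tibble and return it invisibly.
check_beta_tbl <- function(beta, tol = 1e-9) {
  if (!is.data.frame(beta) || !"probe_id" %in% names(beta)) {
    abort_format("Methylation data must be a data frame with a `probe_id` column.")
  }
  if (anyDuplicated(beta$probe_id)) {
    abort_format("Duplicated probe IDs in methylation data.")
  }
  smp <- setdiff(names(beta), "probe_id")
  if (length(smp) == 0L) abort_format("Methylation data has no sample columns.")
  if (anyDuplicated(smp)) abort_format("Duplicated sample IDs in methylation data.")
  vals <- as.matrix(beta[smp])
  if (!is.numeric(vals)) abort_value("Beta values must be numeric.")
  bad <- !is.na(vals) & (vals < -tol | vals > 1 + tol)
  if (any(bad)) {
    abort_value(sprintf(
      "Found %d beta value(s) outside [0, 1] (tolerance %g); refusing to clip.",
      sum(bad), tol
    ))
  }
  invisible(beta)
}

check_samples_present <- function(beta, ids, what = "sample") {
  missing <- setdiff(ids, setdiff(names(beta), "probe_id"))
  if (length(missing)) {
    abort_value(sprintf(
      "%d %s ID(s) not found in the methylation data (e.g. %s).",
      length(missing), what, missing[1]
    ))
  }
  invisible(TRUE)
}

# Population (divide-by-n) variance, NA-aware; returns NA for all-missing.
pop_var <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}
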