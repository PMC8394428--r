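# internal helpers shared across modules

GENOTYPES <- c("AA", "AG", "GG")

#' @keywords internal
assert_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    rlang::abort(sprintf("`%s` must be a single probability in [0, 1], got %s.",
                         what, deparse(x)), class = "ccr5flux_config_error")
  }
  invisible(x)
}

#' @keywords internal
assert_count <- function(x, what, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok) {
    rlang::abort(sprintf("`%s` must be a %s integer, got %s.",
                         what, if (positive) "positive" else "non-negative",
                         deparse(x)), class = "ccr5flux_config_error")
  }
  invisible(as.integer(x))
}

#' @keywords internal
assert_genotype <- function(genotype) {
  if (!is.character(genotype) || length(genotype) != 1L ||
      !genotype %in% GENOTYPES) {
    rlang::abort(sprintf("`genotype` must be one of %s.",
                         paste0('"', GENOTYPES, '"', collapse = ", ")),
                 class = "ccr5flux_config_error")
  }
  invisible(genotype)
}

# Spawn reproducible child seeds from one master seed, so per-subject event
# streams are independent of cohort ordering and can be regenerated alone.
#' @keywords internal
spawn_seeds <- function(master_seed, n) {
  if (is.null(master_seed)) {
    return(sample.int(.Machine$integer.max, n))
  }
  withr::with_seed(master_seed, sample.int(.Machine$integer.max, n))
}

# lognormal (meanlog, sdlog) matching a target arithmetic mean and sd
#' @keywords internal
lognormal_from_mean_sd <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
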