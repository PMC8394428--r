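# Case-control genetics: allele/genotype/carriership tabulation, HWE,
# Pearson chi-square, and Wald odds ratios.

#' Tabulate genotype counts per group
#'
#' Collapses a subject-level cohort into genotype counts for cases and
#' controls. Missing genotypes are dropped listwise and their number is
#' recorded in the `n_missing` attribute.
#'
#' @param cohort Data frame with columns `subject_id`, `group`
#'   (`"case"`/`"control"`) and `genotype` (`"AA"`, `"AG"`, `"GG"`, or `NA`).
#' @return A tibble with columns `group`, `n_AA`, `n_AG`, `n_GG`, `n`.
#' @export
#' @examples
#' cohort <- simulate_genotype_cohort(cohort_sim_config(seed = 1))
#' genotype_counts(cohort)
genotype_counts <- function(cohort) {
  stopifnot(all(c("subject_id", "group", "genotype") %in% names(cohort)))
  if (anyDuplicated(cohort$subject_id)) {
    rlang::abort("`subject_id` values must be unique.")
  }
  bad <- !is.na(cohort$genotype) & !cohort$genotype %in% GENOTYPES
  if (any(bad)) {
    rlang::abort(sprintf("Unknown genotype value(s): %s.",
                         paste(unique(cohort$genotype[bad]), collapse = ", ")))
  }
  n_missing <- sum(is.na(cohort$genotype))
  out <- cohort |>
    dplyr::filter(!is.na(.data$genotype)) |>
    dplyr::count(.data$group, .data$genotype) |>
    tidyr::pivot_wider(names_from = "genotype", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)
  for (g in paste0("n_", GENOTYPES)) {
    if (!g %in% names(out)) out[[g]] <- 0L
  }
  out <- out |>
    dplyr::select("group", "n_AA", "n_AG", "n_GG") |>
    dplyr::mutate(n = .data$n_AA + .data$n_AG + .data$n_GG)
  attr(out, "n_missing") <- n_missing
  out
}

#' Count alleles from genotype counts
#'
#' For a biallelic A/G locus, `n_A = 2 n_AA + n_AG` and
#' `n_G = 2 n_GG + n_AG`; the two always sum to twice the subject count.
#'
#' @param counts A tibble as returned by [genotype_counts()], or any data
#'   frame with columns `n_AA`, `n_AG`, `n_GG` (one row per group).
#' @return The input with added columns `n_A` and `n_G`.
#' @export
count_alleles <- function(counts) {
  stopifnot(all(c("n_AA", "n_AG", "n_GG") %in% names(counts)))
  dplyr::mutate(tibble::as_tibble(counts),
                n_A = 2L * .data$n_AA + .data$n_AG,
                n_G = 2L * .data$n_GG + .data$n_AG)
}

#' Pearson chi-square test on an r x c contingency table
#'
#' Classical Pearson chi-square without continuity correction:
#' `E = rowsum %o% colsum / N`, `X2 = sum((O - E)^2 / E)`,
#' `df = (r - 1)(c - 1)`, with the p-value from the chi-square distribution.
#' No Yates correction is applied at any table size; the study's published
#' allelic, carriership and responder statistics are uncorrected.
#'
#' @param observed Numeric matrix of non-negative counts (at least 2 x 2).
#' @return A `ccr5_contingency` object with elements `observed`, `expected`,
#'   `statistic`, `df`, `p.value`, `method`.
#' @export
#' @examples
#' pearson_chi2(matrix(c(6, 4, 1, 1, 3, 6), nrow = 3))
pearson_chi2 <- function(observed) {
  observed <- as.matrix(observed)
  if (any(is.na(observed)) || any(observed < 0)) {
    rlang::abort("All observed counts must be non-negative and non-missing.")
  }
  if (nrow(observed) < 2L || ncol(observed) < 2L) {
    rlang::abort("Contingency table needs at least 2 rows and 2 columns.")
  }
  rs <- rowSums(observed)
  cs <- colSums(observed)
  if (any(rs == 0) || any(cs == 0)) {
    zr <- which(rs == 0)
    zc <- which(cs == 0)
    rlang::abort(sprintf(
      "Degenerate table: zero margin in %s.",
      paste(c(if (length(zr)) paste("row", paste(zr, collapse = ",")),
              if (length(zc)) paste("column", paste(zc, collapse = ","))),
            collapse = " and ")))
  }
  expected <- outer(rs, cs) / sum(observed)
  statistic <- sum((observed - expected)^2 / expected)
  df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
  p <- stats::pchisq(statistic, df = df, lower.tail = FALSE)
  structure(
    list(observed = observed, expected = expected, statistic = statistic,
         df = df, p.value = p,
         method = "Pearson chi-square (no continuity correction)"),
    class = "ccr5_contingency")
}

#' Hardy-Weinberg equilibrium test for one group
#'
#' Expected genotype counts are taken from the observed allele frequency
#' (`n p^2`, `2 n p q`, `n q^2`) and compared with the observed genotype
#' counts by Pearson chi-square on 1 degree of freedom (three genotype
#' classes minus one estimated allele frequency).
#'
#' @param n_AA,n_AG,n_GG Genotype counts for a single group.
#' @return A `ccr5_contingency` object (df = 1). For a monomorphic group the
#'   test is undefined: `statistic` and `p.value` are `NA` and the result
#'   carries `monomorphic = TRUE`.
#' @export
#' @examples
#' hwe_test(92, 115, 50)  # control genotype distribution; p > 0.05
hwe_test <- function(n_AA, n_AG, n_GG) {
  for (v in c(n_AA, n_AG, n_GG)) assert_count(v, "genotype count", positive = FALSE)
  n <- n_AA + n_AG + n_GG
  if (n == 0L) rlang::abort("HWE test needs at least one genotyped subject.")
  observed <- c(AA = n_AA, AG = n_AG, GG = n_GG)
  p_A <- (2 * n_AA + n_AG) / (2 * n)
  q_G <- 1 - p_A
  expected <- n * c(AA = p_A^2, AG = 2 * p_A * q_G, GG = q_G^2)
  mono <- p_A == 0 || q_G == 0
  statistic <- if (mono) NA_real_ else sum((observed - expected)^2 / expected)
  structure(
    list(observed = observed, expected = expected, statistic = statistic,
         df = 1L,
         p.value = if (mono) NA_real_ else
           stats::pchisq(statistic, df = 1L, lower.tail = FALSE),
         monomorphic = mono, allele_freq_A = p_A,
         method = "Hardy-Weinberg equilibrium chi-square (df = 1)"),
    class = "ccr5_contingency")
}

#' Odds ratio with Wald 95% confidence interval for a 2 x 2 table
#'
#' `OR = ad / bc` with the exposed cases in cell `a`; the confidence
#' interval is the Wald log-normal interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z = 1.96` for
#' the default 95% level. No small-sample correction is applied unless a
#' zero cell is present and `haldane = TRUE`, in which case 0.5 is added to
#' every cell and the result is flagged.
#'
#' @param table 2 x 2 numeric matrix: rows = (cases, controls), columns =
#'   (risk category, reference category).
#' @param conf_level Confidence level (default 0.95).
#' @param haldane Apply the Haldane-Anscombe +0.5 correction when a cell is
#'   zero, instead of erroring. Default `FALSE`.
#' @return A `ccr5_or` object with `estimate`, `conf.low`, `conf.high`, `z`,
#'   `se_log`, `corrected`.
#' @export
#' @examples
#' # G-allele association: cases (G, A) = (116, 96); controls (215, 299)
#' odds_ratio(matrix(c(116, 215, 96, 299), nrow = 2))
odds_ratio <- function(table, conf_level = 0.95, haldane = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    rlang::abort("`table` must be a 2 x 2 matrix.")
  }
  if (any(table < 0) || any(is.na(table))) {
    rlang::abort("All cells must be non-negative counts.")
  }
  corrected <- FALSE
  if (any(table == 0)) {
    if (!haldane) {
      rlang::abort(paste0(
        "Zero cell in 2 x 2 table; the Wald odds ratio is undefined. ",
        "Use `haldane = TRUE` for the +0.5 continuity mode."))
    }
    table <- table + 0.5
    corrected <- TRUE
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(estimate = or,
         conf.low = exp(log(or) - z * se),
         conf.high = exp(log(or) + z * se),
         z = z, se_log = se, conf_level = conf_level, corrected = corrected,
         table = table,
         method = "Wald (log-normal) odds-ratio confidence interval"),
    class = "ccr5_or")
}

#' Collapse genotype counts into a carriership 2 x 2 table
#'
#' Carriers of the risk allele are the risk homozygotes plus heterozygotes;
#' non-carriers are the opposite homozygotes. Rows are (case, control),
#' columns are (carrier, non-carrier), matching the orientation expected by
#' [odds_ratio()].
#'
#' @param counts Two-row tibble from [genotype_counts()] containing both a
#'   `"case"` and a `"control"` row.
#' @param risk_allele `"G"` (default) or `"A"`.
#' @return Named 2 x 2 matrix of counts.
#' @export
carriership_table <- function(counts, risk_allele = c("G", "A")) {
  risk_allele <- match.arg(risk_allele)
  stopifnot(all(c("group", "n_AA", "n_AG", "n_GG") %in% names(counts)))
  row_for <- function(grp) {
    r <- counts[counts$group == grp, ]
    if (nrow(r) != 1L) rlang::abort(sprintf("Need exactly one '%s' row.", grp))
    if (risk_allele == "G") {
      c(carrier = r$n_GG + r$n_AG, non_carrier = r$n_AA)
    } else {
      c(carrier = r$n_AA + r$n_AG, non_carrier = r$n_GG)
    }
  }
  out <- rbind(case = row_for("case"), control = row_for("control"))
  storage.mode(out) <- "double"
  out
}

#' Full case-control association report for one biallelic SNP
#'
#' Assembles, from a subject-level cohort, the complete association summary:
#' genotype and allele counts with percentages (rounded to integers, as
#' conventionally printed), Hardy-Weinberg equilibrium per group, the allelic
#' chi-square test and Wald odds ratio, and the carriership model for the
#' chosen risk allele.
#'
#' @param cohort Data frame with `subject_id`, `group`, `genotype`.
#' @param risk_allele `"G"` (default) or `"A"`.
#' @param haldane Passed to [odds_ratio()]: apply the +0.5 correction when a
#'   table cell is zero (e.g. a monomorphic group) instead of erroring.
#' @return A `ccr5_assoc` object; see [tidy.ccr5_assoc()] for the tabular
#'   form.
#' @export
#' @examples
#' report <- association_report(rs1799987_cohort())
#' report
association_report <- function(cohort, risk_allele = c("G", "A"),
                               haldane = FALSE) {
  risk_allele <- match.arg(risk_allele)
  counts <- genotype_counts(cohort)
  if (!all(c("case", "control") %in% counts$group)) {
    rlang::abort("Cohort must contain both cases and controls.")
  }
  counts <- count_alleles(counts)
  counts <- counts[match(c("case", "control"), counts$group), ]

  allele_tab <- if (risk_allele == "G") {
    rbind(case = c(counts$n_G[1], counts$n_A[1]),
          control = c(counts$n_G[2], counts$n_A[2]))
  } else {
    rbind(case = c(counts$n_A[1], counts$n_G[1]),
          control = c(counts$n_A[2], counts$n_G[2]))
  }
  colnames(allele_tab) <- c(risk_allele, setdiff(c("A", "G"), risk_allele))

  geno_tab <- as.matrix(counts[, c("n_AA", "n_AG", "n_GG")])
  rownames(geno_tab) <- counts$group
  colnames(geno_tab) <- GENOTYPES

  carrier_tab <- carriership_table(counts, risk_allele)

  hwe <- list(
    case = hwe_test(counts$n_AA[1], counts$n_AG[1], counts$n_GG[1]),
    control = hwe_test(counts$n_AA[2], counts$n_AG[2], counts$n_GG[2]))

  structure(
    list(counts = counts,
         risk_allele = risk_allele,
         n_missing = attr(genotype_counts(cohort), "n_missing"),
         genotype_pct = round(100 * sweep(geno_tab, 1, rowSums(geno_tab), "/")),
         allele_pct = round(100 * sweep(allele_tab, 1, rowSums(allele_tab), "/")),
         carrier_pct = round(100 * carrier_tab[, "carrier"] /
                               rowSums(carrier_tab)),
         allele_test = pearson_chi2(allele_tab),
         genotype_test = pearson_chi2(geno_tab),
         carrier_test = pearson_chi2(carrier_tab),
         allele_or = odds_ratio(allele_tab, haldane = haldane),
         carrier_or = odds_ratio(carrier_tab, haldane = haldane),
         hwe = hwe),
    class = "ccr5_assoc")
}

#' @export
print.ccr5_contingency <- function(x, ...) {
  cat(x$method, "\n")
  if (isTRUE(x$monomorphic)) {
    cat("  monomorphic group: test undefined\n")
  } else {
    cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p.value))
  }
  invisible(x)
}

#' @export
print.ccr5_or <- function(x, ...) {
  cat(sprintf("OR = %.3f, %d%% CI %.2f-%.2f%s\n",
              x$estimate, round(100 * x$conf_level), x$conf.low, x$conf.high,
              if (x$corrected) " (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}

#' @export
print.ccr5_assoc <- function(x, ...) {
  cat("Case-control association report (risk allele ", x$risk_allele, ")\n\n",
      sep = "")
  print(x$counts)
  cat(sprintf("\nAllelic: chi2 = %.2f, p = %.4g; ", x$allele_test$statistic,
              x$allele_test$p.value))
  print(x$allele_or)
  cat(sprintf("Carriership (%d%% vs %d%% carriers): chi2 = %.2f, p = %.4g; ",
              x$carrier_pct[["case"]], x$carrier_pct[["control"]],
              x$carrier_test$statistic, x$carrier_test$p.value))
  print(x$carrier_or)
  cat(sprintf("HWE: cases p = %.3g, controls p = %.3g\n",
              x$hwe$case$p.value, x$hwe$control$p.value))
  invisible(x)
}
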