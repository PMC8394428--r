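# broom-style tidy()/glance() methods for fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contingency-test result
#'
#' One row per table cell with observed and expected counts and the cell's
#' Pearson residual.
#'
#' @param x A `ccr5_contingency` from [pearson_chi2()], [hwe_test()] or
#'   [responder_association()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `column`, `observed`, `expected`,
#'   `residual`.
#' @method tidy ccr5_contingency
#' @export
tidy.ccr5_contingency <- function(x, ...) {
  obs <- as.matrix(x$observed)
  if (is.null(dim(obs))) obs <- matrix(obs, nrow = 1)
  exp <- matrix(as.numeric(x$expected), nrow = nrow(obs))
  rn <- rownames(obs) %||% as.character(seq_len(nrow(obs)))
  cn <- colnames(obs) %||% as.character(seq_len(ncol(obs)))
  tibble::tibble(
    row = rep(rn, times = ncol(obs)),
    column = rep(cn, each = nrow(obs)),
    observed = as.vector(obs),
    expected = as.vector(exp),
    residual = (as.vector(obs) - as.vector(exp)) / sqrt(as.vector(exp)))
}

#' @rdname tidy.ccr5_contingency
#' @method glance ccr5_contingency
#' @export
glance.ccr5_contingency <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 method = x$method)
}

#' Tidy an odds-ratio result
#'
#' @param x A `ccr5_or` from [odds_ratio()].
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `conf.low`, `conf.high`,
#'   `se_log`, `conf.level`, `corrected`.
#' @method tidy ccr5_or
#' @export
tidy.ccr5_or <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf.low = x$conf.low,
                 conf.high = x$conf.high, se_log = x$se_log,
                 conf.level = x$conf_level, corrected = x$corrected)
}

#' @rdname tidy.ccr5_or
#' @method glance ccr5_or
#' @export
glance.ccr5_or <- tidy.ccr5_or

#' Glance at a group-comparison test
#'
#' @param x A `ccr5_test` from [mann_whitney()], [kruskal_wallis()] or
#'   [one_way_anova()].
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p.value`, `method`, `n_total`,
#'   `n_groups`, `adjustment`.
#' @method glance ccr5_test
#' @export
glance.ccr5_test <- function(x, ...) {
  tibble::tibble(statistic = unname(x$statistic), p.value = x$p.value,
                 method = x$method, n_total = sum(x$n_per_group),
                 n_groups = length(x$n_per_group), adjustment = x$adjustment)
}

#' Tidy an association report
#'
#' One row per association model (allelic, carriership) with the chi-square
#' statistic, p-value, odds ratio and Wald CI.
#'
#' @param x A `ccr5_assoc` from [association_report()].
#' @param ... Unused.
#' @return Tibble with one row per model.
#' @method tidy ccr5_assoc
#' @export
tidy.ccr5_assoc <- function(x, ...) {
  tibble::tibble(
    model = c("allelic", "carriership"),
    risk_allele = x$risk_allele,
    statistic = c(x$allele_test$statistic, x$carrier_test$statistic),
    df = c(x$allele_test$df, x$carrier_test$df),
    p.value = c(x$allele_test$p.value, x$carrier_test$p.value),
    estimate = c(x$allele_or$estimate, x$carrier_or$estimate),
    conf.low = c(x$allele_or$conf.low, x$carrier_or$conf.low),
    conf.high = c(x$allele_or$conf.high, x$carrier_or$conf.high))
}

#' @rdname tidy.ccr5_assoc
#' @method glance ccr5_assoc
#' @export
glance.ccr5_assoc <- function(x, ...) {
  tibble::tibble(
    or_allelic = x$allele_or$estimate,
    ci_low_allelic = x$allele_or$conf.low,
    ci_high_allelic = x$allele_or$conf.high,
    p_allelic = x$allele_test$p.value,
    or_carrier = x$carrier_or$estimate,
    ci_low_carrier = x$carrier_or$conf.low,
    ci_high_carrier = x$carrier_or$conf.high,
    p_carrier = x$carrier_test$p.value,
    pct_carrier_case = unname(x$carrier_pct["case"]),
    pct_carrier_control = unname(x$carrier_pct["control"]),
    hwe_p_case = x$hwe$case$p.value,
    hwe_p_control = x$hwe$control$p.value)
}
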