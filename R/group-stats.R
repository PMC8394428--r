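# Group comparisons used downstream of the expression and kinetic scores:
# Mann-Whitney U, Kruskal-Wallis, one-way ANOVA, Bonferroni post-hoc.

#' @keywords internal
pull_groups <- function(data, value, group) {
  v <- rlang::eval_tidy(value, data)
  g <- rlang::eval_tidy(group, data)
  if (length(v) != length(g)) rlang::abort("value/group lengths differ.")
  keep <- !is.na(v) & !is.na(g)
  split(as.numeric(v[keep]), as.character(g[keep]))
}

#' @keywords internal
new_ccr5_test <- function(statistic, p, method, groups, adjustment = "none") {
  structure(list(statistic = statistic, p.value = p, method = method,
                 n_per_group = vapply(groups, length, integer(1)),
                 adjustment = adjustment),
            class = "ccr5_test")
}

# exact permutation distribution of the rank-sum of group 1: counts of
# n1-subsets of the (tied, midranked) pooled ranks by subset sum, via
# cardinality-constrained subset-sum DP on the half-integer grid
#' @keywords internal
ranksum_exact_p <- function(ranks, n1, u_obs) {
  r2 <- as.integer(round(2 * ranks))     # midranks live on a 0.5 grid
  n <- length(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # counts[k+1, s+1] = number of k-subsets with rank2-sum s
  counts <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  counts[1L, 1L] <- 1
  for (i in seq_len(n)) {
    kmax <- min(i, n1)
    for (k in kmax:1) {
      shifted <- c(rep(0, r2[i]), counts[k, seq_len(smax + 1L - r2[i])])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  dist <- counts[n1 + 1L, ]
  total <- sum(dist)
  n2 <- n - n1
  # U = R1 - n1(n1+1)/2 ; work on the doubled grid
  u2 <- (seq_along(dist) - 1L) - n1 * (n1 + 1L)
  u2_obs <- round(2 * u_obs)
  p_le <- sum(dist[u2 <= u2_obs]) / total
  p_ge <- sum(dist[u2 >= u2_obs]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U test for two groups
#'
#' U is computed from midranks (ties share their average rank). The
#' two-sided p-value is exact — from the complete permutation distribution of
#' the rank sum, which accommodates ties — whenever `n1 * n2 <=
#' exact_threshold`, and otherwise uses the normal approximation with the
#' standard tie-corrected variance (no continuity correction). The reported
#' `statistic` is U for the first group (alphabetical group order).
#'
#' @param data Data frame in tidy form.
#' @param value,group Columns holding the measurements and the two group
#'   labels (bare names; default `value`, `group`).
#' @param exact_threshold Use the exact distribution when the product of the
#'   group sizes is at most this (default 400).
#' @return A `ccr5_test` object (see [glance.ccr5_test()]).
#' @export
#' @examples
#' d <- tibble::tibble(value = c(1, 2, 3, 4, 5, 6),
#'                     group = rep(c("a", "b"), each = 3))
#' mann_whitney(d)  # exact two-sided p = 0.1
mann_whitney <- function(data, value = value, group = group,
                         exact_threshold = 400) {
  groups <- pull_groups(data, rlang::enquo(value), rlang::enquo(group))
  if (length(groups) != 2L) {
    rlang::abort(sprintf("Mann-Whitney needs exactly 2 groups, got %d.",
                         length(groups)))
  }
  groups <- groups[order(names(groups))]
  x <- groups[[1]]; y <- groups[[2]]
  if (length(x) == 0L || length(y) == 0L) {
    rlang::abort("Both groups must be non-empty.")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  ranks <- rank(c(x, y))             # midranks
  u <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  exact <- n1 * n2 <= exact_threshold
  if (exact) {
    p <- ranksum_exact_p(ranks, n1, u)
    method <- "Mann-Whitney U (exact, midranks)"
  } else {
    ties <- table(ranks)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  new_ccr5_test(c(U = u), min(1, p), method, groups)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' `groups - 1` degrees of freedom (via [stats::kruskal.test()]). A fully
#' degenerate input (every value identical) returns `H = 0`, `p = 1`.
#'
#' @inheritParams mann_whitney
#' @return A `ccr5_test` object.
#' @export
kruskal_wallis <- function(data, value = value, group = group) {
  groups <- pull_groups(data, rlang::enquo(value), rlang::enquo(group))
  if (length(groups) < 2L || any(lengths(groups) == 0L)) {
    rlang::abort("Kruskal-Wallis needs at least 2 non-empty groups.")
  }
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    return(new_ccr5_test(c(H = 0), 1, "Kruskal-Wallis rank test", groups))
  }
  kt <- stats::kruskal.test(vals, factor(rep(names(groups), lengths(groups))))
  new_ccr5_test(c(H = unname(kt$statistic)), kt$p.value,
                "Kruskal-Wallis rank test", groups)
}

#' One-way analysis of variance
#'
#' Classical equal-variance F test (`F = MS_between / MS_within`, via
#' [stats::oneway.test()] with `var.equal = TRUE`). A degenerate input with
#' zero within-group variance everywhere is flagged with `p = NA`.
#'
#' @inheritParams mann_whitney
#' @return A `ccr5_test` object.
#' @export
one_way_anova <- function(data, value = value, group = group) {
  groups <- pull_groups(data, rlang::enquo(value), rlang::enquo(group))
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    rlang::abort("ANOVA needs at least 2 groups with at least 2 values each.")
  }
  within_var <- vapply(groups, stats::var, numeric(1))
  if (all(within_var == 0)) {
    out <- new_ccr5_test(c(F = NA_real_), NA_real_,
                         "One-way ANOVA (degenerate: zero within-group variance)",
                         groups)
    return(out)
  }
  vals <- unlist(groups, use.names = FALSE)
  ft <- stats::oneway.test(vals ~ factor(rep(names(groups), lengths(groups))),
                           var.equal = TRUE)
  new_ccr5_test(c(F = unname(ft$statistic)), ft$p.value,
                "One-way ANOVA (equal variances)", groups)
}

#' Pairwise post-hoc comparisons with Bonferroni correction
#'
#' Tests every unordered pair of groups with the Mann-Whitney U test and
#' multiplies each raw p-value by the number of comparisons, capped at 1
#' (Bonferroni).
#'
#' @inheritParams mann_whitney
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @return Tibble with one row per pair: `group1`, `group2`, `statistic`,
#'   `p.value`, `p.adjusted`, `n1`, `n2`.
#' @export
pairwise_posthoc <- function(data, value = value, group = group,
                             adjustment = c("bonferroni", "none"),
                             exact_threshold = 400) {
  adjustment <- match.arg(adjustment)
  value <- rlang::enquo(value); group <- rlang::enquo(group)
  groups <- pull_groups(data, value, group)
  if (length(groups) < 2L) rlang::abort("Need at least 2 groups.")
  labels <- sort(names(groups))
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    d <- tibble::tibble(
      value = c(groups[[pr[1]]], groups[[pr[2]]]),
      group = rep(pr, c(length(groups[[pr[1]]]), length(groups[[pr[2]]]))))
    t <- mann_whitney(d, exact_threshold = exact_threshold)
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   statistic = unname(t$statistic), p.value = t$p.value,
                   n1 = unname(t$n_per_group[1]), n2 = unname(t$n_per_group[2]))
  })
  res$p.adjusted <- if (adjustment == "bonferroni") {
    pmin(1, res$p.value * nrow(res))
  } else {
    res$p.value
  }
  res
}

#' @export
print.ccr5_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  %s = %.4g, p = %.4g (n = %s)\n",
              names(x$statistic) %||% "stat", x$statistic, x$p.value,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}
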