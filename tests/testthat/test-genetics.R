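# Allele counting, HWE, Pearson chi-square, odds ratios, carriership.

test_that("allele counts follow the 2*hom + het identity on the study counts", {
  counts <- tibble::tibble(group = c("control", "case"),
                           n_AA = c(92L, 21L), n_AG = c(115L, 54L),
                           n_GG = c(50L, 31L))
  out <- count_alleles(counts)
  expect_identical(out$n_A, c(299L, 96L))
  expect_identical(out$n_G, c(215L, 116L))
  expect_identical(out$n_A + out$n_G,
                   2L * (counts$n_AA + counts$n_AG + counts$n_GG))
  zero <- count_alleles(tibble::tibble(n_AA = 0L, n_AG = 0L, n_GG = 0L))
  expect_identical(c(zero$n_A, zero$n_G), c(0L, 0L))
})

test_that("HWE chi-square matches direct computation from allele frequency", {
  h <- hwe_test(92, 115, 50)
  # independent hand computation: expected counts from p = 299/514
  p <- 299 / 514
  expected <- 257 * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(92, 115, 50) - expected)^2 / expected)
  expect_equal(h$statistic, chi2, tolerance = 1e-12)
  expect_equal(unname(h$expected), expected, tolerance = 1e-12)
  expect_gt(h$p.value, 0.05)
  expect_identical(h$df, 1L)
  expect_equal(sum(h$expected), 257)
})

test_that("HWE is zero at exact equilibrium and undefined for monomorphic groups", {
  expect_equal(hwe_test(25, 50, 25)$statistic, 0, tolerance = 1e-12)
  mono <- hwe_test(40, 0, 0)
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$p.value))
})

test_that("Pearson chi-square reproduces the published allelic and responder tests", {
  allele <- pearson_chi2(rbind(case = c(116, 96), control = c(215, 299)))
  expect_equal(allele$statistic, 10.05, tolerance = 0.005)
  expect_equal(round(allele$p.value, 4), 0.0015)
  expect_identical(allele$df, 1L)

  resp <- pearson_chi2(rbind(AA = c(6, 1), AG = c(4, 3), GG = c(1, 6)))
  expect_equal(round(resp$statistic, 1), 7.3)
  expect_equal(round(resp$p.value, 3), 0.027)
  expect_identical(resp$df, 2L)
})

test_that("chi-square is zero for proportional rows and errors on zero margins", {
  expect_equal(pearson_chi2(rbind(c(10, 20), c(30, 60)))$statistic, 0,
               tolerance = 1e-12)
  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "zero margin")
  expect_error(pearson_chi2(rbind(c(5, 0), c(3, 0))), "column")
})

test_that("r x c chi-square agrees with stats::chisq.test and the 2x2 closed form", {
  withr::with_seed(42, {
    for (i in 1:20) {
      tab <- matrix(rpois(6, 30) + 1, nrow = sample(2:3, 1))
      ours <- pearson_chi2(tab)
      ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
      expect_equal(unname(ours$expected), unname(ref$expected),
                   tolerance = 1e-12)
    }
    for (i in 1:20) {
      t2 <- matrix(rpois(4, 40) + 1, nrow = 2)
      a <- t2[1, 1]; b <- t2[1, 2]; c <- t2[2, 1]; d <- t2[2, 2]
      closed <- sum(t2) * (a * d - b * c)^2 /
        (prod(rowSums(t2)) * prod(colSums(t2)))
      expect_equal(pearson_chi2(t2)$statistic, closed, tolerance = 1e-10)
    }
  })
})

test_that("chi-square is invariant to simultaneous row/column swaps", {
  tab <- rbind(c(116, 96), c(215, 299))
  swapped <- tab[2:1, 2:1]
  expect_equal(pearson_chi2(tab)$statistic, pearson_chi2(swapped)$statistic,
               tolerance = 1e-12)
})

test_that("Wald odds ratios reproduce the published allelic and carriership CIs", {
  allelic <- odds_ratio(rbind(c(116, 96), c(215, 299)))
  expect_equal(round(allelic$estimate, 3), 1.680)
  expect_equal(round(allelic$conf.low, 2), 1.22)
  expect_equal(round(allelic$conf.high, 2), 2.32)

  carrier <- odds_ratio(rbind(c(85, 21), c(165, 92)))
  expect_equal(round(carrier$estimate, 3), 2.257)
  expect_equal(round(carrier$conf.low, 2), 1.31)
  expect_equal(round(carrier$conf.high, 2), 3.88)
})

test_that("odds ratio is 1 with a straddling CI for symmetric tables, and label swap inverts it", {
  sym <- odds_ratio(matrix(20, 2, 2))
  expect_equal(sym$estimate, 1, tolerance = 1e-12)
  expect_lt(sym$conf.low, 1)
  expect_gt(sym$conf.high, 1)

  tab <- rbind(c(85, 21), c(165, 92))
  orig <- odds_ratio(tab)
  flipped <- odds_ratio(tab[, 2:1])
  expect_equal(flipped$estimate, 1 / orig$estimate, tolerance = 1e-12)
  expect_equal(flipped$conf.low, 1 / orig$conf.high, tolerance = 1e-12)
  expect_equal(flipped$conf.high, 1 / orig$conf.low, tolerance = 1e-12)
})

test_that("zero cells error by default and engage the Haldane mode when asked", {
  tab <- rbind(c(0, 10), c(5, 5))
  expect_error(odds_ratio(tab), "Zero cell")
  h <- odds_ratio(tab, haldane = TRUE)
  expect_true(h$corrected)
  expect_equal(h$estimate, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
})

test_that("carriership collapses genotypes correctly for either risk allele", {
  counts <- tibble::tibble(group = c("case", "control"),
                           n_AA = c(21L, 92L), n_AG = c(54L, 115L),
                           n_GG = c(31L, 50L))
  g <- carriership_table(counts, "G")
  expect_equal(unname(g["case", ]), c(85, 21))
  expect_equal(unname(g["control", ]), c(165, 92))
  a <- carriership_table(counts, "A")
  expect_equal(unname(a["case", ]), c(75, 31))
})

test_that("association report reproduces all published percentages", {
  rep <- association_report(rs1799987_cohort(), risk_allele = "G")
  expect_equal(unname(rep$allele_pct["control", ]), c(42, 58))   # G, A
  expect_equal(unname(rep$allele_pct["case", ]), c(55, 45))
  expect_equal(unname(rep$genotype_pct["control", ]), c(36, 45, 19))
  expect_equal(unname(rep$genotype_pct["case", ]), c(20, 51, 29))
  expect_equal(unname(rep$carrier_pct), c(80, 64))
  expect_equal(round(rep$carrier_test$p.value, 4), 0.0028)
  # tidy/glance surfaces carry the same numbers
  td <- tidy(rep)
  expect_equal(td$estimate[td$model == "allelic"], rep$allele_or$estimate)
  expect_equal(glance(rep)$pct_carrier_case, 80)
})

test_that("association report flags HWE as undefined for a single-genotype group", {
  cohort <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:40),
    group = rep(c("case", "control"), each = 20),
    genotype = c(rep("AA", 20), rep(c("AA", "AG", "GG"), length.out = 20)))
  rep <- association_report(cohort, haldane = TRUE)
  expect_true(rep$hwe$case$monomorphic)
  expect_false(rep$hwe$control$monomorphic)
  expect_true(rep$allele_or$corrected)  # zero-G case cells flagged
})

test_that("missing genotypes are excluded listwise and counted", {
  cohort <- rs1799987_cohort()
  cohort$genotype[c(1, 2, 200)] <- NA
  counts <- genotype_counts(cohort)
  expect_identical(attr(counts, "n_missing"), 3L)
  expect_equal(sum(counts$n), 360)
})
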