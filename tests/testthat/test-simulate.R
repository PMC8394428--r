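# Synthetic generator: HWE sampling, expression mixtures, kinetic curves.

test_that("degenerate allele frequencies produce a single genotype", {
  cfg <- cohort_sim_config(n_cases = 30, n_controls = 30,
                           freq_g_cases = 0, freq_g_controls = 0, seed = 1)
  cohort <- simulate_genotype_cohort(cfg)
  expect_true(all(cohort$genotype == "AA"))
  cfg$freq_g_cases <- cfg$freq_g_controls <- 1
  expect_true(all(simulate_genotype_cohort(cfg)$genotype == "GG"))
})

test_that("genotype counts match the HWE binomial expectation over replicates", {
  # E[GG] = n q^2 = 257 * 0.4183^2 = 44.97 at the control allele frequency
  q <- 215 / 514
  n_rep <- 2000
  gg <- withr::with_seed(7, vapply(seq_len(n_rep), function(i) {
    cohort <- simulate_genotype_cohort(
      cohort_sim_config(n_cases = 1, n_controls = 257,
                        freq_g_controls = q, seed = NULL))
    sum(cohort$genotype == "GG" & cohort$group == "control")
  }, numeric(1)))
  expected <- 257 * q^2
  mc_se <- sqrt(257 * q^2 * (1 - q^2)) / sqrt(n_rep)
  expect_lt(abs(mean(gg) - expected), 3 * mc_se)
  expect_equal(expected, 44.97, tolerance = 0.001)
})

test_that("cohort sizes and allele-count identities always hold", {
  cohort <- simulate_genotype_cohort(cohort_sim_config(seed = 3))
  expect_identical(sum(cohort$group == "case"), 106L)
  expect_identical(sum(cohort$group == "control"), 257L)
  counts <- count_alleles(genotype_counts(cohort))
  expect_identical(counts$n_A + counts$n_G, 2L * counts$n)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- cohort_sim_config(seed = 11)
  expect_identical(simulate_genotype_cohort(cfg), simulate_genotype_cohort(cfg))

  ecfg <- expression_sim_config(events_per_subject = 500, seed = 11)
  a1 <- simulate_expression_events("AG", ecfg)
  a2 <- simulate_expression_events("AG", ecfg)
  expect_identical(a1$stained, a2$stained)
  expect_identical(a1$isotype, a2$isotype)

  kcfg <- kinetic_sim_config(events_per_second = 10, seed = 11)
  expect_identical(simulate_kinetic_run("GG", "mip1a", config = kcfg),
                   simulate_kinetic_run("GG", "mip1a", config = kcfg))
})

test_that("a zero positive fraction leaves only the isotype false-positive rate", {
  cfg <- expression_sim_config(
    pct_positive_mean = c(AA = 0, AG = 0, GG = 0),
    pct_positive_sd = c(AA = 0, AG = 0, GG = 0),
    events_per_subject = 4000, seed = 5)
  acq <- simulate_expression_events("AA", cfg)
  out <- quantify_expression(acq, percentile = 99.5)
  expect_lt(out$pct_positive, 2)   # ~0.5% nonspecific + sampling noise
})

test_that("GG expression defaults are recovered through the full pipeline", {
  n_subj <- 200
  cfg <- expression_sim_config(events_per_subject = 2000)
  out <- withr::with_seed(21,
    expression_cohort_summaries(rep("GG", n_subj), cfg, seed = NULL))
  se <- 20.80 / sqrt(n_subj)
  # small positive bias is expected: [0,100] clamping of the drawn percent
  # and the 0.5% isotype false-positive rate both push upward
  expect_lt(abs(mean(out$pct_positive) - 41.06), 2 * se + 1.6)
  # recovered percent tracks each subject's drawn truth tightly
  expect_gt(stats::cor(out$pct_positive, out$true_pct_positive), 0.98)
})

test_that("null expression simulation rejects at roughly the nominal rate", {
  cfg <- expression_sim_config(
    pct_positive_mean = c(AA = 30, AG = 30, GG = 30),
    pct_positive_sd = c(AA = 10, AG = 10, GG = 10),
    mfi_mean = c(AA = 1500, AG = 1500, GG = 1500),
    mfi_sd = c(AA = 500, AG = 500, GG = 500),
    events_per_subject = 200)
  p <- withr::with_seed(32, vapply(seq_len(60), function(i) {
    out <- expression_cohort_summaries(rep(c("AA", "AG", "GG"), each = 7),
                                       cfg, seed = NULL)
    kruskal_wallis(out, pct_positive, genotype)$p.value
  }, numeric(1)))
  expect_lt(mean(p < 0.05), 0.2)  # far from systematic rejection under the null
})

test_that("kinetic event stream is stationary before the stimulus and rises after", {
  cfg <- kinetic_sim_config(seed = 13)
  run <- simulate_kinetic_run("AA", "mip1a", responder = TRUE, config = cfg)
  expect_true(all(run$time_s >= 0 & run$time_s <= 200))
  pre <- run$marker[run$time_s < 40]
  early <- run$marker[run$time_s > 43 & run$time_s < 55]
  expect_equal(median(pre), 100, tolerance = 0.02)
  expect_gt(median(early), 115)
})

test_that("fMLP runs are sustained while MIP-1a runs are transient", {
  cfg <- kinetic_sim_config(seed = 17)
  fmlp <- simulate_kinetic_run("AA", "fmlp", config = cfg)
  late_f <- median(fmlp$marker[fmlp$time_s > 180])
  expect_gt(late_f, 100 + 0.9 * attr(fmlp, "amplitude"))
  mip <- simulate_kinetic_run("AA", "mip1a", responder = TRUE, config = cfg)
  peak_m <- median(mip$marker[mip$time_s > 43 & mip$time_s < 50])
  late_m <- median(mip$marker[mip$time_s > 180])
  expect_lt(late_m - 100, 0.3 * (peak_m - 100))  # decayed well below peak
})

test_that("responder draws match the configured genotype probabilities", {
  cfg <- kinetic_sim_config(events_per_second = 2, total_time_s = 50,
                            stim_time_s = 40)
  n_rep <- 300
  drawn <- withr::with_seed(19, vapply(GENOTYPES, function(g) {
    mean(vapply(seq_len(n_rep), function(i) {
      attr(simulate_kinetic_run(g, "mip1a", config = cfg), "responder")
    }, logical(1)))
  }, numeric(1)))
  probs <- c(AA = 6 / 7, AG = 4 / 7, GG = 1 / 7)
  se <- sqrt(probs * (1 - probs) / n_rep)
  expect_true(all(abs(drawn - probs) < 3 * se))
  # fMLP always responds
  f <- simulate_kinetic_run("GG", "fmlp", config = kinetic_sim_config(seed = 2))
  expect_true(attr(f, "responder"))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_sim_config(n_cases = 0), "positive")
  expect_error(cohort_sim_config(freq_g_cases = 1.2), "probability")
  expect_error(kinetic_sim_config(stim_time_s = 300, total_time_s = 200),
               "stim_time")
  expect_error(simulate_expression_events("AB"), "genotype")
})
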