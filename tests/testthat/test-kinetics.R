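# Trace binning, AUC/time, net and relative responses, responder calls.

test_that("trace bins take the median of their events", {
  ev <- make_events(40, marker = 5, time_s = seq(0.05, 3.95, by = 0.1))
  tr <- build_trace(ev, bin_width_s = 1)
  expect_equal(tr$mfi, rep(5, 4))
  expect_equal(tr$t_mid, c(0.5, 1.5, 2.5, 3.5))
  expect_identical(tr$n_events, rep(10L, 4))

  alt <- make_events(8, marker = rep(c(10, 20), 4),
                     time_s = c(0.1, 0.2, 0.3, 0.4, 1.1, 1.2, 1.3, 1.4))
  expect_equal(build_trace(alt, 1)$mfi, c(15, 15))
})

test_that("empty bins are kept with n_events = 0 and NA MFI", {
  ev <- make_events(4, marker = 3, time_s = c(0.5, 0.6, 2.5, 2.6))
  tr <- build_trace(ev, 1)
  expect_identical(tr$n_events, c(2L, 0L, 2L))
  expect_true(is.na(tr$mfi[2]))
  expect_error(build_trace(make_events(0)), "zero events")
})

test_that("trace binning does not depend on event order", {
  ev <- make_events(100, time_s = withr::with_seed(3, runif(100, 0, 10)))
  ev$marker <- withr::with_seed(4, rlnorm(100, 4, 0.3))
  shuffled <- ev[withr::with_seed(5, sample.int(100)), ]
  expect_equal(build_trace(ev, 1)$mfi, build_trace(shuffled, 1)$mfi)
})

test_that("AUC/time equals the closed form for constant and linear traces", {
  const <- make_trace(rep(7, 50))
  expect_equal(auc_per_time(const, c(0, 50)), 7, tolerance = 1e-12)

  ramp <- make_trace(seq(0.5, 9.5, by = 1))  # mfi = t over 10 s
  expect_equal(auc_per_time(ramp, c(0, 10)), 5.0, tolerance = 1e-12)
})

test_that("AUC/time errors informatively when a window lacks bins", {
  tr <- make_trace(rep(1, 10))
  expect_error(auc_per_time(tr, c(30, 40)), "\\[30, 40\\]")
  gap <- make_trace(c(1, NA, NA, 1, 1))
  expect_error(auc_per_time(gap, c(1, 3)), "non-empty bin")
})

test_that("trapezoid on a noiseless synthetic run matches the analytic integral", {
  cfg <- kinetic_sim_config(baseline_noise_sd = 0, seed = 6)
  run <- simulate_kinetic_run("AA", "mip1a", responder = TRUE, config = cfg)
  tr <- build_trace(gate_events(run), 1)
  a <- attr(run, "amplitude")
  for (win in list(c(40, 61), c(23, 40), c(45, 120))) {
    keep <- !is.na(tr$mfi) & tr$t_mid >= win[1] & tr$t_mid <= win[2]
    t1 <- min(tr$t_mid[keep]); t2 <- max(tr$t_mid[keep])
    oracle <- curve_integral(t1, t2, b = 100, a = a, t0 = 40, r = 3,
                             tau = 30) / (t2 - t1)
    expect_equal(auc_per_time(tr, win), oracle, tolerance = 0.01)
  }
})

test_that("rectangle rule at fine widths converges to the trapezoid AUC/time", {
  # brute-force oracle on the generating curve itself
  shape <- function(t) {
    ifelse(t <= 0, 0, ifelse(t < 3, t / 3, exp(-(t - 3) / 30)))
  }
  curve <- function(t) 100 + 30 * shape(t - 40)
  t_fine <- seq(40.5, 60.5, by = 1e-4)
  rect <- mean(curve(t_fine))
  tr <- make_trace(curve(seq(0.5, 199.5, by = 1)))
  expect_equal(auc_per_time(tr, c(40, 61)), rect, tolerance = 0.005)
})

test_that("net response is zero for flat traces and exact for noiseless steps", {
  flat <- make_trace(rep(100, 200))
  expect_equal(net_response(flat), 0, tolerance = 1e-12)

  # instantaneous noiseless step: fMLP plateau with no rise time
  cfg <- kinetic_sim_config(baseline_noise_sd = 0, rise_s = 0, seed = 10)
  run <- simulate_kinetic_run("AG", "fmlp", config = cfg)
  tr <- build_trace(gate_events(run), 1)
  expect_equal(net_response(tr), cfg$fmlp_net_target[["AG"]],
               tolerance = 1e-9)
})

test_that("net response is invariant to a constant shift and scales linearly", {
  cfg <- kinetic_sim_config(baseline_noise_sd = 0, seed = 14)
  run <- simulate_kinetic_run("AA", "mip1a", responder = TRUE, config = cfg)
  tr <- build_trace(gate_events(run), 1)
  net <- net_response(tr)

  shifted <- tr
  shifted$mfi <- shifted$mfi + 55
  expect_equal(net_response(shifted), net, tolerance = 1e-9)

  scaled <- tr
  scaled$mfi <- 100 + 2.5 * (scaled$mfi - 100)   # scale above shared baseline
  expect_equal(net_response(scaled), 2.5 * net, tolerance = 1e-9)
})

test_that("relative response handles the trivial and invalid-control cases", {
  expect_equal(relative_response(5, 5), 1)
  expect_equal(relative_response(0, 60), 0)
  expect_equal(relative_response(-3, 60), -0.05)
  expect_warning(out <- relative_response(5, -1), "non-positive fMLP")
  expect_true(is.na(out))
})

test_that("equal scaling of both runs leaves the relative response unchanged", {
  cfg <- kinetic_sim_config(baseline_noise_sd = 0, seed = 15)
  mip <- build_trace(gate_events(
    simulate_kinetic_run("AG", "mip1a", responder = TRUE, config = cfg)), 1)
  fmlp <- build_trace(gate_events(
    simulate_kinetic_run("AG", "fmlp", config = cfg)), 1)
  r1 <- relative_response(net_response(mip), net_response(fmlp))
  scale_tr <- function(tr, s) {
    tr$mfi <- 100 + s * (tr$mfi - 100)
    tr
  }
  r2 <- relative_response(net_response(scale_tr(mip, 3)),
                          net_response(scale_tr(fmlp, 3)))
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("responder calls separate flat traces from clear steps", {
  flat <- make_trace(rep(100, 200))
  expect_message(res_flat <- classify_responder(flat), "Degenerate baseline")
  expect_false(as.logical(res_flat))

  step <- make_trace(c(rep(100, 40), rep(140, 160)))
  expect_message(res_step <- classify_responder(step), "Degenerate baseline")
  expect_true(as.logical(res_step))

  noisy_flat <- make_trace(100 + withr::with_seed(16, rnorm(200, 0, 1)))
  expect_false(as.logical(classify_responder(noisy_flat)))

  short <- make_trace(rep(100, 41))
  short$mfi[1:38] <- NA
  expect_error(classify_responder(short), "at least 3")
})

test_that("responder association reproduces the published genotype x responder test", {
  scores <- tibble::tibble(
    genotype = rep(c("AA", "AG", "GG"), each = 7),
    responder = c(rep(TRUE, 6), FALSE,
                  rep(TRUE, 4), rep(FALSE, 3),
                  TRUE, rep(FALSE, 6)))
  res <- responder_association(scores)
  expect_equal(round(res$statistic, 1), 7.3)
  expect_equal(round(res$p.value, 3), 0.027)
  expect_identical(res$df, 2L)

  prop <- tibble::tibble(
    genotype = rep(c("AA", "AG", "GG"), each = 4),
    responder = rep(c(TRUE, TRUE, FALSE, FALSE), 3))
  expect_equal(responder_association(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(responder_association(scores[1:7, ]), "2 genotype groups")
})

test_that("full kinetic scoring is deterministic and recovers generative truth", {
  genos <- rep(c("AA", "AG", "GG"), each = 3)
  s1 <- kinetic_cohort_scores(genos, seed = 23)
  s2 <- kinetic_cohort_scores(genos, seed = 23)
  expect_identical(s1, s2)
  expect_identical(s1$responder, s1$responder_true)
  expect_true(all(s1$net_fmlp > 0))
})
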