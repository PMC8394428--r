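# Synthetic cohort and per-event cytometry generators. Defaults reproduce the
# statistical structure of the Löfgren's syndrome study conditions: HWE
# genotype sampling at the observed allele frequencies, genotype-dependent
# CCR5 expression, and genotype-dependent calcium responder probability and
# response magnitude.

# ---- configs -----------------------------------------------------------

#' Configuration for simulating a case-control genotype cohort
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium within each group at
#' the configured G-allele frequency. Defaults: 106 cases at the case G
#' frequency observed in the study cohort (116/212) and 257 controls at the
#' European-population frequency 0.4327.
#'
#' @param n_cases,n_controls Group sizes (positive integers).
#' @param freq_g_cases,freq_g_controls G-allele frequency per group, in
#'   `[0, 1]`.
#' @param seed Optional integer master seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_cases = 106L, n_controls = 257L,
                              freq_g_cases = 116 / 212,
                              freq_g_controls = 0.4327,
                              seed = NULL) {
  assert_count(n_cases, "n_cases")
  assert_count(n_controls, "n_controls")
  assert_prob(freq_g_cases, "freq_g_cases")
  assert_prob(freq_g_controls, "freq_g_controls")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 freq_g_cases = freq_g_cases,
                 freq_g_controls = freq_g_controls,
                 seed = seed),
            class = "cohort_sim_config")
}

#' Configuration for simulating CCR5 expression panel events
#'
#' Each subject draws a true percent-CCR5-positive value from a genotype
#' specific normal distribution truncated to `[0, 100]`, and a positive
#' population MFI from a genotype-specific lognormal. Events are a mixture of
#' a "positive" population (lognormal around the subject MFI) and a
#' "background" population shared with the matched isotype control, so that
#' isotype-anchored thresholding is meaningful. Default means/SDs are the
#' published group summaries: percent positive 41.06 (SD 20.80) for GG vs
#' 24.53 (SD 11.32) for A-allele carriers; MFI 2324.97 (SD 1382.38) for
#' G carriers vs 1283.65 (SD 523.47) for AA.
#'
#' @param pct_positive_mean,pct_positive_sd Named numeric vectors
#'   (`AA`, `AG`, `GG`): mean and SD of the true percent positive.
#' @param mfi_mean,mfi_sd Named numeric vectors: arithmetic mean and SD of the
#'   positive-population MFI (internally matched by a lognormal).
#' @param events_per_subject Events per acquisition.
#' @param background_meanlog,background_sdlog Lognormal parameters of the
#'   background/isotype fluorescence.
#' @param subset_weights Mixture weights of classical / intermediate /
#'   non-classical monocytes (must sum to 1).
#' @param seed Optional integer master seed.
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(
    pct_positive_mean = c(AA = 24.53, AG = 24.53, GG = 41.06),
    pct_positive_sd = c(AA = 11.32, AG = 11.32, GG = 20.80),
    mfi_mean = c(AA = 1283.65, AG = 2324.97, GG = 2324.97),
    mfi_sd = c(AA = 523.47, AG = 1382.38, GG = 1382.38),
    events_per_subject = 5000L,
    background_meanlog = log(50), background_sdlog = 0.5,
    subset_weights = c(classical = 0.85, intermediate = 0.10,
                       nonclassical = 0.05),
    seed = NULL) {
  assert_count(events_per_subject, "events_per_subject")
  for (v in list(pct_positive_mean, pct_positive_sd, mfi_mean, mfi_sd)) {
    stopifnot(all(GENOTYPES %in% names(v)))
  }
  if (abs(sum(subset_weights) - 1) > 1e-8) {
    rlang::abort("`subset_weights` must sum to 1.",
                 class = "ccr5flux_config_error")
  }
  structure(list(pct_positive_mean = pct_positive_mean,
                 pct_positive_sd = pct_positive_sd,
                 mfi_mean = mfi_mean, mfi_sd = mfi_sd,
                 events_per_subject = as.integer(events_per_subject),
                 background_meanlog = background_meanlog,
                 background_sdlog = background_sdlog,
                 subset_weights = subset_weights,
                 seed = seed),
            class = "expression_sim_config")
}

#' Configuration for simulating calcium-flux kinetic runs
#'
#' A kinetic acquisition is a Poisson-timed event stream over
#' `[0, total_time_s]`: cells pass the laser once, so events sample a
#' deterministic population calcium curve with multiplicative lognormal
#' event noise. The curve is flat at `baseline_level` before the stimulus;
#' after stimulus addition, responder MIP-1alpha runs rise (linear ramp over
#' `rise_s`) and decay exponentially with time constant `decay_tau_s`
#' (transient), while fMLP runs rise to a sustained plateau held for the
#' rest of the acquisition (every subject responds to the positive control).
#'
#' Amplitudes are parameterised by the *expected net response* (response
#' frame AUC/time minus baseline AUC/time) rather than the raw peak, so the
#' defaults are directly the published group medians: MIP-1alpha net response
#' 23.25 / 16.35 / 5.35 (a.u.) for AA / AG / GG, and fMLP net responses
#' chosen so the MIP-1alpha:fMLP ratio is 0.38 / 0.24 / 0.07. Default
#' responder probabilities are the published responder fractions 6/7, 4/7,
#' 1/7.
#'
#' @param baseline_level Baseline fluo-4 MFI (a.u.).
#' @param baseline_noise_sd Event-level noise SD at baseline (a.u.);
#'   internally a coefficient of variation `baseline_noise_sd /
#'   baseline_level` applied multiplicatively (lognormal, mean 1).
#' @param responder_prob Named probabilities of a MIP-1alpha response per
#'   genotype.
#' @param mip_net_target Named expected MIP-1alpha net responses (a.u.) for
#'   responders.
#' @param fmlp_net_target Named expected fMLP net responses (a.u.).
#' @param rise_s Linear rise time of the response (seconds).
#' @param decay_tau_s Exponential decay constant of the MIP-1alpha transient
#'   (seconds).
#' @param stim_time_s Stimulus addition time (default 40 s of baseline).
#' @param total_time_s Total acquisition length (default 200 s).
#' @param events_per_second Mean gated-monocyte event rate.
#' @param mip_frame_s,fmlp_frame_s Response-frame lengths used to convert
#'   net-response targets into curve amplitudes (match [frame_spec()]).
#' @param seed Optional integer master seed.
#' @return A `kinetic_sim_config` list.
#' @export
kinetic_sim_config <- function(
    baseline_level = 100, baseline_noise_sd = 5,
    responder_prob = c(AA = 6 / 7, AG = 4 / 7, GG = 1 / 7),
    mip_net_target = c(AA = 23.25, AG = 16.35, GG = 5.35),
    fmlp_net_target = c(AA = 23.25 / 0.38, AG = 16.35 / 0.24, GG = 5.35 / 0.07),
    rise_s = 3, decay_tau_s = 30,
    stim_time_s = 40, total_time_s = 200,
    events_per_second = 100,
    mip_frame_s = 21, fmlp_frame_s = 49,
    seed = NULL) {
  if (stim_time_s <= 0 || stim_time_s >= total_time_s) {
    rlang::abort("Need 0 < stim_time_s < total_time_s.",
                 class = "ccr5flux_config_error")
  }
  for (g in GENOTYPES) assert_prob(responder_prob[[g]], paste0("responder_prob[", g, "]"))
  stopifnot(baseline_level > 0, baseline_noise_sd >= 0, events_per_second > 0,
            rise_s >= 0, decay_tau_s > 0)
  structure(list(baseline_level = baseline_level,
                 baseline_noise_sd = baseline_noise_sd,
                 responder_prob = responder_prob,
                 mip_net_target = mip_net_target,
                 fmlp_net_target = fmlp_net_target,
                 rise_s = rise_s, decay_tau_s = decay_tau_s,
                 stim_time_s = stim_time_s, total_time_s = total_time_s,
                 events_per_second = events_per_second,
                 mip_frame_s = mip_frame_s, fmlp_frame_s = fmlp_frame_s,
                 seed = seed),
            class = "kinetic_sim_config")
}

# ---- cohort ------------------------------------------------------------

#' Simulate a case-control genotype cohort under HWE
#'
#' @param config A [cohort_sim_config()].
#' @return Tibble with `subject_id`, `group` (`"case"`/`"control"`),
#'   `genotype`.
#' @export
#' @examples
#' simulate_genotype_cohort(cohort_sim_config(seed = 42))
simulate_genotype_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  draw <- function(n, q) {
    # HWE genotype probabilities with q = freq(G)
    p <- 1 - q
    sample(GENOTYPES, n, replace = TRUE, prob = c(p^2, 2 * p * q, q^2))
  }
  sim <- function() {
    tibble::tibble(
      subject_id = c(sprintf("case_%03d", seq_len(config$n_cases)),
                     sprintf("ctrl_%03d", seq_len(config$n_controls))),
      group = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
      genotype = c(draw(config$n_cases, config$freq_g_cases),
                   draw(config$n_controls, config$freq_g_controls)))
  }
  if (is.null(config$seed)) sim() else withr::with_seed(config$seed, sim())
}

# ---- shared channel machinery -------------------------------------------

# scatter + CD14/CD16 channels for n monocyte events with given subset labels
#' @keywords internal
monocyte_channels <- function(n, subset_weights) {
  idx <- sample.int(length(subset_weights), n, replace = TRUE,
                    prob = subset_weights)
  subset <- names(subset_weights)[idx]
  nonclassical <- subset == "nonclassical"
  classical <- subset == "classical"
  cd14 <- exp(stats::rnorm(n, sd = 0.30) +
                c(log(500), log(150))[nonclassical + 1L])
  cd16 <- exp(stats::rnorm(n, sd = 0.40) +
                c(log(300), log(30))[classical + 1L])
  tibble::tibble(
    fsc = stats::rnorm(n, 500, 50),
    ssc = stats::rnorm(n, 300, 40),
    cd14 = cd14, cd16 = cd16,
    subset_true = subset)
}

# ---- expression panel ----------------------------------------------------

#' Simulate a CCR5 expression acquisition and its matched isotype control
#'
#' Draws the subject's true percent-positive and positive-population MFI from
#' the genotype-specific distributions in `config`, then emits two event
#' tables: the CCR5-stained acquisition (mixture of positive and background
#' events) and the isotype control (background only).
#'
#' @param genotype `"AA"`, `"AG"` or `"GG"`.
#' @param config An [expression_sim_config()].
#' @param subject_id Identifier stored in the tables.
#' @return List with elements `stained` and `isotype`, each a tibble with
#'   columns `time_s`, `fsc`, `ssc`, `cd14`, `cd16`, `marker`,
#'   `subset_true`; the list carries attributes `true_pct_positive` and
#'   `true_mfi_positive` (the drawn generative values) plus `genotype`.
#' @export
simulate_expression_events <- function(genotype,
                                       config = expression_sim_config(),
                                       subject_id = "subject") {
  assert_genotype(genotype)
  stopifnot(inherits(config, "expression_sim_config"))
  n <- config$events_per_subject
  if (n <= 0) rlang::abort("events_per_subject must be positive.")

  sim <- function() {
    # subject-level truths
    pct <- stats::rnorm(1, config$pct_positive_mean[[genotype]],
                        config$pct_positive_sd[[genotype]])
    pct <- min(100, max(0, pct))
    mfi_par <- lognormal_from_mean_sd(config$mfi_mean[[genotype]],
                                      config$mfi_sd[[genotype]])
    mfi_pos <- stats::rlnorm(1, mfi_par$meanlog, mfi_par$sdlog)

    make_table <- function(n, positive_frac) {
      ch <- monocyte_channels(n, config$subset_weights)
      is_pos <- stats::runif(n) < positive_frac
      marker <- stats::rlnorm(n, config$background_meanlog,
                              config$background_sdlog)
      n_pos <- sum(is_pos)
      if (n_pos > 0) {
        # positive population: lognormal with median at the subject's MFI
        marker[is_pos] <- stats::rlnorm(n_pos, log(mfi_pos), 0.4)
      }
      dplyr::mutate(ch,
                    time_s = sort(stats::runif(n, 0, 60)),
                    marker = marker,
                    .before = 1)
    }
    out <- list(stained = make_table(n, pct / 100),
                isotype = make_table(n, 0))
    attr(out, "true_pct_positive") <- pct
    attr(out, "true_mfi_positive") <- mfi_pos
    attr(out, "genotype") <- genotype
    attr(out, "subject_id") <- subject_id
    attr(out, "marker_name") <- "ccr5"
    out
  }
  if (is.null(config$seed)) sim() else withr::with_seed(config$seed, sim())
}

# ---- kinetic runs --------------------------------------------------------

# expected time-average of the unit response shape over a frame of length L
# starting at the stimulus: linear rise over r, then either exponential decay
# (tau) or sustained plateau (tau = Inf).
#' @keywords internal
response_frame_factor <- function(frame_s, rise_s, decay_tau_s = Inf) {
  stopifnot(frame_s > rise_s)
  rise_part <- rise_s / 2
  post <- frame_s - rise_s
  tail_part <- if (is.finite(decay_tau_s)) {
    decay_tau_s * (1 - exp(-post / decay_tau_s))
  } else {
    post
  }
  (rise_part + tail_part) / frame_s
}

# unit response shape evaluated at times t (seconds after stimulus)
#' @keywords internal
response_shape <- function(t, rise_s, decay_tau_s = Inf) {
  s <- numeric(length(t))
  up <- t > 0 & t < rise_s
  s[up] <- t[up] / rise_s
  post <- t >= rise_s
  s[post] <- if (is.finite(decay_tau_s)) {
    exp(-(t[post] - rise_s) / decay_tau_s)
  } else {
    1
  }
  s
}

#' Simulate one calcium-flux kinetic acquisition
#'
#' @param genotype `"AA"`, `"AG"` or `"GG"` (selects amplitude and, when
#'   `responder = NULL`, the responder probability).
#' @param stimulus `"mip1a"` or `"fmlp"`. fMLP runs always respond (positive
#'   control); the `responder` flag is ignored for them.
#' @param responder Logical; for MIP-1alpha runs, whether this subject
#'   responds. `NULL` draws it from `config$responder_prob[[genotype]]`.
#' @param config A [kinetic_sim_config()].
#' @param subject_id Identifier stored in the table.
#' @return Tibble of events (`time_s`, `fsc`, `ssc`, `cd14`, `cd16`,
#'   `marker`, `subset_true`) sorted by time, with attributes `stimulus`,
#'   `stim_time_s`, `total_time_s`, `responder` (the generative truth),
#'   `amplitude`, `genotype`, `subject_id`, `marker_name = "fluo4"`.
#' @export
simulate_kinetic_run <- function(genotype,
                                 stimulus = c("mip1a", "fmlp"),
                                 responder = NULL,
                                 config = kinetic_sim_config(),
                                 subject_id = "subject") {
  assert_genotype(genotype)
  stimulus <- match.arg(stimulus)
  stopifnot(inherits(config, "kinetic_sim_config"))

  sim <- function() {
    if (stimulus == "fmlp") {
      responds <- TRUE
      amp <- config$fmlp_net_target[[genotype]] /
        response_frame_factor(config$fmlp_frame_s, config$rise_s, Inf)
      tau <- Inf
    } else {
      responds <- if (is.null(responder)) {
        stats::runif(1) < config$responder_prob[[genotype]]
      } else {
        isTRUE(responder)
      }
      amp <- if (responds) {
        config$mip_net_target[[genotype]] /
          response_frame_factor(config$mip_frame_s, config$rise_s,
                                config$decay_tau_s)
      } else {
        0
      }
      tau <- config$decay_tau_s
    }

    n <- stats::rpois(1, config$events_per_second * config$total_time_s)
    if (n == 0) rlang::abort("Simulated acquisition has zero events.")
    t <- sort(stats::runif(n, 0, config$total_time_s))
    curve <- config$baseline_level +
      amp * response_shape(t - config$stim_time_s, config$rise_s, tau)
    cv <- config$baseline_noise_sd / config$baseline_level
    noise <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, -sdlog^2 / 2, sdlog)  # mean-1 multiplicative noise
    } else {
      1
    }
    ch <- monocyte_channels(n, c(classical = 0.85, intermediate = 0.10,
                                 nonclassical = 0.05))
    out <- dplyr::mutate(ch, time_s = t, marker = curve * noise, .before = 1)
    attr(out, "stimulus") <- stimulus
    attr(out, "stim_time_s") <- config$stim_time_s
    attr(out, "total_time_s") <- config$total_time_s
    attr(out, "responder") <- responds
    attr(out, "amplitude") <- amp
    attr(out, "genotype") <- genotype
    attr(out, "subject_id") <- subject_id
    attr(out, "marker_name") <- "fluo4"
    out
  }
  if (is.null(config$seed)) sim() else withr::with_seed(config$seed, sim())
}
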