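# Shared oracle helpers, independent of the implementation paths they check.

# closed-form integral of the kinetic population curve over absolute times
# [t1, t2] (curve: baseline b; from t0, linear rise over r to amplitude a,
# then exp decay with tau, or sustained plateau when tau = Inf)
curve_integral <- function(t1, t2, b, a, t0, r, tau = Inf) {
  shape_int <- function(u) {  # integral of unit shape over [0, u], u >= 0
    if (u <= 0) return(0)
    rise <- if (u < r) u^2 / (2 * r) else r / 2
    post <- max(0, u - r)
    tail <- if (is.finite(tau)) tau * (1 - exp(-post / tau)) else post
    rise + tail
  }
  b * (t2 - t1) + a * (shape_int(t2 - t0) - shape_int(t1 - t0))
}

# trace built directly from a deterministic curve (no events), for tests of
# the frame arithmetic in isolation
make_trace <- function(mfi, bin_width_s = 1, stimulus = "mip1a",
                       stim_time_s = 40) {
  out <- tibble::tibble(
    t_mid = (seq_along(mfi) - 0.5) * bin_width_s,
    mfi = mfi,
    n_events = rep(10L, length(mfi)))
  class(out) <- c("ccr5_trace", class(out))
  attr(out, "bin_width_s") <- bin_width_s
  attr(out, "stimulus") <- stimulus
  attr(out, "stim_time_s") <- stim_time_s
  out
}

# event table with exactly known channel values (noiseless fixtures)
make_events <- function(n, fsc = 500, ssc = 300, cd14 = 500, cd16 = 30,
                        marker = 100, time_s = NULL) {
  tibble::tibble(
    time_s = time_s %||% seq(0, 1, length.out = n),
    fsc = rep_len(fsc, n), ssc = rep_len(ssc, n),
    cd14 = rep_len(cd14, n), cd16 = rep_len(cd16, n),
    marker = rep_len(marker, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
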