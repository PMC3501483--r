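# simple hand-built sweep: flat baseline, linear rise to a peak, linear
# relaxation to a plateau, then exponential-ish return to baseline
ramp_trace <- function(peak = -1, plateau = -0.4, baseline = 0,
                       light_on = 0.5, light_off = 0.8, sweep = 1,
                       rate = 1000) {
  tt <- seq(0, sweep, by = 1 / rate)
  y <- rep(baseline, length(tt))
  t_peak <- light_on + 0.02
  rise <- tt >= light_on & tt < t_peak
  y[rise] <- baseline + (peak - baseline) * (tt[rise] - light_on) / 0.02
  dec <- tt >= t_peak & tt < light_off
  y[dec] <- baseline + plateau - baseline + (peak - plateau) *
    pmax(0, 1 - (tt[dec] - t_peak) / 0.05)
  off <- tt >= light_off
  y[off] <- baseline + (plateau - baseline) * exp(-(tt[off] - light_off) / 0.02)
  tevc_trace(tt, y, -120, light_on, light_off)
}

test_that("segmentation covers the sweep with contiguous windows around the peak", {
  tr <- ramp_trace()
  seg <- segment_trace(tr)
  expect_equal(tr$times[max(seg$baseline)], 0.5 - 1e-3)  # [0, 0.5)
  expect_equal(tr$times[seg$peak_index], 0.52, tolerance = 2e-3)
  expect_equal(max(seg$rise), seg$peak_index)
  expect_equal(min(seg$decay), seg$peak_index)
  expect_equal(min(seg$off), max(seg$decay) + 1L)
  covered <- sort(c(seg$baseline, seg$rise, seg$decay[-1], seg$off))
  expect_identical(covered, seq_along(tr$times))
})

test_that("segmentation fails loudly when no light-window peak exists", {
  tt <- seq(0, 1, by = 1e-3)
  flat <- tevc_trace(tt, rep(0, length(tt)), -120, 0.2, 0.6)
  expect_error(segment_trace(flat), "no photocurrent peak")
})

test_that("peak of a simulated WT sweep matches the eigen-derived peak time", {
  tr <- wt_like_trace()
  seg <- segment_trace(tr)
  t_peak <- tr$times[seg$peak_index] - tr$light_on
  # oracle: locate the conductance maximum by exact expm propagation of the
  # light-on generator on a fine grid
  p <- photocycle_params()
  A <- chr2pore:::photocycle_matrix(p, light = 1)
  tg <- seq(0, 0.1, by = 1e-4)
  cond <- vapply(tg, function(t) {
    s <- as.vector(Matrix::expm(A * t) %*% c(1, 0, 0, 0))
    s[2] + p$gamma * s[3]
  }, 0)
  t_ref <- tg[which.max(cond)]
  expect_lt(abs(t_peak - t_ref), 1e-3)
  expect_gt(t_peak, 0)
})

test_that("inactivation ratio is by construction and scale/offset invariant", {
  tr <- ramp_trace(peak = -1, plateau = -0.4)
  s <- summarize_sweep(tr, steady_window_ms = 50)
  expect_equal(s$Iss_over_Ip, 0.4, tolerance = 1e-2)
  expect_equal(s$I_p, -1, tolerance = 1e-6)
  for (k in c(0.5, 3)) {
    tr2 <- tr; tr2$currents <- tr$currents * k
    expect_equal(summarize_sweep(tr2)$Iss_over_Ip, s$Iss_over_Ip,
                 tolerance = 1e-12)
  }
  tr3 <- tr; tr3$currents <- tr$currents + 2.5  # baseline shift
  expect_equal(summarize_sweep(tr3)$Iss_over_Ip, s$Iss_over_Ip,
               tolerance = 1e-9)
  expect_error(summarize_sweep(tr, steady_window_ms = 500), "shorter")
})

test_that("reducing the O1->O2 transition raises the stationary/peak ratio", {
  r_full <- summarize_sweep(wt_like_trace())$Iss_over_Ip
  p_less <- photocycle_params(e12 = photocycle_params()$e12 / 4)
  r_less <- summarize_sweep(wt_like_trace(params = p_less))$Iss_over_Ip
  expect_gt(r_less, r_full)
})

test_that("noiseless biexponential segments are recovered to spec precision", {
  proto <- protocol_spec(sample_rate_Hz = 20000, sweep_s = 0.5,
                         light_on = 0, light_off = 0.005)
  tr <- make_biexp_trace(A1 = -1, tau1_ms = 5, A2 = -1, tau2_ms = 50,
                         protocol = proto)
  # fit the full sampled decay so the generator amplitudes apply unshifted
  fit <- fit_exp_series(tr$times, tr$currents, n_components = 2L)
  expect_true(fit$converged)
  taus <- sort(fit$components$tau_ms)
  expect_lt(abs(taus[1] - 5) / 5, 0.005)
  expect_lt(abs(taus[2] - 50) / 50, 0.005)
  # equal amplitudes: weighted tau = 27.5 ms
  expect_lt(abs(fit$tau_weighted_ms - 27.5) / 27.5, 0.005)
  expect_gt(fit$r2, 0.9999)
  # weighted tau lies between the component taus; components sorted by |A|
  expect_true(fit$tau_weighted_ms >= min(taus) &&
              fit$tau_weighted_ms <= max(taus))
  expect_true(all(diff(abs(fit$components$amplitude)) <= 0))
})

test_that("fits are deterministic and flag degenerate segments", {
  proto <- protocol_spec(sample_rate_Hz = 5000, sweep_s = 0.5,
                         light_on = 0, light_off = 0.005)
  tr <- make_biexp_trace(-1, 5, -1, 50, protocol = proto,
                         noise_sd = 0.01, seed = 2)
  f1 <- fit_exponential(tr, "off", 2L)
  f2 <- fit_exponential(tr, "off", 2L)
  expect_identical(f1, f2)
  # constant segment: offset-only result, converged = FALSE
  tt <- seq(0, 1, by = 1e-3)
  y <- c(rep(0, 300), seq(0, -1, length.out = 50),
         rep(-1, 350), rep(0.7, 301))
  const <- tevc_trace(tt, y, -120, 0.3, 0.7)
  f <- fit_exponential(const, "off")
  expect_false(f$converged)
  expect_equal(f$offset, 0.7, tolerance = 1e-9)
})

test_that("same-day WT normalization divides peak currents and enforces days", {
  expect_equal(normalize_to_reference(-2, -4), 0.5)
  expect_equal(normalize_to_reference(-3, -3), 1)
  expect_error(normalize_to_reference(-2, -4, day = "d1", wt_day = "d2"),
               "same-day")
  expect_error(normalize_to_reference(-2, 0), "nonzero")
})

test_that("apparent kinetics of the calibrated WT simulator match their targets", {
  k <- sweep_kinetics(wt_like_trace())
  expect_equal(k$tau_on_ms, 4.6, tolerance = 0.05)
  expect_equal(k$tau_decay_ms, 122, tolerance = 0.05)
  expect_equal(k$tau_off_ms, 12.1, tolerance = 0.05)
})
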