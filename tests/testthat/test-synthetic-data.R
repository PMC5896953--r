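test_that("generator output is fixed exactly by config + seed", {
  a <- make_tbs_session(tbs_gen_config(seed = 5, baseline_min = 1,
                                       post_min = 0))
  b <- make_tbs_session(tbs_gen_config(seed = 5, baseline_min = 1,
                                       post_min = 0))
  expect_identical(lapply(a$sweeps, `[[`, "samples"),
                   lapply(b$sweeps, `[[`, "samples"))
  expect_identical(a$metadata$truth, b$metadata$truth)

  p1 <- make_dual_ap_session(propagation_gen_config(seed = 2), c(50, 150))
  p2 <- make_dual_ap_session(propagation_gen_config(seed = 2), c(50, 150))
  expect_identical(p1[[1]]$dend$samples, p2[[1]]$dend$samples)

  s1 <- make_patch_sweep_set(patch_gen_config(seed = 3))
  s2 <- make_patch_sweep_set(patch_gen_config(seed = 3))
  expect_identical(s1$test_sweep$samples, s2$test_sweep$samples)

  c1 <- make_ltp_cohort(ltp_cohort_config(seed = 4))
  c2 <- make_ltp_cohort(ltp_cohort_config(seed = 4))
  expect_identical(lapply(c1, `[[`, "epsp_series"),
                   lapply(c2, `[[`, "epsp_series"))
})

test_that("spikelet-free, plateau-free induction stays below the spikelet threshold", {
  # with no regenerative events the compound EPSP response must never
  # reach the 2.5 mV/ms dendritic-spike criterion
  cfg <- quiet_tbs(spikelet_rate = 0, plateau_amp_mV = 0, seed = 9)
  ses <- make_tbs_session(cfg)
  mx <- max(vapply(ses$sweeps,
                   function(s) max(sweep_derivative(s)$samples), 1.0))
  expect_lt(mx, 2.5)
  # the analytic kernel slope bound agrees with dense evaluation
  analytic <- biexp_max_slope(cfg$epsp_amp_mV, cfg$epsp_rise_ms,
                              cfg$epsp_decay_ms)
  t_dense <- seq(0, 100, by = 1e-3)
  k <- cfg$epsp_amp_mV * biexp_kernel(t_dense, cfg$epsp_rise_ms,
                                      cfg$epsp_decay_ms)
  expect_equal(max(diff(k) / 1e-3), analytic, tolerance = 1e-3)
  expect_lt(analytic, 2.5)
})

test_that("a spikelet dV/dt target colliding with the AP class is a config error", {
  expect_error(tbs_gen_config(spikelet_dvdt_targets = c(4.2, 45),
                              ap_enabled = FALSE),
               "collide")
  expect_silent(tbs_gen_config(spikelet_dvdt_targets = c(4.2, 45),
                               ap_enabled = TRUE))
})

test_that("a single strong spikelet target yields exactly one strong event", {
  ses <- make_induction_session(
    quiet_tbs(spikelet_dvdt_targets = 14.5, seed = 21), n_spikelets = 1)
  ev <- detect_session_events(ses, epoch = "induction")
  ev <- ev[ev$event_class != "epsp_only", ]
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$event_class, "strong_dspike")
})

test_that("dual-recording ground truth follows the closed forms", {
  cfg0 <- propagation_gen_config(latency_jitter_ms = 0, amp_noise_sd_mV = 0)
  prs <- make_dual_ap_session(cfg0, c(0, 147, 226))
  pts <- propagation_points(prs)
  # identity at the soma
  expect_equal(pts$amp_dend_mV[1], pts$amp_soma_mV[1], tolerance = 1e-6)
  expect_equal(pts$latency_ms[1], 0, tolerance = 1e-6)
  # x = lambda: amplitude falls to 1/e of the somatic value
  expect_equal(pts$amp_dend_mV[2], 93.6 * exp(-1), tolerance = 2e-3)
  # x = velocity * 1 ms: latency 1 ms
  expect_equal(pts$latency_ms[3], 1, tolerance = 1e-3)
  expect_error(make_dual_ap_session(cfg0, -10), "within")
  expect_error(make_dual_ap_session(cfg0, 400), "within")
})

test_that("the passive patch response is linear and channel signs are enforced", {
  set0 <- make_patch_sweep_set(patch_gen_config(noise_sd_pA = 0))
  # -4 x the subpulse response reproduces the full passive response exactly
  expect_equal(-4 * set0$test_subpulses[[1]]$samples,
               set0$test_sweep$samples, tolerance = 1e-12)
  expect_error(patch_gen_config(i_a_soma_pA = -5), "non-negative")
  expect_error(patch_gen_config(i_na_soma_pA = 5), "non-positive")

  # sign conventions across generator configurations
  for (seed in 1:3) {
    st <- make_patch_sweep_set(
      patch_gen_config(seed = seed, noise_sd_pA = 0),
      recording_site("dendrite", 120),
      c(na = TRUE, ka = TRUE, kdr = TRUE))
    expect_lt(measure_component(st, "na")$peak_pA, 0)
    expect_gt(measure_component(st, "ka")$peak_pA, 0)
    expect_gt(measure_component(st, "kdr")$peak_pA, 0)
  }
})

test_that("LTP cohort nulls and config errors behave as specified", {
  coh <- make_ltp_cohort(ltp_cohort_config(ltp_slope_pct_per_spike = 0,
                                           ltp_noise_sd_pct = 0,
                                           meas_noise_sd_mV = 0, seed = 2))
  expect_equal(vapply(coh, ltp_magnitude, 1.0), rep(100, 13),
               tolerance = 1e-9)
  expect_error(make_ltp_cohort(ltp_cohort_config(ltp_intercept_pct = -50,
                                                 ltp_slope_pct_per_spike = 0,
                                                 ltp_noise_sd_pct = 0)),
               "non-positive")
  expect_error(ltp_cohort_config(n_cells = 1), "at least 2")
})

test_that("every inserted spikelet is recoverable from the ground-truth log", {
  for (seed in c(11, 12)) {
    ses <- make_induction_session(quiet_tbs(seed = seed), n_spikelets = 5)
    tr <- ses$metadata$truth$spikelets
    expect_equal(nrow(tr), 5L)
    ev <- detect_session_events(ses, epoch = "induction")
    ev <- ev[ev$event_class != "epsp_only", ]
    expect_equal(nrow(ev), 5L)
    # each logged event matched by a detection within 0.2 ms
    d_ms <- vapply(tr$time_s,
                   function(t) min(abs(ev$time_s - t)) * 1000, 1.0)
    expect_lt(max(d_ms), 0.2)
  }
})
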