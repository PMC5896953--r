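test_that("the derivative of simple traces is exact", {
  fs <- 20000
  # ramp of 1 mV per ms
  tt <- (0:999) / fs
  ramp <- new_sweep(tt * 1000, fs, "voltage")
  d <- sweep_derivative(ramp, detection_config())$samples
  # interior samples: the shrinking edge windows of the smoother see only
  # half the ramp, so the first/last window-width samples are excluded
  expect_equal(d[40:960], rep(1, 921), tolerance = 1e-9)
  # constant trace
  d0 <- sweep_derivative(flat_sweep(), detection_config())$samples
  expect_equal(d0, rep(0, 2000))
})

test_that("sweep_derivative equals the brute-force smoothing + difference oracle", {
  set.seed(42)
  fs <- 20000
  x <- cumsum(rnorm(1500)) / 10 - 81
  sw <- new_sweep(x, fs, "voltage")
  for (w_ms in c(0.5, 1.5)) {
    cfg <- detection_config(smooth_window_ms = w_ms)
    expect_equal(sweep_derivative(sw, cfg)$samples,
                 brute_dvdt(x, fs, w_ms), tolerance = 1e-10)
  }
  # window shorter than 2 samples falls back with a warning
  expect_warning(sweep_derivative(sw, detection_config(smooth_window_ms = 0.01)),
                 "skipping smoothing")
})

test_that("classification is the half-open threshold ladder at both sites", {
  soma <- recording_site("soma")
  dend <- recording_site("dendrite", 150)
  cfg <- detection_config()
  expect_identical(classify_dvdt(1.3, soma, cfg), "epsp_only")
  expect_identical(classify_dvdt(4.2, soma, cfg), "weak_dspike")
  expect_identical(classify_dvdt(14.5, soma, cfg), "strong_dspike")
  # boundary convention: half-open intervals
  expect_identical(classify_dvdt(c(2.5, 10, 40), soma, cfg),
                   c("weak_dspike", "strong_dspike", "axosomatic_ap"))
  expect_identical(classify_dvdt(c(2.4999, 9.9999, 39.9999), soma, cfg),
                   c("epsp_only", "weak_dspike", "strong_dspike"))
  # site dependence: the AP threshold drops to 20 mV/ms at the dendrite
  expect_identical(classify_dvdt(30, soma, cfg), "strong_dspike")
  expect_identical(classify_dvdt(30, dend, cfg), "axosomatic_ap")
  # total and monotone in dvdt
  v <- seq(0, 60, by = 0.25)
  cl <- classify_dvdt(v, soma, cfg)
  ord <- c(epsp_only = 1, weak_dspike = 2, strong_dspike = 3,
           axosomatic_ap = 4)
  expect_true(all(diff(ord[cl]) >= 0))
  expect_error(classify_dvdt(-1, soma, cfg), "non-negative")
})

test_that("raising a spikelet's generator target never lowers its class", {
  ord <- c(epsp_only = 1, weak_dspike = 2, strong_dspike = 3,
           axosomatic_ap = 4)
  got <- vapply(c(3, 5, 9, 12, 20, 35), function(tg) {
    ses <- make_induction_session(
      quiet_tbs(spikelet_dvdt_targets = tg, seed = 33), n_spikelets = 1)
    ev <- detect_session_events(ses, epoch = "induction")
    ev <- ev[ev$event_class != "epsp_only", ]
    ord[[ev$event_class[which.max(ev$dvdt_peak)]]]
  }, 1.0)
  expect_true(all(diff(got) >= 0))
})

test_that("detect_events recovers logged spikelets with classes and times", {
  cfg3 <- quiet_tbs(spikelet_dvdt_targets = c(4, 6, 15), seed = 5)
  ses <- make_induction_session(cfg3, n_spikelets = 3)
  ev <- detect_session_events(ses, epoch = "induction")
  ev <- ev[ev$event_class != "epsp_only", ]
  tr <- ses$metadata$truth$spikelets
  expect_equal(nrow(ev), 3L)
  expect_setequal(ev$event_class, c("weak_dspike", "weak_dspike",
                                    "strong_dspike"))
  m <- vapply(tr$time_s, function(t) min(abs(ev$time_s - t)) * 1000, 1.0)
  expect_lt(max(m), 0.2)
  # detected peaks equal an exhaustive scan of the smoothed derivative
  sw <- ses$sweeps[[1]]
  d_oracle <- brute_dvdt(sw$samples, sw$sampling_rate, 1.5)
  for (i in which(ev$time_s < 5)) {
    idx <- which(abs(sweep_times(sw) - ev$time_s[i]) < 0.003)
    expect_equal(ev$dvdt_peak[i], max(d_oracle[idx]), tolerance = 1e-9)
  }
})

test_that("axosomatic APs are detected but excluded from dendritic-spike counts", {
  ses <- make_induction_session(
    quiet_tbs(ap_enabled = TRUE, ap_rate = 1, n_bursts = 2L,
              n_episodes = 1L, seed = 8), n_spikelets = 0)
  ev <- detect_session_events(ses, epoch = "induction")
  aps <- ev[ev$event_class == "axosomatic_ap", ]
  expect_equal(nrow(aps), nrow(ses$metadata$truth$aps))
  expect_equal(dspike_count(ses), 0L)
})

test_that("detect_events validates its inputs", {
  sw <- flat_sweep()
  expect_equal(nrow(detect_events(sw, stim_protocol(numeric(0), "test"))),
               0L)
  expect_error(detect_events(sw, stim_protocol(5, "test")),
               "inside the sweep")
})

test_that("ap_threshold finds the crossing at the analytically solved time", {
  # template with analytic max slope 300 mV/ms: amp = 300 * sd * sqrt(e)
  s_ms <- 0.3
  amp <- 300 * s_ms * exp(0.5)
  sw <- ap_sweep(amp = amp, sd_ms = s_ms, center_s = 0.02, fs = 50000)
  cfg <- detection_config(smooth_window_ms = 0)
  res <- ap_threshold(sw, recording_site("soma"), cfg)
  expect_true(res$found)
  # solve amp * u/s * exp(-u^2/2) = 40 on the outer rising branch
  u <- uniroot(function(u) amp * u / s_ms * exp(-u^2 / 2) - 40,
               c(1.5, 5))$root
  t_analytic <- 0.02 - u * s_ms / 1000
  expect_lt(abs(res$time_s - t_analytic), 1 / 50000)   # within one sample
})

test_that("ap_threshold distinguishes sites and reports not-found", {
  # peak dV/dt 30 mV/ms: crossing at dendritic threshold (20) only
  s_ms <- 1
  sw <- ap_sweep(amp = 30 * s_ms * exp(0.5), sd_ms = s_ms, fs = 50000)
  cfg <- detection_config(smooth_window_ms = 0.2)
  expect_true(ap_threshold(sw, recording_site("dendrite", 150), cfg)$found)
  expect_false(ap_threshold(sw, recording_site("soma"), cfg)$found)
  # subthreshold EPSP-only sweep: not found anywhere
  ses <- make_tbs_session(quiet_tbs(spikelet_rate = 0, n_episodes = 1L,
                                    n_bursts = 1L, seed = 2))
  expect_false(ap_threshold(ses$sweeps[[1]], recording_site("soma"),
                            detection_config())$found)
})
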