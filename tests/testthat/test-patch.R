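test_that("P over -4 cancels the passive response", {
  # noise-free: exact cancellation, and doubling the leak changes nothing
  for (g in c(1, 2)) {
    s0 <- make_patch_sweep_set(patch_gen_config(g_leak_nS = g,
                                                noise_sd_pA = 0))
    corr <- p_over_minus4(s0$test_sweep, s0$test_subpulses)
    expect_equal(max(abs(corr$samples)), 0, tolerance = 1e-10)
  }
  # noisy passive patches: corrected trace is zero-mean noise whose SD is
  # sqrt(1 + 16/n_sub) times the sweep noise
  sd_corr <- 0.2 * sqrt(1 + 16 / 4)
  for (seed in 1:20) {
    s <- make_patch_sweep_set(patch_gen_config(seed = seed))
    corr <- p_over_minus4(s$test_sweep, s$test_subpulses)
    idx <- which(sweep_times(corr) > s$protocol$na_test_on_s + 0.001 &
                   sweep_times(corr) < s$protocol$na_test_off_s)
    expect_lt(max(abs(corr$samples[idx])), 6 * sd_corr)
    expect_lt(abs(mean(corr$samples[idx])), 3 * sd_corr / sqrt(30))
  }
  expect_error(p_over_minus4(s0$test_sweep, list()), "between 1 and 4")
})

test_that("fewer subpulse sweeps still cancel the passive response", {
  s0 <- make_patch_sweep_set(patch_gen_config(noise_sd_pA = 0,
                                              n_subpulses = 2L))
  corr <- p_over_minus4(s0$test_sweep, s0$test_subpulses)
  expect_equal(max(abs(corr$samples)), 0, tolerance = 1e-10)
})

test_that("Na+ measurement recovers the generator peak", {
  soma <- recording_site("soma")
  s <- make_patch_sweep_set(patch_gen_config(noise_sd_pA = 0), soma,
                            c(na = TRUE))
  m <- measure_component(s, "na")
  expect_equal(m$peak_pA, -6.81, tolerance = 0.02)
  # noisy default: within the noise of the corrected trace
  s2 <- make_patch_sweep_set(patch_gen_config(seed = 5), soma,
                             c(na = TRUE))
  expect_equal(measure_component(s2, "na")$peak_pA, -6.81,
               tolerance = 4 * 0.2 * sqrt(5))
})

test_that("A-current isolation recovers per-site peaks and inactivates", {
  distal <- recording_site("dendrite", 150)
  s <- make_patch_sweep_set(patch_gen_config(noise_sd_pA = 0), distal,
                            c(ka = TRUE))
  expect_equal(measure_component(s, "ka")$peak_pA, 102.3, tolerance = 0.2)
  soma <- make_patch_sweep_set(patch_gen_config(noise_sd_pA = 0),
                               recording_site("soma"), c(ka = TRUE))
  expect_equal(measure_component(soma, "ka")$peak_pA, 30.4,
               tolerance = 0.06)
  # the isolated trace inactivates: < 20% of peak at the test-pulse end
  iso <- isolate_a_current(
    p_over_minus4(s$k_m120_sweep, s$k_m120_subpulses),
    p_over_minus4(s$k_m40_sweep, s$k_m40_subpulses))
  tt <- sweep_times(iso)
  tail_v <- mean(iso$samples[tt > s$protocol$k_test_off_s - 0.005 &
                               tt < s$protocol$k_test_off_s])
  expect_lt(abs(tail_v), 0.2 * max(iso$samples))
})

test_that("non-inactivating patches give a null A-current across seeds", {
  for (seed in 1:20) {
    s <- make_patch_sweep_set(patch_gen_config(seed = seed),
                              recording_site("dendrite", 120),
                              c(kdr = TRUE))
    iso <- isolate_a_current(
      p_over_minus4(s$k_m120_sweep, s$k_m120_subpulses),
      p_over_minus4(s$k_m40_sweep, s$k_m40_subpulses))
    idx <- which(sweep_times(iso) > s$protocol$k_test_on_s + 0.001 &
                   sweep_times(iso) < s$protocol$k_test_off_s)
    # difference of two corrected traces: noise SD sqrt(2)*sqrt(5)*0.2
    expect_lt(max(abs(iso$samples[idx])), 6 * sqrt(10) * 0.2)
  }
})

test_that("delayed-rectifier density is uniform across sites", {
  mk <- function(site) measure_component(
    make_patch_sweep_set(patch_gen_config(noise_sd_pA = 0), site,
                         c(kdr = TRUE)), "kdr")$peak_pA
  v_soma <- mk(recording_site("soma"))
  v_dist <- mk(recording_site("dendrite", 200))
  expect_equal(v_soma, v_dist)
  expect_equal(v_soma, 19.6, tolerance = 0.05)
})

test_that("measure_component validates missing sweep variants", {
  s <- make_patch_sweep_set(patch_gen_config(), recording_site("soma"),
                            c(ka = TRUE))
  s$k_m40_sweep <- NULL
  expect_error(measure_component(s, "ka"), "k_m40_sweep")
})

test_that("location grouping, ordering and the 100 um boundary", {
  m <- data.frame(
    site_kind = c(rep("soma", 3), rep("dendrite", 6)),
    distance_um = c(0, 0, 0, 30, 60, 99, 100, 150, 220),
    peak_pA = c(1, 2, 3, 101, 102, 103, 201, 202, 203))
  gt <- group_and_test(m)
  expect_identical(gt$groups$group, c("soma", "proximal", "distal"))
  expect_equal(gt$groups$n, c(3L, 3L, 3L))     # 100 um falls distal
  expect_true(all(diff(gt$groups$mean_pA) > 0))
  expect_lt(gt$kruskal$p_value, 0.05)
  # Dunn-adjusted p-values never undercut the unadjusted ones
  expect_true(all(gt$dunn$p_adj >= gt$dunn$p_unadj))
})

test_that("identical measurements take the H = 0 path without error", {
  m <- data.frame(site_kind = c("soma", "soma", "dendrite", "dendrite"),
                  distance_um = c(0, 0, 150, 160),
                  peak_pA = rep(7, 4))
  gt <- group_and_test(m)
  expect_equal(gt$kruskal$statistic, 0)
  expect_equal(gt$kruskal$p_value, 1)
  expect_true(all(gt$dunn$z == 0))
})
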