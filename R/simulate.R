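#' Synaptic and spike kernels used by the generator
#'
#' `biexp_kernel` is the peak-normalized difference of exponentials
#' `(exp(-t/decay) - exp(-t/rise)) / g_peak` (0 for `t < 0`), the standard
#' EPSP shape.  Its maximum slope sits exactly at onset, which
#' `biexp_max_slope` returns in closed form: `amp * (1/rise - 1/decay) /
#' g_peak` (mV/ms for `t` in ms).
#'
#' `gauss_kernel` is a Gaussian bump `exp(-(t - center)^2 / (2 sd^2))` used
#' for spikelets and AP templates; its slope maximum is interior and smooth,
#' `gauss_max_slope = amp * exp(-1/2) / sd`, so a target dV/dt peak converts
#' to an amplitude analytically and survives moderate smoothing.
#'
#' @param t_ms Time vector (ms).
#' @param rise_ms,decay_ms Biexponential time constants (ms, rise < decay).
#' @param center_ms,sd_ms Gaussian center and width (ms).
#' @param amp Peak amplitude (mV).
#' @return Kernel values, or the analytic maximum slope in mV/ms.
#' @name kernels
NULL

biexp_peak_factor <- function(rise_ms, decay_ms) {
  tp <- rise_ms * decay_ms / (decay_ms - rise_ms) * log(decay_ms / rise_ms)
  exp(-tp / decay_ms) - exp(-tp / rise_ms)
}

#' @rdname kernels
#' @export
biexp_kernel <- function(t_ms, rise_ms, decay_ms) {
  stopifnot(rise_ms > 0, decay_ms > rise_ms)
  g <- ifelse(t_ms < 0, 0, exp(-t_ms / decay_ms) - exp(-t_ms / rise_ms))
  g / biexp_peak_factor(rise_ms, decay_ms)
}

#' @rdname kernels
#' @export
biexp_max_slope <- function(amp, rise_ms, decay_ms) {
  amp * (1 / rise_ms - 1 / decay_ms) / biexp_peak_factor(rise_ms, decay_ms)
}

#' @rdname kernels
#' @export
gauss_kernel <- function(t_ms, center_ms, sd_ms) {
  exp(-(t_ms - center_ms)^2 / (2 * sd_ms^2))
}

#' @rdname kernels
#' @export
gauss_max_slope <- function(amp, sd_ms) {
  amp * exp(-0.5) / sd_ms
}

# additive recording noise: white Gaussian through a one-pole low pass at
# `corner_hz` (emulating the acquisition Bessel filter), renormalized so the
# output SD equals `sd`.
lp_noise <- function(n, sd, fs, corner_hz = 3000) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  x <- stats::rnorm(n)
  if (is.finite(corner_hz) && corner_hz > 0 && corner_hz < fs / 2) {
    a <- exp(-2 * pi * corner_hz / fs)
    s_stat <- sqrt((1 - a) / (1 + a))
    y <- stats::filter((1 - a) * x, a, method = "recursive",
                       init = stats::rnorm(1) * s_stat)
    x <- as.numeric(y) / s_stat
  }
  sd * x
}

# add `values` into x starting at the sample nearest t_rel_s (clipped)
add_at <- function(x, fs, t_rel_s, values) {
  i0 <- round(t_rel_s * fs) + 1L
  idx <- seq.int(i0, length.out = length(values))
  ok <- idx >= 1L & idx <= length(x)
  x[idx[ok]] <- x[idx[ok]] + values[ok]
  x
}

#' Configuration for synthetic theta-burst sessions
#'
#' Defaults reproduce the signal structure of TBS induction experiments:
#' 7 mV single-shock EPSPs whose kernel (rise 8 ms, decay 40 ms) has an
#' analytic maximum slope of ~1.3 mV/ms — the dV/dt of EPSPs without
#' dendritic spikes — with short-term depression within 100 Hz bursts, a
#' slow NMDAR-type plateau envelope peaking at 36.6 mV after each burst,
#' optional spikelets whose somatic dV/dt peaks are drawn from
#' `spikelet_dvdt_targets`, and optional stereotyped axosomatic APs.
#'
#' @param epsp_amp_mV First-pulse EPSP peak (mV).
#' @param epsp_rise_ms,epsp_decay_ms EPSP kernel time constants (ms).
#' @param depression Within-burst multiplicative depression per stimulus
#'   (floor 0.25).
#' @param spikelet_rate Probability that a burst contains a spikelet.
#' @param spikelet_dvdt_targets Intended somatic dV/dt peaks (mV/ms) drawn
#'   uniformly per inserted spikelet.
#' @param spikelet_sd_ms Gaussian width of the spikelet bump (ms).
#' @param spikelet_delay_ms Spikelet center delay after its stimulus (ms).
#' @param n_spikelets Optional exact number of spikelets to insert across
#'   the induction (overrides `spikelet_rate`).
#' @param plateau_amp_mV Plateau-envelope peak after a burst (mV);
#'   non-stacking across bursts (pointwise maximum of per-burst envelopes).
#' @param plateau_tau_ms Alpha-function time constant of the envelope (ms).
#' @param ap_enabled Insert axosomatic AP waveforms during bursts.
#' @param ap_amp_mV,ap_sd_ms,ap_rate AP template amplitude/width and
#'   per-burst insertion probability.
#' @param v_rest_mV Resting membrane potential (mV).
#' @param noise_sd_mV Additive recording-noise SD (mV).
#' @param noise_corner_hz Low-pass corner of the noise model (Hz).
#' @param sampling_rate Sampling rate (Hz).
#' @param n_episodes,n_bursts,n_stim TBS repeat structure.
#' @param baseline_min,post_min Minutes of 0.1 Hz test stimulation before
#'   and after induction (0 disables the epoch).
#' @param test_hz Test-stimulation rate (Hz).
#' @param post_scale Post-induction EPSP scaling (1.732 emulates the 173.2%
#'   LTP of spike-positive experiments; 1 is a no-change control).
#' @param seed RNG seed; fixes the session exactly.
#' @return An object of class `tbs_gen_config`.
#' @export
tbs_gen_config <- function(epsp_amp_mV = 7, epsp_rise_ms = 8,
                           epsp_decay_ms = 40, depression = 0.7,
                           spikelet_rate = 0.1,
                           spikelet_dvdt_targets = c(4.2, 14.5),
                           spikelet_sd_ms = 1.5, spikelet_delay_ms = 6,
                           n_spikelets = NULL,
                           plateau_amp_mV = 36.6, plateau_tau_ms = 150,
                           ap_enabled = FALSE, ap_amp_mV = 93.6,
                           ap_sd_ms = 0.25, ap_rate = 0.1,
                           v_rest_mV = -81.3,
                           noise_sd_mV = 0.3, noise_corner_hz = 3000,
                           sampling_rate = 20000,
                           n_episodes = 4L, n_bursts = 10L, n_stim = 10L,
                           baseline_min = 10, post_min = 30, test_hz = 0.1,
                           post_scale = 1.732, seed = 1L) {
  if (spikelet_rate < 0 || spikelet_rate > 1)
    stop("spikelet_rate must lie in [0, 1]", call. = FALSE)
  if (epsp_amp_mV < 0 || plateau_amp_mV < 0 || ap_amp_mV < 0 ||
      noise_sd_mV < 0)
    stop("amplitudes and noise SD must be non-negative", call. = FALSE)
  if (length(spikelet_dvdt_targets) &&
      any(spikelet_dvdt_targets >= detection_config()$ap_soma) && !ap_enabled)
    stop("spikelet dV/dt target at or above the somatic AP threshold with ",
         "ap_enabled = FALSE would collide with the AP class", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "tbs_gen_config"
  cfg
}

# deterministic within-episode backbone (EPSPs + plateau envelope) on the
# episode grid; identical for every episode, so computed once
tbs_episode_backbone <- function(cfg, n_ep_samp, pre_s) {
  fs <- cfg$sampling_rate
  x <- numeric(n_ep_samp)
  t_ker <- (seq_len(round(0.4 * fs)) - 1L) / fs * 1000
  ker1 <- biexp_kernel(t_ker, cfg$epsp_rise_ms, cfg$epsp_decay_ms)
  for (b in seq_len(cfg$n_bursts) - 1L) {
    for (s in seq_len(cfg$n_stim) - 1L) {
      amp <- cfg$epsp_amp_mV * max(cfg$depression^s, 0.25)
      x <- add_at(x, fs, pre_s + b / 5 + s / 100, amp * ker1)
    }
  }
  # plateau: pointwise max of per-burst alpha envelopes (non-stacking)
  tt <- (seq_len(n_ep_samp) - 1L) / fs
  env <- numeric(n_ep_samp)
  tau_s <- cfg$plateau_tau_ms / 1000
  for (b in seq_len(cfg$n_bursts) - 1L) {
    t_end <- pre_s + b / 5 + (cfg$n_stim - 1L) / 100 + 0.01
    u <- (tt - t_end) / tau_s
    a <- ifelse(u > 0, u * exp(1 - u), 0)
    env <- pmax(env, a)
  }
  x + cfg$plateau_amp_mV * env
}

#' Generate a synthetic theta-burst induction session
#'
#' Produces baseline test sweeps, `n_episodes` induction sweeps holding the
#' full TBS response (summating EPSPs, plateau envelopes, spikelets, and
#' optionally APs), and post-induction test sweeps scaled by `post_scale`.
#' Every inserted event and per-sweep EPSP amplitude is logged in
#' `metadata$truth`, so downstream recovery tests can compare against the
#' generator's ground truth rather than hard-coded numbers.
#'
#' @param cfg A [tbs_gen_config()].
#' @return A single-channel somatic [recording_session()]; `metadata$truth`
#'   holds `spikelets` (time, target dV/dt, episode, burst), `aps`, `epsp`
#'   (per test stimulus), `plateau_amp_mV` and `ltp_pct_true`.
#' @export
make_tbs_session <- function(cfg = tbs_gen_config()) {
  stopifnot(inherits(cfg, "tbs_gen_config"))
  set.seed(cfg$seed)
  fs <- cfg$sampling_rate
  pre_s <- 0.02
  ep_dur <- pre_s + (cfg$n_bursts - 1L) / 5 + (cfg$n_stim - 1L) / 100 +
    0.01 + 0.38
  n_ep <- round(ep_dur * fs)
  backbone <- tbs_episode_backbone(cfg, n_ep, pre_s)

  test_dur <- 0.3
  n_test <- round(test_dur * fs)
  t_ker <- (seq_len(round(0.28 * fs)) - 1L) / fs * 1000
  epsp_ker <- biexp_kernel(t_ker, cfg$epsp_rise_ms, cfg$epsp_decay_ms)

  test_sweep <- function(p, amp, epoch) {
    x <- rep(cfg$v_rest_mV, n_test)
    x <- add_at(x, fs, pre_s, amp * epsp_ker)
    x <- x + lp_noise(n_test, cfg$noise_sd_mV, fs, cfg$noise_corner_hz)
    new_sweep(x, fs, "voltage", t0 = p - pre_s, channel = 1L, epoch = epoch)
  }

  base_pulses <- if (cfg$baseline_min > 0)
    seq(-cfg$baseline_min * 60, -1 / cfg$test_hz, by = 1 / cfg$test_hz)
  else numeric(0)
  ind_proto <- tbs_protocol(0, cfg$n_episodes, cfg$n_bursts, cfg$n_stim)
  ind_end <- (cfg$n_episodes - 1L) * 10 + ep_dur
  post_pulses <- if (cfg$post_min > 0)
    seq(ceiling(ind_end) + 1 / cfg$test_hz,
        by = 1 / cfg$test_hz, length.out = cfg$post_min * 60 * cfg$test_hz)
  else numeric(0)

  sweeps <- list()
  truth_epsp <- list()
  for (p in base_pulses) {
    sweeps[[length(sweeps) + 1L]] <- test_sweep(p, cfg$epsp_amp_mV, "baseline")
    truth_epsp[[length(truth_epsp) + 1L]] <-
      data.frame(time_s = p, amp_mV = cfg$epsp_amp_mV, epoch = "baseline")
  }

  # spikelet schedule: one slot per (episode, burst)
  slots <- expand.grid(burst = seq_len(cfg$n_bursts),
                       episode = seq_len(cfg$n_episodes))
  if (!is.null(cfg$n_spikelets)) {
    if (cfg$n_spikelets > nrow(slots))
      stop("n_spikelets exceeds the number of bursts", call. = FALSE)
    chosen <- if (cfg$n_spikelets > 0)
      sample(nrow(slots), cfg$n_spikelets) else integer(0)
  } else {
    chosen <- which(stats::runif(nrow(slots)) < cfg$spikelet_rate)
  }
  spk <- list(); aps <- list()
  spk_sd <- cfg$spikelet_sd_ms
  t_spk <- seq(-5 * spk_sd, 5 * spk_sd, by = 1000 / fs)
  t_ap <- seq(-5 * cfg$ap_sd_ms, 5 * cfg$ap_sd_ms, by = 1000 / fs)

  for (e in seq_len(cfg$n_episodes)) {
    x <- cfg$v_rest_mV + backbone
    for (idx in chosen[slots$episode[chosen] == e]) {
      b <- slots$burst[idx]
      s_idx <- sample(seq_len(cfg$n_stim), 1L)
      target <- if (length(cfg$spikelet_dvdt_targets) == 1L)
        cfg$spikelet_dvdt_targets else sample(cfg$spikelet_dvdt_targets, 1L)
      center_rel <- pre_s + (b - 1L) / 5 + (s_idx - 1L) / 100 +
        cfg$spikelet_delay_ms / 1000
      amp <- target * spk_sd * exp(0.5)
      x <- add_at(x, fs, center_rel + t_spk[1L] / 1000,
                  amp * gauss_kernel(t_spk, 0, spk_sd))
      # logged time is the dV/dt-peak time of the bump (center - sd),
      # the quantity the detector reports
      spk[[length(spk) + 1L]] <-
        data.frame(time_s = (e - 1L) * 10 + center_rel - pre_s -
                     spk_sd / 1000,
                   target_dvdt = target, episode = e, burst = b)
    }
    if (cfg$ap_enabled) {
      for (b in seq_len(cfg$n_bursts)) {
        if (stats::runif(1) < cfg$ap_rate) {
          center_rel <- pre_s + (b - 1L) / 5 + 0.025
          x <- add_at(x, fs, center_rel + t_ap[1L] / 1000,
                      cfg$ap_amp_mV * gauss_kernel(t_ap, 0, cfg$ap_sd_ms))
          aps[[length(aps) + 1L]] <-
            data.frame(time_s = (e - 1L) * 10 + center_rel - pre_s,
                       episode = e, burst = b)
        }
      }
    }
    x <- x + lp_noise(n_ep, cfg$noise_sd_mV, fs, cfg$noise_corner_hz)
    sweeps[[length(sweeps) + 1L]] <-
      new_sweep(x, fs, "voltage", t0 = (e - 1L) * 10 - pre_s, channel = 1L,
                epoch = "induction")
  }

  for (p in post_pulses) {
    amp <- cfg$epsp_amp_mV * cfg$post_scale
    sweeps[[length(sweeps) + 1L]] <- test_sweep(p, amp, "post")
    truth_epsp[[length(truth_epsp) + 1L]] <-
      data.frame(time_s = p, amp_mV = amp, epoch = "post")
  }

  pulse_times <- c(base_pulses, ind_proto$pulse_times, post_pulses)
  proto <- stim_protocol(pulse_times, "TBS",
                         params = c(ind_proto$params,
                                    list(test_hz = cfg$test_hz)))
  truth <- list(
    spikelets = if (length(spk)) do.call(rbind, spk) else
      data.frame(time_s = numeric(0), target_dvdt = numeric(0),
                 episode = integer(0), burst = integer(0)),
    aps = if (length(aps)) do.call(rbind, aps) else
      data.frame(time_s = numeric(0), episode = integer(0),
                 burst = integer(0)),
    epsp = if (length(truth_epsp)) do.call(rbind, truth_epsp) else
      data.frame(time_s = numeric(0), amp_mV = numeric(0),
                 epoch = character(0)),
    plateau_amp_mV = cfg$plateau_amp_mV,
    ltp_pct_true = 100 * cfg$post_scale,
    n_spikelets = length(spk))
  recording_session(sweeps, proto, list(recording_site("soma")),
                    metadata = list(generator = "tbs", seed = cfg$seed,
                                    induction_time_s = 0, truth = truth))
}

#' Induction-only theta-burst session
#'
#' [make_tbs_session()] restricted to the four induction episodes (no
#' baseline or post test sweeps), optionally with an exact spikelet count —
#' the form used for detector specificity runs and cohort simulations.
#'
#' @param cfg A [tbs_gen_config()].
#' @param n_spikelets Optional exact spikelet count (overrides the rate).
#' @param seed Optional seed override.
#' @return A [recording_session()].
#' @export
make_induction_session <- function(cfg = tbs_gen_config(),
                                   n_spikelets = NULL, seed = NULL) {
  cfg$baseline_min <- 0
  cfg$post_min <- 0
  if (!is.null(n_spikelets)) cfg$n_spikelets <- n_spikelets
  if (!is.null(seed)) cfg$seed <- seed
  make_tbs_session(cfg)
}

#' Configuration for synthetic soma-dendrite AP propagation pairs
#'
#' Defaults encode the bAP phenomenology of mature granule cells: somatic
#' amplitude 93.6 mV attenuating as `exp(-x / 147 um)` (147 um solves
#' `93.6 exp(-150/lambda) = 33.7`, the printed soma/dendrite means) and a
#' conduction velocity of 226 um/ms with 0.05 ms latency jitter.
#'
#' @param v_soma_mV Somatic AP amplitude (mV).
#' @param lambda_um Attenuation length constant (um).
#' @param velocity_um_per_ms Conduction velocity (um/ms).
#' @param latency_jitter_ms Gaussian SD added to each latency (ms).
#' @param amp_noise_sd_mV Gaussian SD added to each dendritic amplitude (mV).
#' @param ap_sd_ms Gaussian AP template width (ms).
#' @param t_ap_s Somatic AP time within the sweep (s).
#' @param v_rest_mV Resting potential (mV).
#' @param sweep_dur_s Sweep duration (s).
#' @param sampling_rate Sampling rate (Hz).
#' @param total_length_um Total dendritic path length used for normalized
#'   analyses (um).
#' @param seed RNG seed.
#' @return An object of class `propagation_gen_config`.
#' @export
propagation_gen_config <- function(v_soma_mV = 93.6, lambda_um = 147,
                                   velocity_um_per_ms = 226,
                                   latency_jitter_ms = 0.05,
                                   amp_noise_sd_mV = 3,
                                   ap_sd_ms = 0.3, t_ap_s = 0.02,
                                   v_rest_mV = -81.3, sweep_dur_s = 0.06,
                                   sampling_rate = 50000,
                                   total_length_um = 278, seed = 1L) {
  if (lambda_um <= 0 || velocity_um_per_ms <= 0)
    stop("lambda_um and velocity_um_per_ms must be positive", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "propagation_gen_config"
  cfg
}

#' Generate paired soma-dendrite AP recordings
#'
#' For each requested distance `x`, the dendritic AP amplitude is
#' `v_soma * exp(-x / lambda) + noise` and its half-max latency
#' `x / velocity + jitter`; both realized values are logged as ground truth.
#' The AP template is a Gaussian bump, so half-max crossing times are
#' amplitude-free and the configured latency is recovered exactly in the
#' noise-free case.
#'
#' @param cfg A [propagation_gen_config()].
#' @param distances_um Dendritic recording distances (um, within 0-300).
#' @return A list of [dual_recording()] objects; each carries
#'   `truth$amp_dend_mV` and `truth$latency_ms`.
#' @export
make_dual_ap_session <- function(cfg = propagation_gen_config(),
                                 distances_um) {
  stopifnot(inherits(cfg, "propagation_gen_config"))
  if (any(!is.finite(distances_um)) || any(distances_um < 0) ||
      any(distances_um > 300))
    stop("distances must lie within [0, 300] um", call. = FALSE)
  set.seed(cfg$seed)
  fs <- cfg$sampling_rate
  n <- round(cfg$sweep_dur_s * fs)
  t_ms <- (seq_len(n) - 1L) / fs * 1000
  lapply(distances_um, function(x) {
    amp_d <- cfg$v_soma_mV * exp(-x / cfg$lambda_um) +
      stats::rnorm(1) * cfg$amp_noise_sd_mV
    amp_d <- max(amp_d, 1)
    lat <- x / cfg$velocity_um_per_ms + stats::rnorm(1) * cfg$latency_jitter_ms
    soma <- cfg$v_rest_mV + cfg$v_soma_mV *
      gauss_kernel(t_ms, cfg$t_ap_s * 1000, cfg$ap_sd_ms)
    dend <- cfg$v_rest_mV + amp_d *
      gauss_kernel(t_ms, cfg$t_ap_s * 1000 + lat, cfg$ap_sd_ms)
    dual_recording(
      new_sweep(soma, fs, "voltage", channel = 1L, epoch = "ap_train"),
      new_sweep(dend, fs, "voltage", channel = 2L, epoch = "ap_train"),
      distance_um = x, total_length_um = cfg$total_length_um,
      truth = list(amp_soma_mV = cfg$v_soma_mV, amp_dend_mV = amp_d,
                   latency_ms = lat))
  })
}

#' Configuration for synthetic outside-out patch sweep families
#'
#' Passive patch parameters plus per-site channel-current peaks; the
#' defaults are the per-group means of the recordings (Na: -6.81 soma,
#' -5.02 proximal, -7.17 distal pA; I_A: 30.4 / 61.5 / 102.3 pA; delayed
#' rectifier: uniform 19.6 pA).  Pulse protocols follow the measurement
#' conventions: holding -90 mV; Na, 100 ms prepulse to -120 mV then 30 ms
#' test to 0 mV; K, 150 ms prepulse (-120 or -40 mV) then 200 ms test to
#' +70 mV.
#'
#' @param g_leak_nS Patch leak conductance (nS, reversal at holding).
#' @param c_patch_pF Patch capacitance (pF).
#' @param cap_tau_ms Capacitive-transient decay (ms).
#' @param i_na_soma_pA,i_na_prox_pA,i_na_dist_pA Na+ peak by site group
#'   (pA, inward negative).
#' @param na_rise_ms,na_decay_ms Na+ transient kinetics (ms).
#' @param na_avail_m40 Na+ availability after a -40 mV prepulse (0-1).
#' @param i_a_soma_pA,i_a_prox_pA,i_a_dist_pA A-type K+ peak by site group
#'   (pA, outward positive); fully inactivated by the -40 mV prepulse.
#' @param ka_rise_ms,ka_decay_ms A-current kinetics (ms).
#' @param i_dr_peak_pA Delayed-rectifier peak (pA), uniform across sites.
#' @param kdr_rise_ms,kdr_inact_ms Delayed-rectifier kinetics (ms).
#' @param holding_mV,prepulse_m120,prepulse_m40,na_test_mV,k_test_mV Clamp
#'   levels (mV).
#' @param na_prepulse_ms,k_prepulse_ms,na_test_ms,k_test_ms,pre_hold_ms,post_hold_ms
#'   Segment durations (ms).
#' @param pipette_res_MOhm Open-tip resistance (MOhm), metadata only.
#' @param noise_sd_pA,noise_corner_hz Recording-noise model.
#' @param sampling_rate Sampling rate (Hz).
#' @param n_subpulses Number of -P/4 subpulse sweeps (1-4).
#' @param seed RNG seed.
#' @return An object of class `patch_gen_config`.
#' @export
patch_gen_config <- function(g_leak_nS = 1, c_patch_pF = 0.1,
                             cap_tau_ms = 0.1,
                             i_na_soma_pA = -6.81, i_na_prox_pA = -5.02,
                             i_na_dist_pA = -7.17,
                             na_rise_ms = 0.5, na_decay_ms = 4,
                             na_avail_m40 = 0.1,
                             i_a_soma_pA = 30.4, i_a_prox_pA = 61.5,
                             i_a_dist_pA = 102.3,
                             ka_rise_ms = 1, ka_decay_ms = 15,
                             i_dr_peak_pA = 19.6, kdr_rise_ms = 2,
                             kdr_inact_ms = 300,
                             holding_mV = -90, prepulse_m120 = -120,
                             prepulse_m40 = -40, na_test_mV = 0,
                             k_test_mV = 70,
                             na_prepulse_ms = 100, k_prepulse_ms = 150,
                             na_test_ms = 30, k_test_ms = 200,
                             pre_hold_ms = 10, post_hold_ms = 20,
                             pipette_res_MOhm = 18.8,
                             noise_sd_pA = 0.2, noise_corner_hz = 3000,
                             sampling_rate = 50000, n_subpulses = 4L,
                             seed = 1L) {
  if (any(c(i_a_soma_pA, i_a_prox_pA, i_a_dist_pA, i_dr_peak_pA) < 0))
    stop("K+ current peaks must be non-negative (outward)", call. = FALSE)
  if (any(c(i_na_soma_pA, i_na_prox_pA, i_na_dist_pA) > 0))
    stop("Na+ current peaks must be non-positive (inward)", call. = FALSE)
  if (n_subpulses < 1L || n_subpulses > 4L)
    stop("n_subpulses must be between 1 and 4", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "patch_gen_config"
  cfg
}

site_group <- function(site) {
  if (site$kind == "soma") "soma"
  else if (site$distance_um < 100) "proximal" else "distal"
}

patch_peak_for_site <- function(cfg, site, component) {
  g <- site_group(site)
  switch(component,
         na = switch(g, soma = cfg$i_na_soma_pA, proximal = cfg$i_na_prox_pA,
                     distal = cfg$i_na_dist_pA),
         ka = switch(g, soma = cfg$i_a_soma_pA, proximal = cfg$i_a_prox_pA,
                     distal = cfg$i_a_dist_pA),
         kdr = cfg$i_dr_peak_pA)
}

# passive (leak + capacitive) current response to a command waveform,
# linear in the command by construction
passive_response <- function(cmd_mV, cfg, fs) {
  leak <- cfg$g_leak_nS * (cmd_mV - cfg$holding_mV)  # nS * mV = pA
  steps <- which(diff(cmd_mV) != 0)
  cap <- numeric(length(cmd_mV))
  t_dec <- seq(0, 8 * cfg$cap_tau_ms, by = 1000 / fs)
  dec <- exp(-t_dec / cfg$cap_tau_ms)
  for (i in steps) {
    dv <- cmd_mV[i + 1L] - cmd_mV[i]
    amp <- dv * cfg$c_patch_pF / (cfg$cap_tau_ms)   # pF*mV/ms = pA
    cap <- add_at(cap, fs, i / fs, amp * dec)
  }
  leak + cap
}

#' Generate the voltage-clamp sweep family of one outside-out patch
#'
#' Builds the Na-protocol test sweep, its `-P/4` subpulse sweeps (command
#' scaled by -1/4, passive response only — channels do not gate in the
#' hyperpolarized subpulse range), and both K-protocol prepulse variants
#' (-120 and -40 mV) with their own subpulse families.  Channel currents are
#' included per `channel_mix`; the -40 mV prepulse fully inactivates the
#' A-current and reduces Na+ availability to `na_avail_m40`.
#'
#' @param cfg A [patch_gen_config()].
#' @param site A [recording_site()].
#' @param channel_mix Named logical flags `na`, `ka`, `kdr`; all `FALSE`
#'   gives a purely passive patch (used for linearity nulls).
#' @return An object of class `patch_sweep_set` with elements `test_sweep`,
#'   `test_subpulses`, `k_m120_sweep`, `k_m120_subpulses`, `k_m40_sweep`,
#'   `k_m40_subpulses`, `protocol`, `site`, `channel_mix`,
#'   `pipette_res_MOhm` and a `truth` log of the inserted peaks.
#' @export
make_patch_sweep_set <- function(cfg = patch_gen_config(),
                                 site = recording_site("soma"),
                                 channel_mix = c(na = FALSE, ka = FALSE,
                                                 kdr = FALSE)) {
  stopifnot(inherits(cfg, "patch_gen_config"))
  mix <- c(na = FALSE, ka = FALSE, kdr = FALSE)
  mix[names(channel_mix)] <- as.logical(channel_mix)
  set.seed(cfg$seed)
  fs <- cfg$sampling_rate

  build_cmd <- function(prepulse_mV, prepulse_ms, test_mV, test_ms) {
    n_pre0 <- round(cfg$pre_hold_ms / 1000 * fs)
    n_pre <- round(prepulse_ms / 1000 * fs)
    n_test <- round(test_ms / 1000 * fs)
    n_post <- round(cfg$post_hold_ms / 1000 * fs)
    cmd <- c(rep(cfg$holding_mV, n_pre0), rep(prepulse_mV, n_pre),
             rep(test_mV, n_test), rep(cfg$holding_mV, n_post))
    list(cmd = cmd, t_test_on = n_pre0 / fs + prepulse_ms / 1000,
         t_test_off = n_pre0 / fs + (prepulse_ms + test_ms) / 1000)
  }

  noisy_sweep <- function(i_pA, epoch) {
    x <- i_pA + lp_noise(length(i_pA), cfg$noise_sd_pA, fs,
                         cfg$noise_corner_hz)
    new_sweep(x, fs, "current", channel = 1L, epoch = epoch)
  }

  active_current <- function(n, t_test_on, prepulse, test_kind) {
    t_ms <- ((seq_len(n) - 1L) / fs - t_test_on) * 1000
    out <- numeric(n)
    if (test_kind == "na" && mix[["na"]]) {
      avail <- if (prepulse <= -100) 1 else cfg$na_avail_m40
      out <- out + avail * patch_peak_for_site(cfg, site, "na") *
        biexp_kernel(t_ms, cfg$na_rise_ms, cfg$na_decay_ms)
    }
    if (test_kind == "k") {
      if (mix[["ka"]] && prepulse <= -100)
        out <- out + patch_peak_for_site(cfg, site, "ka") *
          biexp_kernel(t_ms, cfg$ka_rise_ms, cfg$ka_decay_ms)
      if (mix[["kdr"]]) {
        act <- ifelse(t_ms < 0, 0,
                      (1 - exp(-pmax(t_ms, 0) / cfg$kdr_rise_ms)) *
                        exp(-pmax(t_ms, 0) / cfg$kdr_inact_ms))
        # peak-normalize: maximum of (1-e^(-t/r))e^(-t/i) at t* = r log((r+i)/r)
        tstar <- cfg$kdr_rise_ms *
          log((cfg$kdr_rise_ms + cfg$kdr_inact_ms) / cfg$kdr_rise_ms)
        pkf <- (1 - exp(-tstar / cfg$kdr_rise_ms)) *
          exp(-tstar / cfg$kdr_inact_ms)
        out <- out + patch_peak_for_site(cfg, site, "kdr") * act / pkf
      }
    }
    # currents flow only during the test pulse
    out[t_ms < 0] <- 0
    out
  }

  family <- function(prepulse_mV, prepulse_ms, test_mV, test_ms, test_kind,
                     epoch) {
    bc <- build_cmd(prepulse_mV, prepulse_ms, test_mV, test_ms)
    full <- passive_response(bc$cmd, cfg, fs) +
      active_current(length(bc$cmd), bc$t_test_on, prepulse_mV, test_kind)
    sub_cmd <- cfg$holding_mV - (bc$cmd - cfg$holding_mV) / 4
    subs <- lapply(seq_len(cfg$n_subpulses), function(k)
      noisy_sweep(passive_response(sub_cmd, cfg, fs),
                  paste0(epoch, "_sub", k)))
    list(sweep = noisy_sweep(full, epoch), subs = subs,
         t_test_on = bc$t_test_on, t_test_off = bc$t_test_off)
  }

  na_fam <- family(cfg$prepulse_m120, cfg$na_prepulse_ms, cfg$na_test_mV,
                   cfg$na_test_ms, "na", "na_test")
  k120 <- family(cfg$prepulse_m120, cfg$k_prepulse_ms, cfg$k_test_mV,
                 cfg$k_test_ms, "k", "k_m120")
  k40 <- family(cfg$prepulse_m40, cfg$k_prepulse_ms, cfg$k_test_mV,
                cfg$k_test_ms, "k", "k_m40")

  truth <- list(
    na_peak_pA = if (mix[["na"]]) patch_peak_for_site(cfg, site, "na") else 0,
    ka_peak_pA = if (mix[["ka"]]) patch_peak_for_site(cfg, site, "ka") else 0,
    kdr_peak_pA = if (mix[["kdr"]])
      patch_peak_for_site(cfg, site, "kdr") else 0,
    ka_decay_ms = cfg$ka_decay_ms)

  structure(list(
    test_sweep = na_fam$sweep, test_subpulses = na_fam$subs,
    k_m120_sweep = k120$sweep, k_m120_subpulses = k120$subs,
    k_m40_sweep = k40$sweep, k_m40_subpulses = k40$subs,
    protocol = list(holding_mV = cfg$holding_mV,
                    na_test_on_s = na_fam$t_test_on,
                    na_test_off_s = na_fam$t_test_off,
                    k_test_on_s = k120$t_test_on,
                    k_test_off_s = k120$t_test_off),
    site = site, channel_mix = mix,
    pipette_res_MOhm = cfg$pipette_res_MOhm, truth = truth),
    class = "patch_sweep_set")
}

#' Configuration for synthetic LTP cohorts
#'
#' Per-cell EPSP amplitude time courses with induction spike counts drawn
#' from a Poisson law and LTP magnitudes linear in the count.  The defaults
#' (counts ~ Poisson(4.14), slope 18 %/spike, intercept 100%, LTP noise SD
#' 30%) give a population spike-count/LTP correlation of ~0.77: with
#' Var(k) = 4.14, r = s*sd(k) / sqrt(s^2 Var(k) + sigma^2) = 0.77.
#'
#' @param n_cells Number of cells (>= 2).
#' @param baseline_epsp_mV,baseline_sd_mV Per-cell baseline EPSP mean and
#'   between-cell SD (mV).
#' @param spike_count_mean Poisson mean of the induction spike count.
#' @param ltp_slope_pct_per_spike Added LTP (%) per induction spike.
#' @param ltp_intercept_pct LTP (%) at zero spikes.
#' @param ltp_noise_sd_pct Between-cell LTP noise SD (%).
#' @param meas_noise_sd_mV Per-measurement EPSP amplitude noise (mV).
#' @param test_hz Test-stimulation rate (Hz).
#' @param baseline_min,post_min Epoch lengths (min).
#' @param seed RNG seed.
#' @return An object of class `ltp_cohort_config`.
#' @export
ltp_cohort_config <- function(n_cells = 13L, baseline_epsp_mV = 7,
                              baseline_sd_mV = 1.5,
                              spike_count_mean = 4.14,
                              ltp_slope_pct_per_spike = 18,
                              ltp_intercept_pct = 100,
                              ltp_noise_sd_pct = 30,
                              meas_noise_sd_mV = 0.3, test_hz = 0.1,
                              baseline_min = 10, post_min = 30, seed = 1L) {
  if (n_cells < 2L) stop("n_cells must be at least 2", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "ltp_cohort_config"
  cfg
}

#' Generate a synthetic LTP cohort
#'
#' Each cell gets a baseline EPSP amplitude series (`baseline_min` minutes
#' at `test_hz`), an induction spike count `k ~ Poisson(spike_count_mean)`,
#' and a post-induction series whose level is
#' `baseline * (intercept + slope * k + noise) / 100`.  A configuration
#' whose draw produces a non-positive LTP percentage is rejected as a
#' config error, per the requirement that generated LTP magnitudes stay
#' positive.
#'
#' @param cfg An [ltp_cohort_config()].
#' @return A list of [ltp_experiment()] objects; each `truth` logs the true
#'   LTP percentage and spike count.
#' @export
make_ltp_cohort <- function(cfg = ltp_cohort_config()) {
  stopifnot(inherits(cfg, "ltp_cohort_config"))
  set.seed(cfg$seed)
  t_base <- seq(-cfg$baseline_min * 60, -1 / cfg$test_hz,
                by = 1 / cfg$test_hz)
  t_post <- seq(1 / cfg$test_hz, cfg$post_min * 60, by = 1 / cfg$test_hz)
  lapply(seq_len(cfg$n_cells), function(i) {
    base <- max(cfg$baseline_epsp_mV + stats::rnorm(1) * cfg$baseline_sd_mV,
                0.5)
    k <- stats::rpois(1, cfg$spike_count_mean)
    ltp_true <- cfg$ltp_intercept_pct + cfg$ltp_slope_pct_per_spike * k +
      stats::rnorm(1) * cfg$ltp_noise_sd_pct
    if (ltp_true <= 0)
      stop("config error: drawn LTP percentage is non-positive; reduce ",
           "ltp_noise_sd_pct or raise the intercept", call. = FALSE)
    amps <- c(base + stats::rnorm(length(t_base)) * cfg$meas_noise_sd_mV,
              base * ltp_true / 100 +
                stats::rnorm(length(t_post)) * cfg$meas_noise_sd_mV)
    ltp_experiment(
      epsp_series = data.frame(time_s = c(t_base, t_post), amp_mV = amps),
      induction_time_s = 0, spike_count = k, condition = "control",
      truth = list(ltp_pct_true = ltp_true, spike_count = k,
                   baseline_mV = base))
  })
}
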