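# shared fixtures, built in code

# flat voltage sweep at a given level
flat_sweep <- function(level = -81.3, n = 2000, fs = 20000, t0 = 0) {
  new_sweep(rep(level, n), fs, "voltage", t0 = t0)
}

# voltage sweep holding one Gaussian AP template; amplitude and width are
# chosen by the caller, baseline at v_rest
ap_sweep <- function(amp = 93.6, sd_ms = 0.3, center_s = 0.02, fs = 50000,
                     dur_s = 0.06, v_rest = -81.3) {
  t_ms <- (seq_len(round(dur_s * fs)) - 1L) / fs * 1000
  new_sweep(v_rest + amp * gauss_kernel(t_ms, center_s * 1000, sd_ms),
            fs, "voltage")
}

# config without baseline/post epochs and without noise, for exact checks
quiet_tbs <- function(...) {
  tbs_gen_config(noise_sd_mV = 0, baseline_min = 0, post_min = 0, ...)
}

# count detected dendritic spikes (weak + strong) over the induction
dspike_count <- function(session, cfg = detection_config()) {
  ev <- detect_session_events(session, epoch = "induction", cfg = cfg)
  sum(ev$event_class %in% c("weak_dspike", "strong_dspike"))
}

# independent moving-average + central-difference oracle, written directly
# from the definitions (no shared code with sweep_derivative)
brute_dvdt <- function(x, fs, smooth_window_ms) {
  dt_ms <- 1000 / fs
  w <- round(smooth_window_ms / dt_ms)
  n <- length(x)
  if (w >= 2L) {
    half <- (w - 1L) %/% 2L
    x <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half); hi <- min(n, i + (w - 1L - half))
      mean(x[lo:hi])
    }, 1.0)
  }
  d <- numeric(n)
  for (i in 2:(n - 1L)) d[i] <- (x[i + 1L] - x[i - 1L]) / (2 * dt_ms)
  d[1L] <- (x[2L] - x[1L]) / dt_ms
  d[n] <- (x[n] - x[n - 1L]) / dt_ms
  d
}
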