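#' Paired soma-dendrite recording
#'
#' @param soma,dend Voltage [new_sweep()] objects from the somatic and
#'   dendritic pipettes (same sampling rate).
#' @param distance_um Dendritic recording distance from the soma (um).
#' @param total_length_um Optional total dendritic path length (um), needed
#'   for normalized-distance analyses.
#' @param truth Optional generator ground-truth list.
#' @return An object of class `dual_recording`.
#' @export
dual_recording <- function(soma, dend, distance_um, total_length_um = NA_real_,
                           truth = list()) {
  assert_kind(soma, "voltage"); assert_kind(dend, "voltage")
  if (soma$sampling_rate != dend$sampling_rate)
    stop("soma and dendrite sweeps must share a sampling rate", call. = FALSE)
  if (!is.finite(distance_um) || distance_um < 0)
    stop("distance_um must be non-negative", call. = FALSE)
  structure(list(soma = soma, dend = dend, distance_um = distance_um,
                 total_length_um = total_length_um, truth = truth),
            class = "dual_recording")
}

window_index <- function(tt, window) {
  if (length(window) != 2L || !all(is.finite(window)) || window[2] <= window[1])
    stop("window must be a finite (t_start, t_end) pair", call. = FALSE)
  idx <- which(tt >= window[1] & tt <= window[2])
  if (!length(idx))
    stop("window [", window[1], ", ", window[2], "] s is outside the sweep",
         call. = FALSE)
  idx
}

#' Baseline-subtracted peak amplitude
#'
#' `max(sweep in window) - mean(sweep in baseline_window)`, invariant to
#' constant voltage offsets.
#'
#' @param sweep A voltage [new_sweep()].
#' @param window `(t_start, t_end)` event window in seconds.
#' @param baseline_window `(t_start, t_end)` baseline window preceding the
#'   event window.
#' @return Amplitude in mV.
#' @export
peak_amplitude <- function(sweep, window, baseline_window) {
  assert_kind(sweep, "voltage")
  tt <- sweep_times(sweep)
  if (baseline_window[1] >= window[1])
    stop("baseline window must precede the event window", call. = FALSE)
  iw <- window_index(tt, window)
  ib <- window_index(tt, baseline_window)
  max(sweep$samples[iw]) - mean(sweep$samples[ib])
}

# rising-phase half-maximum crossing time of the (first) AP in a sweep.
# baseline: mean of the pre-AP stretch ending `gap_ms` before the peak.
half_max_time <- function(sweep, gap_ms = 5) {
  x <- sweep$samples
  tt <- sweep_times(sweep)
  ipk <- which.max(x)
  base_idx <- which(tt < tt[ipk] - gap_ms / 1000)
  if (!length(base_idx)) return(NA_real_)
  base <- mean(x[base_idx])
  amp <- x[ipk] - base
  if (amp <= 0) return(NA_real_)
  level <- base + amp / 2
  below <- which(x[seq_len(ipk)] < level)
  if (!length(below)) return(NA_real_)
  i <- max(below)            # last sample below the level before the peak
  if (i == ipk) return(NA_real_)
  frac <- (level - x[i]) / (x[i + 1L] - x[i])
  tt[i] + frac * (tt[i + 1L] - tt[i])
}

#' Soma-to-dendrite AP latency at half-maximal rising amplitude
#'
#' For each channel, the rising-phase time where the voltage crosses
#' baseline + amplitude/2 is found with linear interpolation; the latency
#' is the dendritic minus the somatic crossing time (positive when the
#' dendrite lags, the physiological case for axonally initiated APs).  The
#' measure is invariant to amplitude rescaling of either sweep.
#'
#' @param pair A [dual_recording()]; each sweep must contain one AP.
#' @param cfg A [detection_config()] (reserved for threshold-based
#'   pre-checks; the crossing itself is amplitude based).
#' @return A list with `found`, `latency_ms`, `t_soma_s`, `t_dend_s`.
#' @export
half_max_latency <- function(pair, cfg = detection_config()) {
  stopifnot(inherits(pair, "dual_recording"))
  ts <- half_max_time(pair$soma)
  td <- half_max_time(pair$dend)
  if (is.na(ts) || is.na(td))
    return(list(found = FALSE, latency_ms = NA_real_,
                t_soma_s = ts, t_dend_s = td))
  list(found = TRUE, latency_ms = (td - ts) * 1000,
       t_soma_s = ts, t_dend_s = td)
}

#' Stimulus-locked EPSP amplitude series
#'
#' For every protocol stimulus falling inside a baseline/post sweep, the
#' EPSP amplitude is the baseline-subtracted peak in a 0-50 ms post-stimulus
#' window against a 5 ms pre-stimulus baseline.
#'
#' @param session A [recording_session()] with low-frequency test sweeps.
#' @param channel Channel to measure (default 1).
#' @param epoch Optional epoch filter (e.g. `c("baseline", "post")`); `NULL`
#'   measures every sweep epoch except `"induction"`.
#' @param peak_window_ms,baseline_ms Post-stimulus search window and
#'   pre-stimulus baseline length (ms).
#' @param smooth_ms Moving-average width applied before the peak search
#'   (ms).  A synaptic peak is tens of ms wide, so a 2 ms average leaves it
#'   untouched while removing the upward bias that taking a maximum over
#'   broadband noise would add to every amplitude.
#' @return Data frame with columns `time_s` (stimulus time), `amp_mV`,
#'   `epoch`; empty for a zero-stimulus session.
#' @export
epsp_amplitude_series <- function(session, channel = 1L, epoch = NULL,
                                  peak_window_ms = 50, baseline_ms = 5,
                                  smooth_ms = 2) {
  sw <- session_sweeps(session, channel)
  if (is.null(epoch)) {
    sw <- Filter(function(s) !identical(s$epoch, "induction"), sw)
  } else {
    sw <- Filter(function(s) s$epoch %in% epoch, sw)
  }
  pulses <- session$protocol$pulse_times
  out <- list()
  for (s in sw) {
    w <- round(smooth_ms / 1000 * s$sampling_rate)
    if (w >= 2L) s$samples <- moving_average(s$samples, w)
    tt_lo <- s$t0 + (baseline_ms + smooth_ms) / 1000
    tt_hi <- s$t0 + (length(s$samples) - 1L) / s$sampling_rate -
      peak_window_ms / 1000
    ps <- pulses[pulses >= tt_lo & pulses <= tt_hi]
    sm <- smooth_ms / 1000   # baseline ends one smoothing width before the
    for (p in ps) {          # pulse so the smeared onset cannot leak in
      amp <- peak_amplitude(s, c(p, p + peak_window_ms / 1000),
                            c(p - baseline_ms / 1000 - sm, p - sm))
      out[[length(out) + 1L]] <- data.frame(time_s = p, amp_mV = amp,
                                            epoch = s$epoch,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(time_s = numeric(0), amp_mV = numeric(0),
                      epoch = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Plateau-potential amplitude after a burst
#'
#' Baseline-subtracted maximum in the 200 ms following the end of the
#' high-frequency burst (the plateau is measured after the stimulus, where
#' it is uncontaminated by summed EPSPs).
#'
#' @param sweep A voltage [new_sweep()] extending at least `window_ms` past
#'   `burst_end`.
#' @param burst_end Time of the final stimulus of the burst plus one
#'   inter-stimulus interval (s).
#' @param baseline_window `(t_start, t_end)` pre-burst baseline (s).
#' @param window_ms Post-burst search length (default 200 ms).
#' @return Amplitude in mV.
#' @export
plateau_amplitude <- function(sweep, burst_end, baseline_window,
                              window_ms = 200) {
  assert_kind(sweep, "voltage")
  tt <- sweep_times(sweep)
  if (tt[length(tt)] < burst_end + window_ms / 1000)
    stop("sweep must extend at least ", window_ms, " ms past burst_end",
         call. = FALSE)
  peak_amplitude(sweep, c(burst_end, burst_end + window_ms / 1000),
                 baseline_window)
}

#' Isolate the regenerative spike component of a dendritic response
#'
#' Subtracts the scaled subthreshold response from the suprathreshold one:
#' `supra - scale * sub`, where `scale` is the ratio of the injected current
#' amplitudes.  The peak of the result is the spike-component amplitude.
#'
#' @param supra,sub Aligned voltage sweeps of equal length and rate.
#' @param scale Current-amplitude ratio (supra / sub).
#' @return A voltage sweep of the difference.
#' @export
isolate_spike_component <- function(supra, sub, scale = 1) {
  assert_kind(supra, "voltage"); assert_kind(sub, "voltage")
  if (length(supra$samples) != length(sub$samples) ||
      supra$sampling_rate != sub$sampling_rate)
    stop("sweeps must be aligned: equal length and sampling rate",
         call. = FALSE)
  out <- supra
  out$samples <- supra$samples - scale * sub$samples
  out
}

#' Input resistance by Ohm's law
#'
#' `R_in = 1000 * delta_v / delta_i` MOhm for a steady-state voltage
#' deflection `delta_v` (mV) caused by a current step `delta_i` (pA).
#'
#' @param delta_v Steady-state voltage difference (mV).
#' @param delta_i Current step (pA, non-zero).
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(delta_v, delta_i) {
  if (any(delta_i == 0))
    stop("current step must be non-zero", call. = FALSE)
  1000 * delta_v / delta_i
}
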