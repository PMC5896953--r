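#' Detection configuration
#'
#' All thresholds and window settings used by the event detector live here;
#' every analysis operation takes the config explicitly, there is no global
#' state.
#'
#' The dV/dt class ladder is half-open: `[0, weak_lo)` plain EPSP,
#' `[weak_lo, strong_lo)` weak dendritic spike, `[strong_lo, ap_thr)` strong
#' dendritic spike, `[ap_thr, Inf)` axosomatic AP, with `ap_thr` chosen by
#' recording site (40 mV/ms soma, 20 mV/ms dendrite).
#'
#' `smooth_window_ms` is the width of the moving average applied to the
#' voltage before differentiation.  A moving average of width W followed by
#' an adjacent central difference is an endpoint-slope estimator over W, so
#' broadband voltage noise of SD sigma maps to dV/dt noise of roughly
#' `sqrt(2) * sigma / W` mV/ms.  The 1.5 ms default keeps that below
#' 0.3 mV/ms at sigma = 0.3 mV — far under the 2.5 mV/ms weak threshold —
#' while attenuating the slope peak of a spikelet with a ~1.5 ms rise scale
#' by under 10%.
#'
#' @param weak_lo Lower dV/dt bound for weak dendritic spikes (mV/ms).
#' @param strong_lo Lower bound for strong dendritic spikes (mV/ms).
#' @param ap_soma,ap_dendrite Site-specific AP thresholds (mV/ms; 40 V/s and
#'   20 V/s).
#' @param smooth_window_ms Moving-average width before differentiation (ms).
#' @param refractory_ms Minimum separation between detected events (ms).
#'   The suprathreshold dV/dt excursion of a strong spikelet spans several
#'   ms at the detection bandwidth and can graze the threshold on its
#'   rising flank, so the separation must exceed the flank-to-peak
#'   interval; 5 ms does, while staying below the 10 ms spacing of
#'   stimuli within a burst.
#' @param blank_ms Stimulus-artifact blanking window after each pulse (ms).
#' @param last_window_ms Search-window length after the final stimulus of a
#'   burst/sweep (ms).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(weak_lo = 2.5, strong_lo = 10,
                             ap_soma = 40, ap_dendrite = 20,
                             smooth_window_ms = 1.5, refractory_ms = 5,
                             blank_ms = 0.5, last_window_ms = 50) {
  if (!(weak_lo < strong_lo && strong_lo < ap_dendrite && ap_dendrite <= ap_soma))
    stop("thresholds must satisfy weak_lo < strong_lo < ap_dendrite <= ap_soma",
         call. = FALSE)
  if (smooth_window_ms < 0 || refractory_ms < 0 || blank_ms < 0 ||
      last_window_ms <= 0)
    stop("window settings must be non-negative (last_window_ms positive)",
         call. = FALSE)
  structure(list(weak_lo = weak_lo, strong_lo = strong_lo, ap_soma = ap_soma,
                 ap_dendrite = ap_dendrite,
                 smooth_window_ms = smooth_window_ms,
                 refractory_ms = refractory_ms, blank_ms = blank_ms,
                 last_window_ms = last_window_ms),
            class = "detection_config")
}

ap_thr_for_site <- function(site, cfg) {
  if (site$kind == "soma") cfg$ap_soma else cfg$ap_dendrite
}

# centered moving average, length preserving (shrinking window at the edges)
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  # fill the w/2 edge samples with partial-window means
  half <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(x)
  for (i in which(is.na(y))) {
    lo <- max(1L, i - half)
    hi <- min(n, i + (w - 1L - half))
    y[i] <- (cs[hi] - if (lo > 1L) cs[lo - 1L] else 0) / (hi - lo + 1L)
  }
  y
}

#' Temporal derivative of a voltage sweep
#'
#' Applies a moving average of width `smooth_window_ms` and then a central
#' difference, scaled to mV/ms.  Output length equals input length
#' (one-sided differences at the edges).  A smoothing window shorter than
#' two samples falls back to no smoothing with a warning.
#'
#' @param sweep A voltage [new_sweep()].
#' @param cfg A [detection_config()].
#' @return A sweep-like object of class `gc_sweep` whose samples are dV/dt
#'   in mV/ms (`signal_kind` stays `"voltage"`; the derivative is a derived
#'   trace, not a recording).
#' @export
sweep_derivative <- function(sweep, cfg = detection_config()) {
  assert_kind(sweep, "voltage")
  dt_ms <- 1000 / sweep$sampling_rate
  w <- round(cfg$smooth_window_ms / dt_ms)
  x <- sweep$samples
  if (w >= 2L) {
    x <- moving_average(x, w)
  } else if (cfg$smooth_window_ms > 0) {
    warning("smoothing window shorter than 2 samples; skipping smoothing",
            call. = FALSE)
  }
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt_ms)
  d[1L] <- (x[2L] - x[1L]) / dt_ms
  d[n] <- (x[n] - x[n - 1L]) / dt_ms
  out <- sweep
  out$samples <- d
  out
}

#' Classify a dV/dt peak
#'
#' Pure, total, monotone function of the dV/dt peak given the config ladder.
#' Boundaries follow the half-open convention: exactly `weak_lo` is a weak
#' dendritic spike, exactly `strong_lo` a strong one, exactly the site AP
#' threshold an axosomatic AP.
#'
#' @param dvdt_peak Numeric vector of dV/dt peaks (mV/ms, non-negative).
#' @param site A [recording_site()] (selects the AP threshold).
#' @param cfg A [detection_config()].
#' @return Character vector with levels `epsp_only`, `weak_dspike`,
#'   `strong_dspike`, `axosomatic_ap`.
#' @export
classify_dvdt <- function(dvdt_peak, site = recording_site("soma"),
                          cfg = detection_config()) {
  if (any(!is.finite(dvdt_peak)) || any(dvdt_peak < 0))
    stop("dvdt_peak must be finite and non-negative", call. = FALSE)
  thr <- ap_thr_for_site(site, cfg)
  cut_labels <- c("epsp_only", "weak_dspike", "strong_dspike", "axosomatic_ap")
  idx <- findInterval(dvdt_peak, c(cfg$weak_lo, cfg$strong_lo, thr)) + 1L
  cut_labels[idx]
}

# one candidate index per contiguous run of x >= thr (the run maximum):
# local maxima that are not separated by a dip below threshold belong to
# the same suprathreshold excursion and would double-count a single event
run_maxima <- function(x, thr) {
  above <- x >= thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  vapply(keep, function(j) {
    idx <- starts[j]:ends[j]
    idx[which.max(x[idx])]
  }, 1L)
}

#' Detect and classify fast events within stimulus windows
#'
#' Within each stimulus search window (onset + blanking to the next
#' stimulus; the last stimulus of a sweep extends `last_window_ms`), each
#' contiguous excursion of the smoothed dV/dt at or above `weak_lo`
#' contributes one candidate at its maximum (local maxima not separated by
#' a dip below threshold are one event); candidates separated by at least
#' `refractory_ms` become events.  Events at or above the site AP
#' threshold are retained with class `axosomatic_ap` but are never counted
#' as dendritic spikes by downstream operations.
#'
#' @param sweep A voltage [new_sweep()].
#' @param protocol A [stim_protocol()]; only pulses inside the sweep are
#'   searched.  An empty protocol yields an empty event table; a protocol
#'   with no pulse inside the sweep is a validation error.
#' @param site A [recording_site()].
#' @param cfg A [detection_config()].
#' @return A data frame with columns `sweep_id`, `time_s`, `dvdt_peak`
#'   (mV/ms), `v_at_peak` (mV), `event_class`, `stimulus_index` (1-based
#'   index into `protocol$pulse_times`), sorted by time.
#' @export
detect_events <- function(sweep, protocol, site = recording_site("soma"),
                          cfg = detection_config()) {
  assert_kind(sweep, "voltage")
  empty <- data.frame(sweep_id = character(0), time_s = numeric(0),
                      dvdt_peak = numeric(0), v_at_peak = numeric(0),
                      event_class = character(0), stimulus_index = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(protocol$pulse_times)) return(empty)

  tt <- sweep_times(sweep)
  t_lo <- tt[1L]; t_hi <- tt[length(tt)]
  inside <- protocol$pulse_times >= t_lo & protocol$pulse_times <= t_hi
  if (!any(inside))
    stop("no protocol stimulus falls inside the sweep", call. = FALSE)
  pulses <- protocol$pulse_times[inside]
  pulse_idx <- which(inside)

  d <- sweep_derivative(sweep, cfg)$samples
  cand <- run_maxima(d, cfg$weak_lo)
  if (!length(cand)) return(empty)

  # assign candidates to stimulus windows
  starts <- pulses + cfg$blank_ms / 1000
  ends <- c(pulses[-1L], pulses[length(pulses)] + cfg$last_window_ms / 1000)
  ct <- tt[cand]
  win <- findInterval(ct, starts)
  keep <- win >= 1L & ct < ends[pmax(win, 1L)]
  cand <- cand[keep]; win <- win[keep]
  if (!length(cand)) return(empty)

  # refractory: greedy acceptance by descending dV/dt
  ord <- order(d[cand], decreasing = TRUE)
  acc_t <- numeric(0); acc <- logical(length(cand))
  ref_s <- cfg$refractory_ms / 1000
  for (j in ord) {
    tj <- tt[cand[j]]
    if (!length(acc_t) || min(abs(acc_t - tj)) >= ref_s) {
      acc[j] <- TRUE
      acc_t <- c(acc_t, tj)
    }
  }
  cand <- cand[acc]; win <- win[acc]

  o <- order(tt[cand])
  cand <- cand[o]; win <- win[o]
  data.frame(
    sweep_id = rep(if (is.na(sweep$id)) "" else sweep$id, length(cand)),
    time_s = tt[cand],
    dvdt_peak = d[cand],
    v_at_peak = sweep$samples[cand],
    event_class = classify_dvdt(d[cand], site, cfg),
    stimulus_index = pulse_idx[win],
    stringsAsFactors = FALSE)
}

#' Detect events across all induction sweeps of a session
#'
#' Convenience wrapper running [detect_events()] over every sweep of a
#' channel (optionally restricted to an epoch such as `"induction"`) and
#' binding the event tables.
#'
#' @param session A [recording_session()].
#' @param channel Channel to analyze (default 1).
#' @param epoch Optional epoch label filter.
#' @param cfg A [detection_config()].
#' @return The combined event data frame (see [detect_events()]).
#' @export
detect_session_events <- function(session, channel = 1L, epoch = NULL,
                                  cfg = detection_config()) {
  site <- session$sites[[match(channel, sort(unique(
    vapply(session$sweeps, function(s) s$channel, 1L))))]]
  sw <- session_sweeps(session, channel, epoch)
  out <- lapply(sw, detect_events, protocol = session$protocol, site = site,
                cfg = cfg)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' AP threshold crossing time and voltage
#'
#' First time the smoothed dV/dt crosses the site's AP threshold (40 V/s
#' soma, 20 V/s dendrite), located with linear interpolation between
#' samples; the voltage at that time is the spike threshold.
#'
#' @param sweep A voltage [new_sweep()].
#' @param site A [recording_site()].
#' @param cfg A [detection_config()].
#' @return A list with `found` (logical), `time_s`, and `threshold_mV`
#'   (both `NA` when no crossing exists — a not-found result, not an error).
#' @export
ap_threshold <- function(sweep, site = recording_site("soma"),
                         cfg = detection_config()) {
  assert_kind(sweep, "voltage")
  thr <- ap_thr_for_site(site, cfg)
  d <- sweep_derivative(sweep, cfg)$samples
  above <- which(d >= thr)
  if (!length(above))
    return(list(found = FALSE, time_s = NA_real_, threshold_mV = NA_real_))
  i <- above[1L]
  tt <- sweep_times(sweep)
  if (i == 1L) {
    t_cross <- tt[1L]
  } else {
    frac <- (thr - d[i - 1L]) / (d[i] - d[i - 1L])
    t_cross <- tt[i - 1L] + frac * (tt[i] - tt[i - 1L])
  }
  v_cross <- stats::approx(tt, sweep$samples, xout = t_cross)$y
  list(found = TRUE, time_s = t_cross, threshold_mV = v_cross)
}
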