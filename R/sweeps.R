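#' Construct a single recording sweep
#'
#' A sweep is one uniformly sampled trace of membrane voltage (mV) or
#' current (pA).  Sample `i` (1-based) lies at time `t0 + (i - 1) / sampling_rate`
#' seconds; all stimulus times in a session share this clock.
#'
#' @param samples Numeric vector of sample values (mV for voltage sweeps,
#'   pA for current sweeps).  At least two samples, no missing values.
#' @param sampling_rate Sampling rate in Hz.  Recordings in this preparation
#'   are digitized at 20-50 kHz; rates outside that range are accepted only
#'   with `strict = FALSE`.
#' @param signal_kind Either `"voltage"` or `"current"`.
#' @param t0 Start time of the first sample, in seconds.
#' @param channel Integer channel index (1 = first pipette, 2 = second).
#' @param epoch Optional label tying the sweep to a protocol epoch
#'   (e.g. `"baseline"`, `"induction"`, `"post"`).
#' @param id Optional sweep identifier; generated from channel/position when
#'   written to disk if missing.
#' @param strict Enforce the 20-50 kHz sampling-rate band (default `TRUE`).
#'
#' @return An object of class `gc_sweep`.
#' @export
new_sweep <- function(samples, sampling_rate,
                      signal_kind = c("voltage", "current"),
                      t0 = 0, channel = 1L, epoch = NA_character_,
                      id = NA_character_, strict = TRUE) {
  signal_kind <- match.arg(signal_kind)
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("sweep must contain at least 2 samples", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("sweep samples must be finite and non-missing", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number (Hz)", call. = FALSE)
  if (strict && (sampling_rate < 20000 || sampling_rate > 50000))
    stop("sampling_rate ", sampling_rate,
         " Hz outside the 20-50 kHz acquisition band; ",
         "use strict = FALSE to override", call. = FALSE)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         signal_kind = signal_kind, t0 = as.numeric(t0),
         channel = as.integer(channel), epoch = epoch, id = id),
    class = "gc_sweep")
}

#' Sample times of a sweep
#'
#' @param sweep A [new_sweep()] object.
#' @return Numeric vector of sample times in seconds.
#' @export
sweep_times <- function(sweep) {
  stopifnot(inherits(sweep, "gc_sweep"))
  sweep$t0 + (seq_along(sweep$samples) - 1L) / sweep$sampling_rate
}

#' @export
print.gc_sweep <- function(x, ...) {
  cat(sprintf("<gc_sweep> %s, %d samples @ %g kHz, t0 = %g s",
              x$signal_kind, length(x$samples), x$sampling_rate / 1000, x$t0))
  if (!is.na(x$epoch)) cat(", epoch:", x$epoch)
  cat("\n")
  invisible(x)
}

# fail fast when an operation receives the wrong signal kind
assert_kind <- function(sweep, kind) {
  if (!inherits(sweep, "gc_sweep"))
    stop("expected a gc_sweep object", call. = FALSE)
  if (!identical(sweep$signal_kind, kind))
    stop("expected a ", kind, " sweep, got ", sweep$signal_kind, call. = FALSE)
  invisible(sweep)
}

#' Construct a stimulus protocol
#'
#' @param pulse_times Strictly increasing vector of stimulus onset times (s).
#' @param label One of `"TBS"`, `"pairing_pre_post"`, `"pairing_post_pre"`,
#'   `"single_burst"`, `"current_step"`, `"vc_pulse"`, `"test"`.
#' @param params Named list of protocol settings (burst counts, frequencies,
#'   repeat structure).
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(pulse_times,
                          label = c("TBS", "pairing_pre_post",
                                    "pairing_post_pre", "single_burst",
                                    "current_step", "vc_pulse", "test"),
                          params = list()) {
  label <- match.arg(label)
  pulse_times <- as.numeric(pulse_times)
  if (length(pulse_times) && any(diff(pulse_times) <= 0))
    stop("pulse_times must be strictly increasing", call. = FALSE)
  structure(list(pulse_times = pulse_times, label = label, params = params),
            class = "stim_protocol")
}

#' Theta-burst stimulation protocol
#'
#' The standard induction paradigm: bursts of `n_stim` stimuli at
#' `intra_burst_hz`, `n_bursts` bursts at `burst_hz`, the whole episode
#' repeated `n_episodes` times every `episode_interval_s` seconds.  The
#' defaults expand to 4 x 10 x 10 = 400 pulses.
#'
#' @param t_start Time of the first stimulus (s).
#' @param n_episodes,n_bursts,n_stim Repeat structure (defaults 4, 10, 10).
#' @param burst_hz Burst rate within an episode (default 5 Hz).
#' @param intra_burst_hz Stimulus rate within a burst (default 100 Hz).
#' @param episode_interval_s Episode period (default 10 s).
#' @return A [stim_protocol()] with label `"TBS"` (or `"single_burst"` when
#'   it collapses to one burst).
#' @export
tbs_protocol <- function(t_start = 0, n_episodes = 4L, n_bursts = 10L,
                         n_stim = 10L, burst_hz = 5, intra_burst_hz = 100,
                         episode_interval_s = 10) {
  eps <- (seq_len(n_episodes) - 1L) * episode_interval_s
  bursts <- (seq_len(n_bursts) - 1L) / burst_hz
  stims <- (seq_len(n_stim) - 1L) / intra_burst_hz
  times <- t_start + rep(eps, each = n_bursts * n_stim) +
    rep(rep(bursts, each = n_stim), times = n_episodes) +
    rep(stims, times = n_episodes * n_bursts)
  lab <- if (n_episodes == 1L && n_bursts == 1L) "single_burst" else "TBS"
  stim_protocol(times, lab,
                params = list(n_episodes = n_episodes, n_bursts = n_bursts,
                              n_stim = n_stim, burst_hz = burst_hz,
                              intra_burst_hz = intra_burst_hz,
                              episode_interval_s = episode_interval_s))
}

#' Low-frequency EPSP-AP pairing protocol
#'
#' 300 repetitions at 1 Hz of a presynaptic stimulus paired with a
#' postsynaptic AP command at `interval_ms` (positive: AP follows the EPSP).
#'
#' @param t_start Time of the first presynaptic stimulus (s).
#' @param interval_ms EPSP-to-AP interval in ms; +10 gives the pre-post
#'   sequence, -10 the post-pre sequence.
#' @param n_reps Number of pairings (default 300).
#' @param rep_hz Pairing rate (default 1 Hz).
#' @return A [stim_protocol()]; AP command times are stored in `params`.
#' @export
pairing_protocol <- function(t_start = 0, interval_ms = 10, n_reps = 300L,
                             rep_hz = 1) {
  pre <- t_start + (seq_len(n_reps) - 1L) / rep_hz
  lab <- if (interval_ms >= 0) "pairing_pre_post" else "pairing_post_pre"
  stim_protocol(pre, lab,
                params = list(interval_ms = interval_ms, n_reps = n_reps,
                              rep_hz = rep_hz, ap_times = pre + interval_ms / 1000))
}

#' Recording-site metadata
#'
#' @param kind `"soma"` or `"dendrite"`.
#' @param distance_um Distance from the soma along the dendritic path (um);
#'   0 for the soma.  Dendritic sites beyond 300 um exceed the dendritic
#'   tree of this cell type and are rejected unless `strict = FALSE`.
#' @param strict Enforce the 300 um dendritic bound.
#' @return An object of class `recording_site`.
#' @export
recording_site <- function(kind = c("soma", "dendrite"), distance_um = 0,
                           strict = TRUE) {
  kind <- match.arg(kind)
  if (!is.finite(distance_um) || distance_um < 0)
    stop("distance_um must be a non-negative number", call. = FALSE)
  if (kind == "soma" && distance_um != 0)
    stop("somatic site must have distance_um = 0", call. = FALSE)
  if (strict && kind == "dendrite" && distance_um > 300)
    stop("dendritic distance ", distance_um, " um exceeds 300 um; ",
         "use strict = FALSE to override", call. = FALSE)
  structure(list(kind = kind, distance_um = as.numeric(distance_um)),
            class = "recording_site")
}

#' Bundle sweeps, a protocol and site metadata into a session
#'
#' @param sweeps List of [new_sweep()] objects.  All sweeps on a channel
#'   must share one sampling rate; at most two channels.
#' @param protocol A [stim_protocol()].
#' @param sites List of [recording_site()], one per channel.
#' @param metadata Free-form named list (cell id, condition label, and the
#'   generator's ground-truth log for synthetic sessions).
#' @return An object of class `gc_session`.
#' @export
recording_session <- function(sweeps, protocol, sites, metadata = list()) {
  if (!length(sweeps) || !all(vapply(sweeps, inherits, TRUE, "gc_sweep")))
    stop("sweeps must be a non-empty list of gc_sweep objects", call. = FALSE)
  if (!inherits(protocol, "stim_protocol"))
    stop("protocol must be a stim_protocol", call. = FALSE)
  if (inherits(sites, "recording_site")) sites <- list(sites)
  if (!all(vapply(sites, inherits, TRUE, "recording_site")))
    stop("sites must be recording_site objects", call. = FALSE)
  chans <- vapply(sweeps, function(s) s$channel, 1L)
  uch <- sort(unique(chans))
  if (length(uch) > 2L)
    stop("at most two channels are supported", call. = FALSE)
  if (length(sites) != length(uch))
    stop("need one recording_site per channel (", length(uch),
         " channel(s), ", length(sites), " site(s))", call. = FALSE)
  for (ch in uch) {
    fs <- vapply(sweeps[chans == ch], function(s) s$sampling_rate, 1.0)
    if (length(unique(fs)) != 1L)
      stop("all sweeps of channel ", ch, " must share one sampling rate",
           call. = FALSE)
  }
  structure(list(sweeps = sweeps, protocol = protocol, sites = sites,
                 metadata = metadata),
            class = "gc_session")
}

#' @export
print.gc_session <- function(x, ...) {
  chans <- vapply(x$sweeps, function(s) s$channel, 1L)
  cat(sprintf("<gc_session> %d sweep(s) on %d channel(s), protocol %s (%d pulses)\n",
              length(x$sweeps), length(unique(chans)),
              x$protocol$label, length(x$protocol$pulse_times)))
  invisible(x)
}

# sweeps of one channel, optionally restricted to an epoch label
session_sweeps <- function(session, channel = 1L, epoch = NULL) {
  keep <- vapply(session$sweeps, function(s) {
    s$channel == channel && (is.null(epoch) || identical(s$epoch, epoch))
  }, TRUE)
  session$sweeps[keep]
}
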