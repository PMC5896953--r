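#' Bundle the pieces of one LTP experiment
#'
#' @param epsp_series Data frame `(time_s, amp_mV)` of stimulus-locked EPSP
#'   amplitudes (from [epsp_amplitude_series()] or the cohort generator).
#' @param induction_time_s Time of the induction protocol (s) on the series
#'   clock.
#' @param induction_events Optional event table from the induction episodes
#'   (see [detect_events()]); used by [count_induction_spikes()].
#' @param condition Condition label (e.g. `"control"`, `"QX-314"`,
#'   `"DL-AP5"`, `"TTX"`).
#' @param spike_count Optional externally supplied induction spike count
#'   (used when no event table is available).
#' @param truth Optional generator ground-truth list.
#' @return An object of class `ltp_experiment`.
#' @export
ltp_experiment <- function(epsp_series, induction_time_s,
                           induction_events = NULL, condition = "control",
                           spike_count = NULL, truth = list()) {
  if (!is.data.frame(epsp_series) ||
      !all(c("time_s", "amp_mV") %in% names(epsp_series)))
    stop("epsp_series must be a data frame with time_s and amp_mV",
         call. = FALSE)
  structure(list(epsp_series = epsp_series,
                 induction_time_s = induction_time_s,
                 induction_events = induction_events,
                 condition = condition, spike_count = spike_count,
                 truth = truth),
            class = "ltp_experiment")
}

#' Build an LTP experiment from a synthetic or recorded session
#'
#' Measures the EPSP amplitude series over the baseline/post sweeps and
#' detects induction events on the induction sweeps.
#'
#' @param session A [recording_session()] with epoch-labelled sweeps and an
#'   `induction_time_s` metadata entry (default 0).
#' @param cfg A [detection_config()].
#' @return An [ltp_experiment()].
#' @export
session_ltp_experiment <- function(session, cfg = detection_config()) {
  series <- epsp_amplitude_series(session, epoch = c("baseline", "post"))
  events <- detect_session_events(session, epoch = "induction", cfg = cfg)
  ltp_experiment(series[, c("time_s", "amp_mV")],
                 induction_time_s =
                   session$metadata$induction_time_s %||% 0,
                 induction_events = events,
                 condition = session$metadata$condition %||% "control",
                 truth = session$metadata$truth %||% list())
}

#' LTP magnitude
#'
#' Post-induction EPSP amplitude, expressed as a percentage of baseline:
#' `100 * mean(amp in [t + 25 min, t + 30 min]) / mean(amp in [t - 5 min, t))`.
#' The measure is scale-equivariant: rescaling all amplitudes leaves the
#' percentage unchanged.
#'
#' @param exp An [ltp_experiment()].
#' @return LTP magnitude in percent.
#' @export
ltp_magnitude <- function(exp) {
  stopifnot(inherits(exp, "ltp_experiment"))
  t0 <- exp$induction_time_s
  s <- exp$epsp_series
  base <- s$amp_mV[s$time_s >= t0 - 300 & s$time_s < t0]
  post <- s$amp_mV[s$time_s >= t0 + 1500 & s$time_s <= t0 + 1800]
  if (!length(base))
    stop("no amplitudes in the 5 min baseline window", call. = FALSE)
  if (!length(post))
    stop("no amplitudes in the 25-30 min post-induction window",
         call. = FALSE)
  if (mean(base) == 0)
    stop("zero baseline mean", call. = FALSE)
  100 * mean(post) / mean(base)
}

#' Count dendritic spikes during induction
#'
#' Counts induction events classed `weak_dspike` or `strong_dspike`;
#' `epsp_only` and `axosomatic_ap` events are excluded.  Falls back to the
#' experiment's stored `spike_count` when no event table is attached.
#'
#' @param exp An [ltp_experiment()].
#' @return A non-negative integer count.
#' @export
count_induction_spikes <- function(exp) {
  stopifnot(inherits(exp, "ltp_experiment"))
  ev <- exp$induction_events
  if (is.null(ev)) {
    if (is.null(exp$spike_count))
      stop("experiment has neither induction events nor a spike count",
           call. = FALSE)
    return(as.integer(exp$spike_count))
  }
  sum(ev$event_class %in% c("weak_dspike", "strong_dspike"))
}

#' Association between induction spike count and LTP magnitude
#'
#' Pearson correlation (default; Spearman available) between the per-cell
#' induction dendritic-spike count and the LTP percentage, with a two-sided
#' p-value from the t distribution.  Zero variance in either variable is a
#' degenerate result, not an error.
#'
#' @param cohort List of [ltp_experiment()] objects (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `p`, `n`, `degenerate`, plus the per-cell
#'   `spike_count` and `ltp_pct` vectors.
#' @export
spike_ltp_association <- function(cohort, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(cohort) < 3L)
    stop("need at least 3 experiments", call. = FALSE)
  k <- vapply(cohort, count_induction_spikes, 1L)
  ltp <- vapply(cohort, ltp_magnitude, 1.0)
  if (stats::sd(k) == 0 || stats::sd(ltp) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(k),
                degenerate = TRUE, spike_count = k, ltp_pct = ltp))
  ct <- stats::cor.test(k, ltp, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(k),
       degenerate = FALSE, spike_count = k, ltp_pct = ltp)
}

#' Nonparametric comparison of two LTP condition groups
#'
#' Wilcoxon signed-rank test for paired data, Wilcoxon rank-sum
#' (Mann-Whitney) for unpaired, both two-sided, plus group means +/- SEM.
#'
#' @param a,b Numeric vectors of LTP percentages (>= 3 each; equal length
#'   when paired).
#' @param paired Paired comparison?
#' @return List with `statistic`, `p`, `paired`, and per-group `mean`/`sem`.
#' @export
compare_conditions <- function(a, b, paired = FALSE) {
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 values per group", call. = FALSE)
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal group sizes", call. = FALSE)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  if (paired && all(a == b)) {
    # all differences zero: the signed-rank statistic sits at its null
    # center and there is no evidence against the null
    return(list(statistic = 0, p = 1, paired = TRUE,
                mean_a = mean(a), sem_a = sem(a), mean_b = mean(b),
                sem_b = sem(b),
                method = "Wilcoxon signed rank test (all differences zero)"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            exact = NULL))
  list(statistic = unname(wt$statistic), p = wt$p.value, paired = paired,
       mean_a = mean(a), sem_a = sem(a), mean_b = mean(b), sem_b = sem(b),
       method = wt$method)
}
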