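#' Leak and capacitive subtraction by the P over -4 procedure
#'
#' Subpulse sweeps are recorded with the command waveform scaled by -1/4
#' from the holding level, so their averaged response times -4 estimates
#' the linear (leak + capacitive) component of the test response with
#' inverted sign:
#' `corrected = test + 4 * mean(subpulses)`.  For a purely passive patch
#' the corrected trace is zero-mean noise; doubling the leak conductance
#' leaves it unchanged.
#'
#' @param test A current [new_sweep()] recorded at full pulse amplitude.
#' @param subpulses List of 1-4 current sweeps at -1/4 amplitude (the
#'   correction scale adapts to the sweeps supplied; they are averaged
#'   first).
#' @return A current sweep of the corrected trace.
#' @export
p_over_minus4 <- function(test, subpulses) {
  assert_kind(test, "current")
  if (inherits(subpulses, "gc_sweep")) subpulses <- list(subpulses)
  if (length(subpulses) < 1L || length(subpulses) > 4L)
    stop("need between 1 and 4 subpulse sweeps", call. = FALSE)
  for (s in subpulses) {
    assert_kind(s, "current")
    if (length(s$samples) != length(test$samples) ||
        s$sampling_rate != test$sampling_rate)
      stop("subpulse sweeps must be aligned with the test sweep",
           call. = FALSE)
  }
  sub_mean <- Reduce(`+`, lapply(subpulses, `[[`, "samples")) /
    length(subpulses)
  out <- test
  out$samples <- test$samples + 4 * sub_mean
  out$epoch <- "p4_corrected"
  out
}

#' Isolate the transient A-type K+ current
#'
#' `sweep_m120 - sweep_m40`: the -40 mV prepulse fully inactivates the
#' A-current while leaving non-inactivating components unchanged, so the
#' difference of the two leak-corrected responses is the A-current
#' (positive transient).
#'
#' @param sweep_m120,sweep_m40 Aligned leak-corrected current sweeps
#'   recorded with -120 and -40 mV prepulses.
#' @return A current sweep of the difference.
#' @export
isolate_a_current <- function(sweep_m120, sweep_m40) {
  assert_kind(sweep_m120, "current"); assert_kind(sweep_m40, "current")
  if (length(sweep_m120$samples) != length(sweep_m40$samples) ||
      sweep_m120$sampling_rate != sweep_m40$sampling_rate)
    stop("prepulse sweeps must be aligned", call. = FALSE)
  out <- sweep_m120
  out$samples <- sweep_m120$samples - sweep_m40$samples
  out$epoch <- "a_current"
  out
}

peak_window_idx <- function(sweep, t_on, t_off, blank_ms = 1) {
  tt <- sweep_times(sweep)
  idx <- which(tt >= t_on + blank_ms / 1000 & tt < t_off)
  if (!length(idx))
    stop("empty peak-search window", call. = FALSE)
  idx
}

#' Measure one channel-current component of a patch
#'
#' Component conventions: `na` is the minimum of the P/-4-corrected 0 mV
#' test sweep (inward, negative); `ka` the maximum of the
#' [isolate_a_current()] trace of the corrected K-protocol variants; `kdr`
#' the maximum of the corrected -40 mV-prepulse sweep.  The first 1 ms
#' after each clamp step is blanked (capacitive residue).
#'
#' @param set A [make_patch_sweep_set()] (or equivalent) object.
#' @param component `"na"`, `"ka"` or `"kdr"`.
#' @param blank_ms Post-step blanking (ms).
#' @return A one-row data frame (class includes `channel_measurement`):
#'   `site_kind`, `distance_um`, `component`, `peak_pA`,
#'   `n_sweeps_averaged`.
#' @export
measure_component <- function(set, component = c("na", "ka", "kdr"),
                              blank_ms = 1) {
  component <- match.arg(component)
  stopifnot(inherits(set, "patch_sweep_set"))
  need <- switch(component,
                 na = c("test_sweep", "test_subpulses"),
                 ka = c("k_m120_sweep", "k_m120_subpulses", "k_m40_sweep",
                        "k_m40_subpulses"),
                 kdr = c("k_m40_sweep", "k_m40_subpulses"))
  for (f in need)
    if (is.null(set[[f]]))
      stop("sweep set lacks the '", f, "' sweeps required for the ",
           component, " measurement", call. = FALSE)
  pk <- switch(component,
    na = {
      corr <- p_over_minus4(set$test_sweep, set$test_subpulses)
      idx <- peak_window_idx(corr, set$protocol$na_test_on_s,
                             set$protocol$na_test_off_s, blank_ms)
      min(corr$samples[idx])
    },
    ka = {
      iso <- isolate_a_current(
        p_over_minus4(set$k_m120_sweep, set$k_m120_subpulses),
        p_over_minus4(set$k_m40_sweep, set$k_m40_subpulses))
      idx <- peak_window_idx(iso, set$protocol$k_test_on_s,
                             set$protocol$k_test_off_s, blank_ms)
      max(iso$samples[idx])
    },
    kdr = {
      corr <- p_over_minus4(set$k_m40_sweep, set$k_m40_subpulses)
      idx <- peak_window_idx(corr, set$protocol$k_test_on_s,
                             set$protocol$k_test_off_s, blank_ms)
      max(corr$samples[idx])
    })
  out <- data.frame(site_kind = set$site$kind,
                    distance_um = set$site$distance_um,
                    component = component, peak_pA = pk,
                    n_sweeps_averaged = 1L + length(switch(component,
                      na = set$test_subpulses, set$k_m40_subpulses)),
                    stringsAsFactors = FALSE)
  class(out) <- c("channel_measurement", class(out))
  out
}

# Dunn's multiple-comparison z tests after a Kruskal-Wallis test, with
# rank-tie correction and Bonferroni adjustment (the 'Dunn's multiple
# comparisons' convention of common analysis software).
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  n <- length(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  combos <- utils::combn(levels(groups), 2L)
  m <- ncol(combos)
  res <- data.frame(comparison = character(m), z = numeric(m),
                    p_unadj = numeric(m), p_adj = numeric(m),
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    a <- combos[1L, j]; b <- combos[2L, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- if (se > 0) (mean_r[[a]] - mean_r[[b]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    res$comparison[j] <- paste(a, "vs", b)
    res$z[j] <- z
    res$p_unadj[j] <- p
    res$p_adj[j] <- min(1, p * m)
  }
  res
}

#' Group channel measurements by location and test for differences
#'
#' Groups measurements into soma, proximal dendrite (< 100 um) and distal
#' dendrite (>= 100 um; a measurement at exactly 100 um is distal), reports
#' per-group mean +/- SEM, and tests for a location effect with the
#' Kruskal-Wallis rank test followed by Dunn's multiple comparisons.
#'
#' @param measurements Data frame with columns `site_kind`, `distance_um`,
#'   `peak_pA` (rows from [measure_component()] may be `rbind`ed directly).
#' @return A list of class `patch_group_test`: `groups` (group, n, mean,
#'   sem), `kruskal` (statistic, df, p_value), `dunn` (pairwise table; z,
#'   unadjusted and Bonferroni-adjusted p).
#' @export
group_and_test <- function(measurements) {
  m <- as.data.frame(measurements)
  if (!all(c("site_kind", "distance_um", "peak_pA") %in% names(m)))
    stop("measurements need site_kind, distance_um and peak_pA columns",
         call. = FALSE)
  grp <- ifelse(m$site_kind == "soma", "soma",
                ifelse(m$distance_um < 100, "proximal", "distal"))
  grp <- factor(grp, levels = c("soma", "proximal", "distal"))
  grp <- droplevels(grp)
  if (nlevels(grp) < 2L)
    stop("need at least 2 non-empty location groups", call. = FALSE)
  groups <- data.frame(
    group = levels(grp),
    n = as.integer(table(grp)),
    mean_pA = as.numeric(tapply(m$peak_pA, grp, mean)),
    sem_pA = as.numeric(tapply(m$peak_pA, grp,
                               function(v) stats::sd(v) / sqrt(length(v)))),
    stringsAsFactors = FALSE)
  if (stats::sd(m$peak_pA) == 0) {
    kr <- list(statistic = 0, df = nlevels(grp) - 1L, p_value = 1)
    dn <- dunn_test(m$peak_pA, grp)   # all-z zero path
  } else {
    kt <- stats::kruskal.test(m$peak_pA, grp)
    kr <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
               p_value = kt$p.value)
    dn <- dunn_test(m$peak_pA, grp)
  }
  structure(list(groups = groups, kruskal = kr, dunn = dn),
            class = "patch_group_test")
}

#' @export
print.patch_group_test <- function(x, ...) {
  cat("<patch_group_test>\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("Kruskal-Wallis chi-squared = %.3g, df = %d, p = %.3g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p_value))
  print(x$dunn, row.names = FALSE)
  invisible(x)
}
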