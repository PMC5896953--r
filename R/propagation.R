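#' Measure propagation points from paired recordings
#'
#' Turns a list of [dual_recording()] objects into the scatter table used
#' by the attenuation and velocity fits: per pair, baseline-subtracted AP
#' peak amplitudes at soma and dendrite and the soma-to-dendrite half-max
#' latency.
#'
#' @param pairs List of [dual_recording()] objects.
#' @param peak_window_s Optional `(t_start, t_end)` AP search window;
#'   defaults to the whole sweep after the first 2 ms of baseline.
#' @return Data frame with columns `distance_um`, `amp_soma_mV`,
#'   `amp_dend_mV`, `latency_ms`, `total_length_um`.
#' @export
propagation_points <- function(pairs, peak_window_s = NULL) {
  rows <- lapply(pairs, function(pr) {
    stopifnot(inherits(pr, "dual_recording"))
    amp1 <- function(sw) {
      tt <- sweep_times(sw)
      w <- if (is.null(peak_window_s))
        c(tt[1] + 0.002, tt[length(tt)]) else peak_window_s
      peak_amplitude(sw, w, c(tt[1], tt[1] + 0.002))
    }
    lat <- half_max_latency(pr)
    data.frame(distance_um = pr$distance_um,
               amp_soma_mV = amp1(pr$soma), amp_dend_mV = amp1(pr$dend),
               latency_ms = if (lat$found) lat$latency_ms else NA_real_,
               total_length_um = pr$total_length_um)
  })
  do.call(rbind, rows)
}

#' Mono-exponential fit of bAP attenuation
#'
#' Least-squares fit of `amp_dend = a0 * exp(-x / lambda)` over points whose
#' distance lies in `range_um`, performed in linear space with a log-linear
#' (analytic) initialization, so the result is deterministic and invariant
#' to point order.  Flat or increasing amplitude profiles are flagged
#' degenerate (`lambda = Inf`) rather than fit.
#'
#' @param points Data frame from [propagation_points()] (needs
#'   `distance_um`, `amp_dend_mV`).
#' @param range_um `(lo, hi)` fitting range in um (default 0-212, the range
#'   over which the attenuation is well constrained).
#' @param weighted Weight points by 1/amplitude (default unweighted).
#' @return An object of class `attenuation_fit` with `a0_mV`, `lambda_um`,
#'   `fit_range_um`, `n`, `rss`, `degenerate`.
#' @export
fit_attenuation <- function(points, range_um = c(0, 212), weighted = FALSE) {
  pts <- points[points$distance_um >= range_um[1] &
                  points$distance_um <= range_um[2], , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("need at least 3 points inside the fitting range", call. = FALSE)
  if (any(pts$amp_dend_mV <= 0))
    stop("amplitudes must be positive", call. = FALSE)
  x <- pts$distance_um; y <- pts$amp_dend_mV
  ll <- stats::lm(log(y) ~ x)
  slope <- stats::coef(ll)[["x"]]
  if (slope >= 0) {
    return(structure(list(a0_mV = mean(y), lambda_um = Inf,
                          fit_range_um = range_um, n = nrow(pts),
                          rss = sum((y - mean(y))^2), degenerate = TRUE),
                     class = "attenuation_fit"))
  }
  start <- list(a0 = exp(stats::coef(ll)[[1]]), lambda = -1 / slope)
  w <- if (weighted) 1 / y else rep(1, length(y))
  fit <- minpack.lm::nlsLM(y ~ a0 * exp(-x / lambda), start = start,
                           weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(a0_mV = cf[["a0"]], lambda_um = cf[["lambda"]],
                 fit_range_um = range_um, n = nrow(pts),
                 rss = sum(stats::residuals(fit)^2), degenerate = FALSE),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  if (x$degenerate)
    cat("<attenuation_fit> degenerate (flat profile), a0 =",
        signif(x$a0_mV, 4), "mV\n")
  else
    cat(sprintf("<attenuation_fit> a0 = %.4g mV, lambda = %.4g um (n = %d, range %g-%g um)\n",
                x$a0_mV, x$lambda_um, x$n, x$fit_range_um[1],
                x$fit_range_um[2]))
  invisible(x)
}

#' Predict dendritic amplitude from an attenuation fit
#'
#' @param object An `attenuation_fit`.
#' @param distance_um Distances (um).
#' @param ... Unused.
#' @return Predicted amplitudes (mV).
#' @export
predict.attenuation_fit <- function(object, distance_um, ...) {
  if (object$degenerate) return(rep(object$a0_mV, length(distance_um)))
  object$a0_mV * exp(-distance_um / object$lambda_um)
}

#' Normalized attenuation over relative dendritic distance
#'
#' Normalizes amplitudes to the paired somatic AP (`y = amp_dend/amp_soma`)
#' and distances to the total dendritic length (`x = distance/total`), then
#' fits the one-parameter mono-exponential `y = exp(-x / lambda_rel)` with
#' `y(0) = 1` enforced by construction.  The result is invariant to uniform
#' rescaling of all amplitudes.
#'
#' @param points Data frame with `distance_um`, `amp_soma_mV`,
#'   `amp_dend_mV`, `total_length_um` (required).
#' @return An object of class `norm_attenuation_fit` with `lambda_rel`
#'   (relative length constant), `n`, and `predict`-able curve.
#' @export
normalized_attenuation <- function(points) {
  if (!"total_length_um" %in% names(points) ||
      any(!is.finite(points$total_length_um)))
    stop("points must carry a finite total_length_um", call. = FALSE)
  xp <- points$distance_um / points$total_length_um
  yp <- points$amp_dend_mV / points$amp_soma_mV
  if (any(yp <= 0) || any(yp > 1 + 1e-6))
    stop("normalized amplitudes must lie in (0, 1]", call. = FALSE)
  use <- xp > 0
  if (sum(use) < 2L)
    stop("need at least 2 points at non-zero relative distance",
         call. = FALSE)
  # log-linear through the origin, then refine in linear space
  lam0 <- -sum(xp[use]^2) / sum(xp[use] * log(yp[use]))
  if (!is.finite(lam0) || lam0 <= 0) lam0 <- 1
  x <- xp; y <- yp
  fit <- minpack.lm::nlsLM(y ~ exp(-x / lam), start = list(lam = lam0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  structure(list(lambda_rel = stats::coef(fit)[["lam"]], n = length(xp),
                 rss = sum(stats::residuals(fit)^2)),
            class = "norm_attenuation_fit")
}

#' @export
predict.norm_attenuation_fit <- function(object, rel_distance, ...) {
  exp(-rel_distance / object$lambda_rel)
}

#' Conduction velocity from the latency-distance regression
#'
#' Ordinary least squares of half-max latency (ms) on recording distance
#' (um); the velocity is the reciprocal slope.  A zero or negative slope is
#' flagged degenerate rather than raised.
#'
#' @param points Data frame with `distance_um` and `latency_ms` (NA
#'   latencies dropped).
#' @return List with `velocity_um_per_ms`, `intercept_ms`, `r` (correlation
#'   coefficient of the fit), `n`, `degenerate`.
#' @export
fit_velocity <- function(points) {
  pts <- points[is.finite(points$latency_ms), , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("need at least 3 points with finite latencies", call. = FALSE)
  fit <- stats::lm(latency_ms ~ distance_um, data = pts)
  slope <- stats::coef(fit)[["distance_um"]]
  r <- if (stats::sd(pts$latency_ms) == 0) NA_real_ else
    stats::cor(pts$distance_um, pts$latency_ms)
  if (slope <= 0)
    return(list(velocity_um_per_ms = NA_real_,
                intercept_ms = stats::coef(fit)[[1]], r = r, n = nrow(pts),
                degenerate = TRUE))
  list(velocity_um_per_ms = 1 / slope,
       intercept_ms = stats::coef(fit)[[1]], r = r, n = nrow(pts),
       degenerate = FALSE)
}
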