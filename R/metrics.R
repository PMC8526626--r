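#' Classifier thresholds for behaviour labels
#'
#' Behaviour labels are assigned from the steady-state metrics with fixed
#' bands: straight vs turning by `|theta_dot|`, slithering vs sidewinding
#' vs backward travel by `|gamma|`, spinning when the body turns without
#' translating.  Runs whose metrics have not converged between the last
#' two periods are labelled `transition`.  The cutoffs are configurable
#' and are carried into all output metadata.
#'
#' @param straight_rate `|theta_dot|` below which a path is straight
#'   (rad/period; default 0.05).
#' @param sidewinding_band `|gamma|` range (rad) labelled sidewinding;
#'   below is slithering, above is backward travel (default
#'   `c(0.35, 2.6)`).
#' @param spin_speed `v_eff` below which a turning snake is spinning in
#'   place (body lengths/period; default 0.02).
#' @param steady_tol absolute metric changes between the final two
#'   one-period windows above which the run is a `transition`:
#'   named vector for `theta_dot` (rad/period), `gamma` (rad), `v_eff`
#'   (body lengths/period).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(straight_rate = 0.05,
                              sidewinding_band = c(0.35, 2.6),
                              spin_speed = 0.02,
                              steady_tol = c(theta_dot = 0.05,
                                             gamma = 0.1, v_eff = 0.02)) {
  if (straight_rate <= 0 || spin_speed <= 0 || any(sidewinding_band <= 0))
    stop("classifier thresholds must be positive")
  if (diff(sidewinding_band) <= 0)
    stop("'sidewinding_band' must be an increasing range")
  structure(list(straight_rate = straight_rate,
                 sidewinding_band = sidewinding_band,
                 spin_speed = spin_speed, steady_tol = steady_tol),
            class = "classifier_config")
}

# wrap an angle into (-pi, pi]
wrap_angle <- function(a) a - 2 * pi * ceiling((a - pi) / (2 * pi))

# Period-smoothed series used by all steady-state metrics.  The COM
# velocity is replaced by the trailing one-period mean velocity
# (displacement over the preceding period), which annihilates every
# intra-period harmonic of the periodic steady state and leaves the
# macroscopic drift; the mean orientation is smoothed the same way.
# theta is the unwrapped heading angle of that smoothed velocity.
metric_series <- function(traj, window) {
  tt <- traj$time
  dt <- tt[2] - tt[1]
  spp <- as.integer(round(1 / dt))
  if (window[2] <= window[1]) stop("metric window must be increasing")
  if (window[2] - window[1] < 1 - 1e-9)
    stop("metric window must cover at least one full period")
  if (window[1] < tt[1] + 1 - 1e-9)
    stop("metric window must start at least one period after the ",
         "trajectory begins (trailing one-period averages are used)")
  if (window[2] > tt[length(tt)] + 1e-9)
    stop("metric window extends beyond the trajectory")
  i0 <- which.min(abs(tt - window[1]))
  i1 <- which.min(abs(tt - window[2]))
  idx <- i0:i1
  lag <- spp
  vs_x <- (traj$x[idx] - traj$x[idx - lag])
  vs_y <- (traj$y[idx] - traj$y[idx - lag])
  ca <- pracma::cumtrapz(tt, traj$alpha)
  alpha_s <- as.vector(ca[idx] - ca[idx - lag])
  psi <- signal::unwrap(atan2(vs_y, vs_x))
  list(t = tt[idx], vs = cbind(vs_x, vs_y), alpha_s = alpha_s, psi = psi)
}

#' Steering rate of the COM trajectory
#'
#' The net rotation of the (period-smoothed) COM velocity heading per
#' unit time over the window: zero for rectilinear travel, the angular
#' rate for steady turning.
#'
#' @param traj a [simulate_snake()] trajectory (or any data frame with
#'   `time`, `x`, `y`, `alpha` columns, uniformly sampled).
#' @param window `c(t0, t1)` in periods covering at least one full period
#'   of steady state and starting at least one period after the
#'   trajectory begins; default is the final period.
#' @return Steering rate in radians per period.
#' @export
steering_rate <- function(traj, window = NULL) {
  window <- default_window(traj, window)
  ms <- metric_series(traj, window)
  (ms$psi[length(ms$psi)] - ms$psi[1]) / (ms$t[length(ms$t)] - ms$t[1])
}

#' Pose angle between body orientation and travel direction
#'
#' The signed angle \eqn{\gamma = \mathrm{atan2}((\bar t \times \bar u)
#' \cdot e_z, \bar t \cdot \bar u)} between the (period-smoothed) mean
#' orientation direction and COM velocity direction, averaged over the
#' window after unwrapping to avoid branch artifacts near \eqn{\pm\pi},
#' then wrapped back into \eqn{(-\pi, \pi]}.  Near zero for slithering
#' (body tangent to path), large for sidewinding, near \eqn{\pi} for
#' backward travel.
#'
#' @inheritParams steering_rate
#' @return Pose angle in radians, in \eqn{(-\pi, \pi]}.
#' @export
pose_angle <- function(traj, window = NULL) {
  window <- default_window(traj, window)
  ms <- metric_series(traj, window)
  tb <- cbind(cos(ms$alpha_s), sin(ms$alpha_s))
  cr <- tb[, 1] * ms$vs[, 2] - tb[, 2] * ms$vs[, 1]
  dd <- tb[, 1] * ms$vs[, 1] + tb[, 2] * ms$vs[, 2]
  ang <- signal::unwrap(atan2(cr, dd))
  span <- ms$t[length(ms$t)] - ms$t[1]
  wrap_angle(pracma::trapz(ms$t, ang) / span)
}

#' Effective speed of the COM
#'
#' The magnitude of the window-averaged COM velocity expressed in the
#' frame co-rotating with the trajectory heading.  Period-smoothed
#' velocities are rotated back by the accumulated heading before
#' averaging, so steady turning does not cancel the average; the
#' chord-to-arc factor \eqn{(\beta/2)/\sin(\beta/2)} (with \eqn{\beta}
#' the rotation per period) converts the per-period displacement chord
#' into the arc speed, making the metric exact for uniform circular as
#' well as rectilinear motion.
#'
#' @inheritParams steering_rate
#' @return Effective speed in body lengths per period (>= 0).
#' @export
effective_speed <- function(traj, window = NULL) {
  window <- default_window(traj, window)
  ms <- metric_series(traj, window)
  phi <- ms$psi - ms$psi[1]
  vr_x <- cos(phi) * ms$vs[, 1] + sin(phi) * ms$vs[, 2]
  vr_y <- -sin(phi) * ms$vs[, 1] + cos(phi) * ms$vs[, 2]
  span <- ms$t[length(ms$t)] - ms$t[1]
  vbar <- c(pracma::trapz(ms$t, vr_x), pracma::trapz(ms$t, vr_y)) / span
  beta <- (ms$psi[length(ms$psi)] - ms$psi[1]) / span  # rotation per period
  corr <- if (abs(beta) > 1e-9 && abs(beta) < 1.9 * pi)
    (beta / 2) / sin(beta / 2) else 1
  sqrt(sum(vbar^2)) * abs(corr)
}

default_window <- function(traj, window) {
  if (!is.null(window)) return(window)
  tmax <- traj$time[nrow(traj)]
  c(tmax - 1, tmax)
}

#' Steady-state gait metrics and behaviour label
#'
#' Computes pose angle, steering rate, and effective speed over the
#' window (default: the final period), checks convergence against the
#' preceding one-period window, and classifies the behaviour.
#'
#' @inheritParams steering_rate
#' @param cfg a [classifier_config()].
#' @return An object of class `gait_metrics` with fields `gamma`,
#'   `theta_dot`, `v_eff`, `converged`, `label`, `window`.
#' @export
gait_metrics <- function(traj, window = NULL, cfg = classifier_config()) {
  window <- default_window(traj, window)
  m <- list(gamma = pose_angle(traj, window),
            theta_dot = steering_rate(traj, window),
            v_eff = effective_speed(traj, window))
  prev <- window - (window[2] - window[1])
  m$converged <- if (prev[1] >= traj$time[1] + 1 - 1e-9) {
    p <- list(gamma = pose_angle(traj, prev),
              theta_dot = steering_rate(traj, prev),
              v_eff = effective_speed(traj, prev))
    tol <- cfg$steady_tol
    abs(wrap_angle(m$gamma - p$gamma)) <= tol[["gamma"]] &&
      abs(m$theta_dot - p$theta_dot) <= tol[["theta_dot"]] &&
      abs(m$v_eff - p$v_eff) <= tol[["v_eff"]]
  } else NA
  m$window <- window
  m$label <- classify(m, cfg)
  structure(m, class = "gait_metrics")
}

#' @export
print.gait_metrics <- function(x, ...) {
  cat("Gait metrics over window [", x$window[1], ", ", x$window[2], "]:\n",
      "  pose angle gamma  = ", format(x$gamma, digits = 4), " rad\n",
      "  steering rate     = ", format(x$theta_dot, digits = 4),
      " rad/period\n",
      "  effective speed   = ", format(x$v_eff, digits = 4),
      " body lengths/period\n",
      "  label             = ", x$label,
      if (isFALSE(x$converged)) " (not converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Classify a behaviour from its metrics
#'
#' Deterministic mapping from `(gamma, theta_dot, v_eff)` to one of
#' `straight_slithering`, `turning_slithering`, `straight_sidewinding`,
#' `turning_sidewinding`, `spinning`, `backward_slithering`,
#' `transition`.
#'
#' @param metrics a [gait_metrics()] result, or a list with fields
#'   `gamma`, `theta_dot`, `v_eff` (and optionally `converged`).
#' @param cfg a [classifier_config()].
#' @return A behaviour label string.
#' @export
classify <- function(metrics, cfg = classifier_config()) {
  if (isFALSE(metrics$converged)) return("transition")
  g <- abs(metrics$gamma); td <- abs(metrics$theta_dot)
  if (metrics$v_eff < cfg$spin_speed && td >= cfg$straight_rate)
    return("spinning")
  if (g > cfg$sidewinding_band[2]) return("backward_slithering")
  mode <- if (g < cfg$sidewinding_band[1]) "slithering" else "sidewinding"
  turn <- if (td < cfg$straight_rate) "straight" else "turning"
  paste(turn, mode, sep = "_")
}
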