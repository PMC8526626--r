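#' Plot a snake trajectory
#'
#' Draws the COM path and, optionally, body-shape snapshots at selected
#' times (quick-look base graphics).
#'
#' @param x a [simulate_snake()] trajectory.
#' @param snapshots times (periods) at which to overlay body shapes.
#' @param ... passed to [graphics::plot()].
#' @return The trajectory, invisibly.
#' @export
plot.snake_trajectory <- function(x, snapshots = NULL, ...) {
  graphics::plot(x$x, x$y, type = "l", asp = 1, xlab = "x (body lengths)",
                 ylab = "y (body lengths)", ...)
  if (!is.null(snapshots)) {
    gait <- attr(x, "gait"); sim <- attr(x, "sim")
    grid <- body_grid(sim$n_s)
    for (ts in snapshots) {
      i <- which.min(abs(x$time - ts))
      st <- snake_state(com = c(x$x[i], x$y[i]), alpha_bar = x$alpha[i],
                        time = x$time[i])
      cf <- reconstruct_configuration(st, gait, grid)
      graphics::lines(cf$positions[, 1], cf$positions[, 2], col = "grey40")
    }
  }
  invisible(x)
}

#' Plot a phase map
#'
#' Images one metric field over the (A, Phi) plane with the zero-level
#' separatrices of steering rate (dashed) and pose angle (dash-dot)
#' overlaid.
#'
#' @param x a [sweep_phase_map()] result.
#' @param field one of `"theta_dot"`, `"gamma"`, `"v_eff"`.
#' @param ... passed to [graphics::image()].
#' @return The phase map, invisibly.
#' @export
plot.phase_map <- function(x, field = c("theta_dot", "gamma", "v_eff"),
                           ...) {
  field <- match.arg(field)
  graphics::image(x$A, x$phi, x[[field]], xlab = "lifting amplitude A",
                  ylab = expression(Phi), main = field, ...)
  for (p in x$separatrices$theta_dot)
    graphics::lines(p$x, p$y, lty = 2)
  for (p in x$separatrices$gamma)
    graphics::lines(p$x, p$y, lty = 4)
  invisible(x)
}
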