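#' Snake state: centre of mass and mean orientation
#'
#' The six-dimensional ODE state: COM position \eqn{\bar x} (body
#' lengths), COM velocity \eqn{\bar x_t} (body lengths per period), mean
#' orientation \eqn{\bar\alpha} (radians) and its rate (radians per
#' period), plus the current time in periods.
#'
#' @param com,com_vel numeric 2-vectors.
#' @param alpha_bar,alpha_bar_t numeric scalars.
#' @param time time in periods.
#' @return An object of class `snake_state`.
#' @export
snake_state <- function(com = c(0, 0), com_vel = c(0, 0), alpha_bar = 0,
                        alpha_bar_t = 0, time = 0) {
  vals <- c(com, com_vel, alpha_bar, alpha_bar_t, time)
  if (length(vals) != 7 || !all(is.finite(vals)))
    stop("snake_state components must be finite (com/com_vel of length 2)")
  structure(list(com = as.numeric(com), com_vel = as.numeric(com_vel),
                 alpha_bar = as.numeric(alpha_bar),
                 alpha_bar_t = as.numeric(alpha_bar_t),
                 time = as.numeric(time)),
            class = "snake_state")
}

#' Reconstruct the body configuration from a state
#'
#' Rebuilds per-arclength positions, orientations, frames, and velocities
#' from the COM/orientation state and the prescribed curvature wave:
#' \eqn{\alpha(s) = \bar\alpha + I[\kappa]},
#' \eqn{x(s) = \bar x + I[\mathbf{t}]} with tangent
#' \eqn{\mathbf{t} = (\cos\alpha, \sin\alpha)} and normal
#' \eqn{\mathbf{n} = (-\sin\alpha, \cos\alpha)}.  Velocities are obtained
#' analytically through the chain rule,
#' \eqn{x_t(s) = \bar x_t + I[(\bar\alpha_t + I[\kappa_t])\,\mathbf{n}]},
#' not by numerical differencing.  The mean-zero property of \eqn{I}
#' guarantees that the quadrature means of \eqn{x(s)} and \eqn{\alpha(s)}
#' equal the COM and \eqn{\bar\alpha} exactly.
#'
#' @param state a [snake_state()].
#' @param gait a [gait_params()].
#' @param grid a [body_grid()].
#' @param t evaluation time (defaults to `state$time`).
#' @return An object of class `body_configuration` with fields `s`,
#'   `positions` (n x 2), `alpha`, `tangents`, `normals`, `velocities`
#'   (n x 2), `alpha_t`, `com`, `time`.
#' @export
reconstruct_configuration <- function(state, gait, grid, t = state$time) {
  kap <- lateral_curvature(grid$s, t, gait)
  alpha <- state$alpha_bar + mean_zero_integral(kap, grid)
  tang <- cbind(cos(alpha), sin(alpha))
  norm <- cbind(-tang[, 2], tang[, 1])
  pos <- sweep(mean_zero_integral(tang, grid), 2, state$com, `+`)
  kd <- curvature_time_derivatives(grid$s, t, gait)
  alpha_t <- state$alpha_bar_t + mean_zero_integral(kd$kappa_t, grid)
  vel <- sweep(mean_zero_integral(alpha_t * norm, grid), 2,
               state$com_vel, `+`)
  structure(list(s = grid$s, positions = pos, alpha = alpha,
                 tangents = tang, normals = norm, velocities = vel,
                 alpha_t = alpha_t, com = state$com, time = t),
            class = "body_configuration")
}

#' @export
print.body_configuration <- function(x, ...) {
  cat("Body configuration at t = ", format(x$time), ": ",
      length(x$s), " nodes, COM (", format(x$com[1]), ", ",
      format(x$com[2]), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.body_configuration <- function(x, ...) {
  data.frame(s = x$s, x = x$positions[, 1], y = x$positions[, 2],
             alpha = x$alpha, vx = x$velocities[, 1],
             vy = x$velocities[, 2])
}
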