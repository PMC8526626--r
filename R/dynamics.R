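#' Simulation configuration
#'
#' Controls the time integration of the equations of motion.  The snake
#' is released from rest with the waves already imposed at `t = 0` and
#' integrated over `n_periods` undulation periods with an adaptive
#' Dormand-Prince Runge-Kutta scheme (deSolve's `ode45`); the default 10
#' periods let startup transients dissipate before metrics are taken over
#' the final period.
#'
#' @param n_periods number of undulation periods to simulate (>= 1).
#' @param n_s arclength nodes for the body grid (default 201).
#' @param rtol,atol integrator tolerances.
#' @param samples_per_period uniform output sampling density (>= 100).
#' @param method deSolve integration method (default `"ode45"`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_periods = 10, n_s = 201, rtol = 1e-8,
                       atol = 1e-10, samples_per_period = 200,
                       method = "ode45") {
  if (!is.numeric(n_periods) || length(n_periods) != 1L || n_periods < 1)
    stop("'n_periods' must be >= 1")
  if (samples_per_period < 100)
    stop("'samples_per_period' must be >= 100")
  structure(list(n_periods = as.integer(n_periods), n_s = as.integer(n_s),
                 rtol = rtol, atol = atol,
                 samples_per_period = as.integer(samples_per_period),
                 method = method),
            class = "sim_config")
}

#' Moment of inertia of the body shape
#'
#' \eqn{J = \int_0^1 (x - \bar x)^2\,ds}, the (nondimensional) second
#' moment of the centreline about the COM.  For a straight body,
#' \eqn{J = 1/12}.
#'
#' @param config a [reconstruct_configuration()] result.
#' @param grid the [body_grid()] the configuration was built on.
#' @return Scalar `J > 0`.
#' @export
moment_of_inertia <- function(config, grid) {
  rel <- sweep(config$positions, 2, config$com)
  quad_mean(rowSums(rel^2), grid)
}

#' Instantaneous accelerations of COM and mean orientation
#'
#' Assembles the nondimensional equations of motion.  The translational
#' balance is \eqn{Fr\,\bar x_{tt} = \int_0^1 F\,ds} with the Coulomb
#' force density \eqn{F = -N p \mu}.  The angular balance is
#' \deqn{Fr\,\bar\alpha_{tt} = \frac{1}{J}\int_0^1 (x-\bar x)\times F\,ds
#'  + \frac{Fr}{J}\int_0^1 I[\mathbf n]\cdot
#'    I[\mathbf t(\bar\alpha_t + I[\kappa_t])^2]
#'  - I[\mathbf t]\cdot I[\mathbf t\,I[\kappa_{tt}]]\,ds,}
#' where the second integral is the inertial correction arising from the
#' prescribed-curvature kinematics (it is obtained by expanding
#' \eqn{x_{tt}} through the reconstruction and crossing with
#' \eqn{x - \bar x}; the internal-force field drops out because its
#' integral and torque integral vanish).
#'
#' This R assembly is the reference implementation; [simulate_snake()]
#' integrates an equivalent compiled version, and the two are
#' cross-checked in the package tests together with a finite-difference
#' oracle.
#'
#' @param state a [snake_state()].
#' @param gait a [gait_params()].
#' @param env an [environment_params()].
#' @param grid a [body_grid()].
#' @param t evaluation time (defaults to `state$time`).
#' @return A list with `com_acc` (2-vector) and `alpha_acc` (scalar).
#' @export
acceleration <- function(state, gait, env, grid, t = state$time) {
  config <- reconstruct_configuration(state, gait, grid, t)
  Nhat <- lifting_modulation(grid$s, t, gait)
  N <- normalized_weight(Nhat, grid)
  F <- friction_force_density(config, N, env)
  if (any(!is.finite(F)))
    stop("non-finite friction force encountered at t = ", format(t))
  w <- grid$weights
  F_net <- as.vector(crossprod(w, F))
  rel <- sweep(config$positions, 2, state$com)  # = I[t]
  torque <- sum(w * (rel[, 1] * F[, 2] - rel[, 2] * F[, 1]))
  J <- moment_of_inertia(config, grid)

  # inertial correction; I[n] = (-I[sin alpha], I[cos alpha]) = rot90(I[t])
  g <- config$alpha_t^2
  Itg <- mean_zero_integral(config$tangents * g, grid)
  kd <- curvature_time_derivatives(grid$s, t, gait)
  Iktt <- mean_zero_integral(kd$kappa_tt, grid)
  Itk <- mean_zero_integral(config$tangents * Iktt, grid)
  corr <- sum(w * (-rel[, 2] * Itg[, 1] + rel[, 1] * Itg[, 2] -
                     (rel[, 1] * Itk[, 1] + rel[, 2] * Itk[, 2])))

  list(com_acc = F_net / env$froude,
       alpha_acc = torque / (J * env$froude) + corr / J)
}

#' Simulate the snake over a number of undulation periods
#'
#' Integrates the COM/orientation equations of motion with the prescribed
#' lateral and lifting waves.  The dynamics are deterministic; there is
#' no randomness anywhere in the model.
#'
#' @param gait a [gait_params()].
#' @param env an [environment_params()].
#' @param sim a [sim_config()].
#' @param initial initial [snake_state()] (default: at rest at the
#'   origin, heading along +x, with the wave already imposed).
#' @return A `snake_trajectory`: a data frame with columns `time`, `x`,
#'   `y`, `vx`, `vy`, `alpha`, `alpha_t`, uniformly sampled, with the
#'   gait/env/sim objects attached as attributes.
#' @examples
#' \donttest{
#' traj <- simulate_snake(gait_params(A = 0), environment_params(2),
#'                        sim_config(n_periods = 4, n_s = 101, rtol = 1e-6))
#' gait_metrics(traj, window = c(3, 4))
#' }
#' @export
simulate_snake <- function(gait, env = environment_params(),
                           sim = sim_config(),
                           initial = snake_state()) {
  stopifnot(inherits(gait, "gait_params"),
            inherits(env, "environment_params"),
            inherits(sim, "sim_config"),
            inherits(initial, "snake_state"))
  grid <- body_grid(sim$n_s)
  ptr <- sim_core_create(unclass(gait), unclass(env)[1:4],
                         grid$s, grid$weights,
                         map_to_core(env$friction_map))
  rhs <- function(t, y, parms) list(sim_core_rhs(parms, t, y))
  y0 <- c(initial$com, initial$com_vel, initial$alpha_bar,
          initial$alpha_bar_t)
  times <- initial$time +
    seq(0, sim$n_periods, by = 1 / sim$samples_per_period)
  out <- try(deSolve::ode(y = y0, times = times, func = rhs, parms = ptr,
                          method = sim$method, rtol = sim$rtol,
                          atol = sim$atol, maxsteps = 500000), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times) ||
      any(!is.finite(out))) {
    last <- if (inherits(out, "try-error")) NULL else out[nrow(out), ]
    stop("integration failed near t = ",
         if (is.null(last)) "start" else format(last[1]),
         if (!is.null(last)) paste0(" (state: ",
                                    paste(format(last[-1]), collapse = ", "),
                                    ")") else "")
  }
  traj <- data.frame(time = out[, 1], x = out[, 2], y = out[, 3],
                     vx = out[, 4], vy = out[, 5], alpha = out[, 6],
                     alpha_t = out[, 7])
  structure(traj, gait = gait, env = env, sim = sim, initial = initial,
            class = c("snake_trajectory", "data.frame"))
}

#' @export
print.snake_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat("Snake trajectory: ", format(x$time[n] - x$time[1]),
      " periods, ", n, " samples; final COM (", format(x$x[n], digits = 4),
      ", ", format(x$y[n], digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Net friction force and torque along a trajectory
#'
#' Re-evaluates the friction force density at each stored sample in the
#' window, integrates over arclength to get the instantaneous net force
#' and torque about the COM, and averages them over the window (default:
#' the final full period) with the trapezoidal rule.  At steady state the
#' period averages vanish for symmetric gaits (no lifting, or symmetric
#' lifting with an even wavenumber ratio).
#'
#' @param traj a [simulate_snake()] trajectory.
#' @param window `c(t0, t1)` in periods; default is the final period.
#' @return A list with `times`, `F_inst` (m x 2), `T_inst` (length m),
#'   `F_net` (2-vector), `T_net` (scalar).
#' @export
net_force_torque <- function(traj, window = NULL) {
  gait <- attr(traj, "gait"); env <- attr(traj, "env")
  sim <- attr(traj, "sim")
  grid <- body_grid(sim$n_s)
  tmax <- traj$time[nrow(traj)]
  if (is.null(window)) window <- c(tmax - 1, tmax)
  idx <- which(traj$time >= window[1] - 1e-9 &
                 traj$time <= window[2] + 1e-9)
  if (length(idx) < 2) stop("window contains fewer than 2 samples")
  m <- length(idx)
  Fi <- matrix(0, m, 2); Ti <- numeric(m)
  w <- grid$weights
  for (j in seq_len(m)) {
    r <- traj[idx[j], ]
    st <- snake_state(com = c(r$x, r$y), com_vel = c(r$vx, r$vy),
                      alpha_bar = r$alpha, alpha_bar_t = r$alpha_t,
                      time = r$time)
    cf <- reconstruct_configuration(st, gait, grid)
    N <- normalized_weight(lifting_modulation(grid$s, r$time, gait), grid)
    F <- friction_force_density(cf, N, env)
    Fi[j, ] <- as.vector(crossprod(w, F))
    rel <- sweep(cf$positions, 2, st$com)
    Ti[j] <- sum(w * (rel[, 1] * F[, 2] - rel[, 2] * F[, 1]))
  }
  tt <- traj$time[idx]
  span <- tt[m] - tt[1]
  list(times = tt, F_inst = Fi, T_inst = Ti,
       F_net = c(pracma::trapz(tt, Fi[, 1]),
                 pracma::trapz(tt, Fi[, 2])) / span,
       T_net = pracma::trapz(tt, Ti) / span)
}
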