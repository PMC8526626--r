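# Independent oracles and synthetic-trajectory builders used across the
# test files.  The oracles deliberately avoid the code paths they check:
# dense quadrature instead of the default grid, finite differences
# instead of the analytic chain rule / assembled angular equation.

# reconstruction oracle: positions from a much finer quadrature grid,
# interpolated back onto the coarse nodes
dense_position_oracle <- function(state, gait, s_coarse, t,
                                  n_dense = 2001) {
  dg <- body_grid(n_dense)
  kap <- lateral_curvature(dg$s, t, gait)
  alpha <- state$alpha_bar + mean_zero_integral(kap, dg)
  tang <- cbind(cos(alpha), sin(alpha))
  pos <- sweep(mean_zero_integral(tang, dg), 2, state$com, `+`)
  cbind(stats::approx(dg$s, pos[, 1], xout = s_coarse)$y,
        stats::approx(dg$s, pos[, 2], xout = s_coarse)$y)
}

# angular acceleration from the raw momentum balance: expand the body
# acceleration via finite differences of the velocity reconstruction
# V(alpha_bar, alpha_bar_t, t) = I[alpha_t n] and solve the torque
# balance Fr * int (x - xbar) x x_tt ds = int (x - xbar) x F ds for
# alpha_bar_tt.  Shares no algebra with the assembled angular equation.
fd_alpha_acc_oracle <- function(state, gait, env, grid, h = 1e-5) {
  V <- function(ab, abt, tt) {
    kap <- lateral_curvature(grid$s, tt, gait)
    alpha <- ab + mean_zero_integral(kap, grid)
    kd <- curvature_time_derivatives(grid$s, tt, gait)
    at <- abt + mean_zero_integral(kd$kappa_t, grid)
    mean_zero_integral(at * cbind(-sin(alpha), cos(alpha)), grid)
  }
  ab <- state$alpha_bar; abt <- state$alpha_bar_t; tt <- state$time
  dV_dab <- (V(ab + h, abt, tt) - V(ab - h, abt, tt)) / (2 * h)
  dV_dabt <- (V(ab, abt + h, tt) - V(ab, abt - h, tt)) / (2 * h)
  dV_dt <- (V(ab, abt, tt + h) - V(ab, abt, tt - h)) / (2 * h)
  cf <- reconstruct_configuration(state, gait, grid)
  rel <- sweep(cf$positions, 2, state$com)
  N <- normalized_weight(lifting_modulation(grid$s, tt, gait), grid)
  F <- friction_force_density(cf, N, env)
  w <- grid$weights
  crossz <- function(a, b) a[, 1] * b[, 2] - a[, 2] * b[, 1]
  Tfric <- sum(w * crossz(rel, F))
  known <- abt * sum(w * crossz(rel, dV_dab)) + sum(w * crossz(rel, dV_dt))
  coefJ <- sum(w * crossz(rel, dV_dabt))
  (Tfric / env$froude - known) / coefJ
}

# synthetic trajectory with prescribed COM path and mean orientation
synth_traj <- function(times, x, y, alpha) {
  structure(data.frame(time = times, x = x, y = y,
                       vx = c(NA, diff(x) / diff(times)[1]),
                       vy = c(NA, diff(y) / diff(times)[1]),
                       alpha = alpha, alpha_t = 0),
            class = c("snake_trajectory", "data.frame"))
}

# uniform straight path at given speed and heading, orientation
# `pose_off` radians away from the travel direction
straight_traj <- function(speed = 0.6, heading = 0, pose_off = 0,
                          n_periods = 5, spp = 100) {
  tt <- seq(0, n_periods, by = 1 / spp)
  synth_traj(tt, speed * tt * cos(heading), speed * tt * sin(heading),
             rep(heading + pose_off, length(tt)))
}

# uniform circular path: radius r, angular rate omega (rad/period),
# orientation tangent to the path
circle_traj <- function(r = 2, omega = 2 * pi / 5, n_periods = 5,
                        spp = 100) {
  tt <- seq(0, n_periods, by = 1 / spp)
  th <- omega * tt
  synth_traj(tt, r * cos(th), r * sin(th), th + pi / 2)
}

# default quick-simulation settings used where full accuracy is not the
# point of the test
quick_sim <- function(n_periods = 10)
  sim_config(n_periods = n_periods, n_s = 101, rtol = 1e-6, atol = 1e-8,
             samples_per_period = 100)
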