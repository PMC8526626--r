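#' Row of friction disks (post-row analogue)
#'
#' Builds `n` equally spaced disks along a line — the planar reduction of
#' a row of rigid posts, which become high-friction patches.
#'
#' @param n number of disks.
#' @param center centre of the row (2-vector, body lengths).
#' @param spacing centre-to-centre spacing (body lengths).
#' @param diameter disk diameter (body lengths).
#' @param scale friction scale inside the disks.
#' @param angle row direction (radians; default pi/2, a row across the
#'   +x travel direction).
#' @return A list of [disk()] primitives (pass to [friction_map()]).
#' @export
disk_row <- function(n, center, spacing, diameter, scale,
                     angle = pi / 2) {
  dvec <- c(cos(angle), sin(angle))
  offs <- (seq_len(n) - (n + 1) / 2) * spacing
  lapply(offs, function(o) disk(center + o * dvec, diameter, scale))
}

#' Ensemble specification for deflection experiments
#'
#' Describes a deterministic ensemble of identical snakes launched at
#' evenly spaced (or explicitly listed) lateral offsets toward a friction
#' landscape.  There is no randomness: the spread of deflection angles
#' arises from the offsets relative to the pattern, as in the underlying
#' deterministic dynamics.
#'
#' @param offsets numeric vector of lateral offsets of the initial COM
#'   (body lengths, perpendicular to the approach heading), or a length-2
#'   range plus `count` to space them evenly.
#' @param count number of snakes when `offsets` is a range.
#' @param map a [friction_map()].
#' @param gait,env,sim common run configuration; `env$friction_map` is
#'   replaced by `map`.
#' @param heading approach heading (radians; default 0, along +x).
#' @param start base initial COM position (2-vector).
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(offsets, count = NULL, map = friction_map(),
                          gait = gait_params(),
                          env = environment_params(mu_t_ratio = 10),
                          sim = sim_config(n_periods = 20, n_s = 101,
                                           rtol = 1e-6, atol = 1e-8,
                                           samples_per_period = 100),
                          heading = 0, start = c(0, 0)) {
  if (!is.null(count)) {
    if (length(offsets) != 2) stop("with 'count', 'offsets' is a range")
    offsets <- seq(offsets[1], offsets[2], length.out = count)
  }
  if (length(offsets) < 1) stop("at least one offset is required")
  env$friction_map <- map
  structure(list(offsets = offsets, map = map, gait = gait, env = env,
                 sim = sim, heading = heading, start = start),
            class = "ensemble_spec")
}

# times (subset of trajectory samples) at which any body node lies on a
# non-background friction scale; all sampled times are reconstructed in
# one vectorized pass (one matrix column per time)
interaction_times <- function(traj, stride = 5) {
  gait <- attr(traj, "gait"); env <- attr(traj, "env")
  sim <- attr(traj, "sim")
  map <- env$friction_map
  if (is.null(map) || length(map$primitives) == 0) return(numeric(0))
  grid <- body_grid(sim$n_s)
  idx <- seq(1, nrow(traj), by = stride)
  tt <- traj$time[idx]
  phase <- outer(grid$s, tt, `+`)
  kap <- gait$epsilon * cos(2 * pi * gait$k * phase)
  alpha <- sweep(mean_zero_integral(kap, grid), 2, traj$alpha[idx], `+`)
  px <- sweep(mean_zero_integral(cos(alpha), grid), 2, traj$x[idx], `+`)
  py <- sweep(mean_zero_integral(sin(alpha), grid), 2, traj$y[idx], `+`)
  sc <- local_scale(cbind(as.vector(px), as.vector(py)), map)
  hit <- colSums(matrix(sc != 1, nrow = grid$n_s)) > 0
  tt[hit]
}

# trailing one-period displacement heading at time t1 (window [t1-1, t1])
heading_at <- function(traj, t1) {
  i1 <- which.min(abs(traj$time - t1))
  i0 <- which.min(abs(traj$time - (t1 - 1)))
  atan2(traj$y[i1] - traj$y[i0], traj$x[i1] - traj$x[i0])
}

#' Run a deflection ensemble through a friction landscape
#'
#' Simulates each snake of the spec, detects the interval during which
#' any body node samples a non-background friction scale, and measures
#' the deflection angle `alpha_p` as the signed change between the
#' heading averaged over one period before first interaction and one
#' period after the last interaction.  Snakes that get stuck (negligible
#' displacement over the final two periods) are flagged and excluded
#' from the probability density but still counted; with an empty map the
#' entry/exit windows default to the first and last periods of steady
#' travel.
#'
#' @param spec an [ensemble_spec()].
#' @param stride trajectory-sample stride for interaction detection.
#' @return An object of class `deflection_result`: a data frame with
#'   columns `offset`, `alpha_p`, `entry_heading`, `exit_heading`,
#'   `interacted`, `stuck`, `incomplete`, with the spec attached as an
#'   attribute.
#' @export
run_ensemble <- function(spec, stride = 5) {
  stopifnot(inherits(spec, "ensemble_spec"))
  perp <- c(-sin(spec$heading), cos(spec$heading))
  rows <- lapply(spec$offsets, function(off) {
    init <- snake_state(com = spec$start + off * perp,
                        alpha_bar = spec$heading)
    traj <- simulate_snake(spec$gait, spec$env, spec$sim, init)
    tmax <- traj$time[nrow(traj)]
    it <- interaction_times(traj, stride)
    interacted <- length(it) > 0
    # without any interaction, compare the first post-transient period
    # against the final one
    t_in <- if (interacted) max(min(it), 1 + traj$time[1]) else
      min(2 + traj$time[1], tmax)
    t_out <- if (interacted) min(max(it) + 1, tmax) else tmax
    incomplete <- interacted && (min(it) < 1 + traj$time[1] ||
                                   max(it) + 1 > tmax)
    n <- nrow(traj)
    i2 <- which.min(abs(traj$time - (tmax - 2)))
    stuck <- sqrt((traj$x[n] - traj$x[i2])^2 +
                    (traj$y[n] - traj$y[i2])^2) < 0.02
    entry <- heading_at(traj, t_in)
    exit <- heading_at(traj, t_out)
    data.frame(offset = off, alpha_p = wrap_angle(exit - entry),
               entry_heading = entry, exit_heading = exit,
               interacted = interacted, stuck = stuck,
               incomplete = incomplete)
  })
  structure(do.call(rbind, rows), spec = spec,
            class = c("deflection_result", "data.frame"))
}

#' Binned probability density of deflection angles
#'
#' Histogram density of the deflection angles of the non-stuck members
#' of a [run_ensemble()] result, on fixed-width bins over
#' `(-90, 90]` degrees.  The density integrates to 1 over the bins.
#'
#' @param result a `deflection_result` (or numeric vector of angles in
#'   radians).
#' @param bin_width_deg bin width in degrees (default 5).
#' @return A data frame with `bin_lo`, `bin_hi` (degrees), `count`, and
#'   `density` (per degree).
#' @export
deflection_pdf <- function(result, bin_width_deg = 5) {
  ang <- if (is.data.frame(result))
    result$alpha_p[!result$stuck] else result
  deg <- ang * 180 / pi
  edges <- seq(-90, 90, by = bin_width_deg)
  cnt <- as.vector(table(cut(deg, edges, right = TRUE)))
  n <- sum(cnt)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             count = cnt,
             density = if (n > 0) cnt / (n * bin_width_deg) else cnt * 0)
}

#' Refraction/reflection scan at a friction strip
#'
#' Launches one snake per incidence angle toward a strip interface and
#' records whether it is refracted (crosses, exit heading keeps the sign
#' of its normal component) or reflected (normal component reverses).
#' The incidence angle is measured between the approach heading and the
#' strip normal.
#'
#' @param angles incidence angles (radians).
#' @param strip_width,strip_scale strip geometry (scale 0 = frictionless).
#' @param distance approach distance from start to the strip (body
#'   lengths, along the strip normal).
#' @param gait,env,sim run configuration (defaults: planar gait on a
#'   strongly anisotropic substrate, which travels straight).
#' @return A data frame with `alpha`, `alpha_p`, `outcome`
#'   (`"refracted"`/`"reflected"`), `stuck`.
#' @export
incidence_scan <- function(angles, strip_width = 0.5, strip_scale = 0,
                           distance = 2.5,
                           gait = gait_params(),
                           env = environment_params(mu_t_ratio = 10),
                           sim = sim_config(n_periods = 20, n_s = 101,
                                            rtol = 1e-6, atol = 1e-8,
                                            samples_per_period = 100)) {
  rows <- lapply(angles, function(a) {
    # strip normal along +x; approach heading rotated by the incidence
    # angle relative to the normal
    m <- friction_map(strip(c(distance, 0), angle = pi / 2,
                            width = strip_width, scale = strip_scale))
    e <- env
    e$friction_map <- m
    init <- snake_state(alpha_bar = a)
    traj <- simulate_snake(gait, e, sim, init)
    res <- run_ensemble_single(traj, m)
    outcome <- if (sign(cos(res$exit)) != sign(cos(res$entry)))
      "reflected" else "refracted"
    data.frame(alpha = a, alpha_p = wrap_angle(res$exit - res$entry),
               outcome = outcome, stuck = res$stuck)
  })
  do.call(rbind, rows)
}

# entry/exit headings and stuck flag for one already-simulated trajectory
run_ensemble_single <- function(traj, map, stride = 5) {
  tmax <- traj$time[nrow(traj)]
  it <- interaction_times(traj, stride)
  t_in <- if (length(it)) max(min(it), 1 + traj$time[1]) else
    min(2 + traj$time[1], tmax)
  t_out <- if (length(it)) min(max(it) + 1, tmax) else tmax
  n <- nrow(traj)
  i2 <- which.min(abs(traj$time - (tmax - 2)))
  list(entry = heading_at(traj, t_in), exit = heading_at(traj, t_out),
       stuck = sqrt((traj$x[n] - traj$x[i2])^2 +
                      (traj$y[n] - traj$y[i2])^2) < 0.02)
}
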