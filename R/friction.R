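#' Frictional environment parameters
#'
#' Anisotropic Coulomb friction is characterized by the transverse and
#' backward coefficients relative to the forward one, `mu_t_ratio` =
#' \eqn{\mu_t/\mu_f} and `mu_b_ratio` = \eqn{\mu_b/\mu_f} (the backward
#' ratio has little effect on behaviour; 1.5 matches measurements on real
#' snakes).  The Froude number \eqn{Fr = (L/\tau^2)/(g\mu_f)} sets the
#' inertia-to-friction balance; terrestrial limbless locomotion is
#' friction dominated with \eqn{Fr \le 1} and the default is 0.1.
#' `velocity_reg` is the Coulomb regularization scale \eqn{\delta} (body
#' lengths per period): sliding directions are computed as
#' \eqn{u = v/\sqrt{|v|^2 + \delta^2}}, which removes the singularity of
#' \eqn{v/|v|} at rest while leaving fast nodes unaffected.
#'
#' @param mu_t_ratio transverse-to-forward friction ratio (> 0).
#' @param mu_b_ratio backward-to-forward friction ratio (> 0; default 1.5).
#' @param froude Froude number (> 0; default 0.1).
#' @param velocity_reg regularization scale \eqn{\delta} (> 0).
#' @param friction_map optional [friction_map()] describing a
#'   heterogeneous substrate; `NULL` means uniform friction.
#' @return An object of class `environment_params`.
#' @export
environment_params <- function(mu_t_ratio = 2, mu_b_ratio = 1.5,
                               froude = 0.1, velocity_reg = 1e-6,
                               friction_map = NULL) {
  for (nm in c("mu_t_ratio", "mu_b_ratio", "froude", "velocity_reg")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("environment parameter '", nm, "' must be a positive scalar")
  }
  if (!is.null(friction_map) && !inherits(friction_map, "friction_map"))
    stop("'friction_map' must be a friction_map object or NULL")
  structure(list(mu_t_ratio = mu_t_ratio, mu_b_ratio = mu_b_ratio,
                 froude = froude, velocity_reg = velocity_reg,
                 friction_map = friction_map),
            class = "environment_params")
}

#' @export
print.environment_params <- function(x, ...) {
  cat("Environment: mu_t/mu_f = ", x$mu_t_ratio, ", mu_b/mu_f = ",
      x$mu_b_ratio, ", Fr = ", x$froude,
      if (is.null(x$friction_map)) ", uniform substrate"
      else paste0(", ", length(x$friction_map$primitives),
                  " friction primitive(s)"), "\n", sep = "")
  invisible(x)
}

#' Froude number from dimensional parameters
#'
#' \eqn{Fr = (L/\tau^2)/(g \mu_f)} for a body of length `L` (m),
#' undulation period `tau` (s), gravitational acceleration `g` (m/s^2),
#' and forward friction coefficient `mu_f`.
#'
#' @param L body length in metres.
#' @param tau undulation period in seconds.
#' @param mu_f forward friction coefficient.
#' @param g gravitational acceleration (default 9.81 m/s^2).
#' @return The dimensionless Froude number.
#' @examples
#' froude_number(L = 0.35, tau = 2, mu_f = 0.089)
#' @export
froude_number <- function(L, tau, mu_f, g = 9.81) {
  (L / tau^2) / (g * mu_f)
}

#' Regularized sliding direction
#'
#' \eqn{u = v/\sqrt{|v|^2 + \delta^2}}: a smooth, bounded (`|u| <= 1`)
#' stand-in for the Coulomb direction \eqn{v/|v|}, exact in the limit
#' \eqn{|v| \gg \delta} and vanishing at rest.
#'
#' @param v velocity: a 2-vector or an n x 2 matrix of row vectors.
#' @param delta regularization scale (> 0).
#' @return Same shape as `v`.
#' @export
regularized_direction <- function(v, delta) {
  if (delta <= 0) stop("'delta' must be > 0")
  if (is.matrix(v)) v / sqrt(rowSums(v^2) + delta^2)
  else v / sqrt(sum(v^2) + delta^2)
}

#' Anisotropic Coulomb friction coefficient vector
#'
#' Decomposes the sliding direction `u` in the local body frame and
#' applies direction-dependent coefficients:
#' \deqn{\mu = \frac{\mu_t}{\mu_f}(u\cdot n)\,n +
#'   \left[H(u\cdot t) + \frac{\mu_b}{\mu_f}(1 - H(u\cdot t))\right]
#'   (u\cdot t)\,t}
#' with Heaviside \eqn{H(x) = (1 + \mathrm{sgn}\,x)/2}, so forward sliding
#' (positive tangential component, toward the head) sees coefficient 1,
#' backward sliding sees \eqn{\mu_b/\mu_f}, and transverse sliding
#' \eqn{\mu_t/\mu_f}.  At exactly zero tangential velocity the two
#' coefficients are averaged (\eqn{H(0) = 1/2}).
#'
#' @param u sliding direction(s): 2-vector or n x 2 matrix (need not be
#'   unit length; typically from [regularized_direction()]).
#' @param t_hat,n_hat unit tangent/normal vectors, same shape as `u`;
#'   must be orthonormal to within 1e-9.
#' @param env an [environment_params()].
#' @return Friction coefficient vector(s), same shape as `u`, in units of
#'   \eqn{\mu_f}.
#' @export
friction_coefficient_vector <- function(u, t_hat, n_hat, env) {
  vec <- !is.matrix(u)
  if (vec) {
    u <- rbind(u); t_hat <- rbind(t_hat); n_hat <- rbind(n_hat)
  }
  bad <- abs(rowSums(t_hat^2) - 1) > 1e-9 |
    abs(rowSums(n_hat^2) - 1) > 1e-9 |
    abs(rowSums(t_hat * n_hat)) > 1e-9
  if (any(bad))
    stop("'t_hat' and 'n_hat' must be orthonormal unit vectors")
  ut <- rowSums(u * t_hat)
  un <- rowSums(u * n_hat)
  coef <- ifelse(ut > 0, 1,
                 ifelse(ut < 0, env$mu_b_ratio, (1 + env$mu_b_ratio) / 2))
  out <- env$mu_t_ratio * un * n_hat + coef * ut * t_hat
  if (vec) out[1, ] else out
}

#' Normalized weight distribution
#'
#' Rescales the raw lifting wave \eqn{\hat N \ge 0} so the body's total
#' weight is conserved: \eqn{N = \eta \hat N} with
#' \eqn{\eta = 1/\int_0^1 \hat N\,ds}.  The normalization is recomputed
#' at every evaluation time, which keeps weight conservation exact even
#' for non-integer wavenumber ratios where \eqn{\int \hat N\,ds} varies
#' with time.
#'
#' @param Nhat nonnegative samples of the raw lifting wave on the grid.
#' @param grid a [body_grid()].
#' @return Samples of `N` whose quadrature integral over `s` is 1.
#' @export
normalized_weight <- function(Nhat, grid) {
  if (any(Nhat < 0)) stop("'Nhat' must be nonnegative")
  intN <- quad_mean(Nhat, grid)  # weights sum to 1 over unit length
  if (!(intN > 1e-12))
    stop("degenerate lifting wave: the whole body is lifted ",
         "(weight integral is zero)")
  Nhat / intN
}

#' Coulomb friction force density along the body
#'
#' \eqn{F(s) = -N(s)\,p(x(s))\,\mu(u(s), t(s), n(s))}: the normalized
#' weight times the local substrate scale times the anisotropic friction
#' coefficient vector, opposing the (regularized) sliding direction.
#'
#' @param config a [reconstruct_configuration()] result.
#' @param N normalized weight samples (see [normalized_weight()]).
#' @param env an [environment_params()]; its `friction_map`, if any,
#'   supplies the local scale field.
#' @return An n x 2 matrix of force densities (nondimensional, scaled by
#'   \eqn{\rho g \mu_f}).
#' @export
friction_force_density <- function(config, N, env) {
  if (length(N) != length(config$s))
    stop("'N' must be sampled on the same grid as 'config'")
  u <- regularized_direction(config$velocities, env$velocity_reg)
  mu <- friction_coefficient_vector(u, config$tangents, config$normals, env)
  p <- local_scale(config$positions, env$friction_map)
  -(N * p) * mu
}
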