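#' Gait parameters: lateral and lifting traveling waves
#'
#' The actuation template consists of a lateral curvature wave
#' \eqn{\kappa(s,t) = \epsilon \cos(2\pi k (s+t))} and a lifting
#' (weight-redistribution) wave
#' \eqn{\hat N(s,t) = \max\{0, A \cos(2\pi k_l (s+t+\Phi)) + 1\}}
#' with \eqn{k_l = \lambda k}.  Arclength \eqn{s \in [0,1]} runs tail to
#' head; time is in undulation periods.  The lifting wave modulates the
#' local normal force: \eqn{A = 0} (or `lifting_model = "none"`) recovers
#' planar gaits, \eqn{\lambda = 2} lifts both sides of the body
#' symmetrically, and \eqn{\lambda = 1} lifts one side only, which is the
#' asymmetric pattern seen in sidewinders.  The `max` clip prevents
#' negative weight.  An alternative model `"exp_curvature"`,
#' \eqn{\hat N = e^{-\kappa}}, ties lifting to regions of high lateral
#' curvature (the classic forward-slithering stereotype); its
#' proportionality constant is irrelevant because the wave is renormalized
#' to unit integral (see [normalized_weight()]).
#'
#' @param epsilon lateral curvature amplitude (dimensionless; default 7).
#' @param k lateral wavenumber, waves per body length (> 0; default 1).
#' @param A lifting amplitude (dimensionless, may be negative).
#' @param phi lifting phase offset \eqn{\Phi}, fraction of a period in
#'   `[0, 1)`.
#' @param lam wavenumber ratio \eqn{\lambda = k_l/k} (>= 0; default 1).
#' @param lifting_model one of `"cosine"`, `"exp_curvature"`, `"none"`.
#' @return An object of class `gait_params`.
#' @examples
#' g <- gait_params(A = 1, phi = 0.25)
#' lateral_curvature(0, 0, g)
#' @export
gait_params <- function(epsilon = 7, k = 1, A = 0, phi = 0, lam = 1,
                        lifting_model = c("cosine", "exp_curvature", "none")) {
  lifting_model <- match.arg(lifting_model)
  for (nm in c("epsilon", "k", "A", "phi", "lam")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("gait parameter '", nm, "' must be a finite numeric scalar")
  }
  if (k <= 0) stop("wavenumber 'k' must be > 0")
  if (lam < 0) stop("wavenumber ratio 'lam' must be >= 0")
  if (phi < 0 || phi >= 1) stop("phase offset 'phi' must lie in [0, 1)")
  structure(list(epsilon = epsilon, k = k, A = A, phi = phi, lam = lam,
                 lifting_model = lifting_model),
            class = "gait_params")
}

#' @export
print.gait_params <- function(x, ...) {
  cat("Gait: kappa = ", x$epsilon, " cos(2*pi*", x$k, "*(s+t)); lifting ",
      x$lifting_model, " (A = ", x$A, ", phi = ", x$phi, ", lambda = ",
      x$lam, ")\n", sep = "")
  invisible(x)
}

#' Lateral curvature wave
#'
#' Evaluates \eqn{\kappa(s,t) = \epsilon \cos(2\pi k(s+t))}.  The wave is
#' periodic in `t` with period 1 and travels head-to-tail in the body
#' frame: \eqn{\kappa(s, t) = \kappa(s+\delta, t-\delta)}.
#'
#' @param s arclength in `[0, 1]` (vectorized).
#' @param t time in periods (vectorized).
#' @param gait a [gait_params()] object.
#' @return Curvature values (dimensionless).
#' @export
lateral_curvature <- function(s, t, gait) {
  gait$epsilon * cos(2 * pi * gait$k * (s + t))
}

#' Time derivatives of the lateral curvature wave
#'
#' Closed forms \eqn{\kappa_t = -2\pi k \epsilon \sin(2\pi k(s+t))} and
#' \eqn{\kappa_{tt} = -(2\pi k)^2 \kappa}, needed by the angular equation
#' of motion.
#'
#' @inheritParams lateral_curvature
#' @return A list with components `kappa_t` and `kappa_tt`.
#' @export
curvature_time_derivatives <- function(s, t, gait) {
  tpk <- 2 * pi * gait$k
  ph <- tpk * (s + t)
  list(kappa_t = -tpk * gait$epsilon * sin(ph),
       kappa_tt = -tpk^2 * gait$epsilon * cos(ph))
}

#' Lifting (weight-redistribution) wave
#'
#' Evaluates the raw lifting modulation \eqn{\hat N(s,t) \ge 0} before
#' normalization.  For the cosine model,
#' \eqn{\hat N = \max\{0, A\cos(2\pi \lambda k (s+t+\Phi)) + 1\}}; with
#' `|A| <= 1` the clip never engages.  `"exp_curvature"` gives
#' \eqn{e^{-\kappa(s,t)}} and `"none"` gives 1 everywhere.
#'
#' @inheritParams lateral_curvature
#' @return Nonnegative modulation values.
#' @export
lifting_modulation <- function(s, t, gait) {
  switch(gait$lifting_model,
    none = rep(1, length(s + t)),
    cosine = pmax(0, gait$A * cos(2 * pi * gait$lam * gait$k *
                                    (s + t + gait$phi)) + 1),
    exp_curvature = exp(-lateral_curvature(s, t, gait)))
}
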