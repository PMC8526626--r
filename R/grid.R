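#' Arclength grid with trapezoidal quadrature
#'
#' Discretizes the body arclength \eqn{s \in [0,1]} (tail at 0, head at 1)
#' on `n_s` uniform nodes.  Quadrature weights are trapezoidal and sum to
#' 1, so `sum(grid$weights * f)` is the quadrature mean of `f` over the
#' unit-length body.
#'
#' @param n_s number of nodes (>= 3; default 201).
#' @return An object of class `body_grid` with fields `n_s`, `s`,
#'   `weights`.
#' @export
body_grid <- function(n_s = 201) {
  if (!is.numeric(n_s) || length(n_s) != 1L || n_s < 3)
    stop("a body grid needs at least 3 nodes")
  n_s <- as.integer(n_s)
  h <- 1 / (n_s - 1)
  w <- c(h / 2, rep(h, n_s - 2), h / 2)
  structure(list(n_s = n_s, s = seq(0, 1, length.out = n_s), weights = w),
            class = "body_grid")
}

#' @export
print.body_grid <- function(x, ...) {
  cat("Arclength grid: ", x$n_s, " nodes on [0, 1], trapezoidal weights\n",
      sep = "")
  invisible(x)
}

# quadrature mean over the body (weights sum to 1)
quad_mean <- function(f, grid) {
  if (is.matrix(f)) as.vector(crossprod(grid$weights, f))
  else sum(grid$weights * f)
}

#' Mean-zero integration operator
#'
#' The reconstruction machinery of the model: \eqn{I[f](s)} is the running
#' integral \eqn{\int_0^s f\,ds'} minus its quadrature mean over the body,
#' so that \eqn{\int_0^1 I[f]\,ds = 0} exactly (by construction, since the
#' same trapezoidal rule is used for both the running integral and the
#' mean).  Positions and orientations follow from the centre of mass and
#' mean orientation as \eqn{x = \bar x + I[\mathbf{t}]} and
#' \eqn{\alpha = \bar\alpha + I[\kappa]}.
#'
#' @param f samples on the grid nodes: a vector, or a matrix with one
#'   column per component of a vector field.
#' @param grid a [body_grid()].
#' @return Samples of \eqn{I[f]}, same shape as `f`.
#' @export
mean_zero_integral <- function(f, grid) {
  if (grid$n_s < 3) stop("a body grid needs at least 3 nodes")
  vec <- !is.matrix(f)
  fm <- if (vec) matrix(f, ncol = 1) else f
  if (nrow(fm) != grid$n_s) stop("'f' must be sampled on the grid nodes")
  cum <- pracma::cumtrapz(grid$s, fm)
  out <- sweep(cum, 2, as.vector(crossprod(grid$weights, cum)))
  if (vec) as.vector(out) else out
}
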