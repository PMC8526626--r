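#' Phase-space sweep over lifting amplitude and phase offset
#'
#' Runs one simulation per grid point of `(A, Phi)` at fixed friction
#' ratio and collects the steady-state metric fields and behaviour
#' labels, plus the zero-level separatrices of steering rate and pose
#' angle that organize the phase diagram.  Cells whose simulation fails
#' are flagged and labelled `transition`; a failure never aborts the
#' sweep.  Cells are independent and the result is deterministic.
#'
#' @param A_values,phi_values axis values (defaults: 41 points over
#'   `[-2, 2]` and `[0, 1]`; desk-scale counterparts of the dense
#'   published maps).
#' @param gait gait template ([gait_params()]); its `A` and `phi` are
#'   overridden cell by cell.
#' @param env an [environment_params()].
#' @param sim a [sim_config()]; the sweep default uses a lighter grid and
#'   tolerance than single-run studies (101 nodes, rtol 1e-6), which
#'   changes the metrics by well under the classifier bands.
#' @param cfg a [classifier_config()].
#' @param verbose print per-row progress to stderr.
#' @return An object of class `phase_map`: axes, metric field matrices
#'   (`theta_dot`, `gamma`, `v_eff`), `label` and `flags` matrices,
#'   `separatrices` (zero contours), and the input objects as metadata.
#' @export
sweep_phase_map <- function(A_values = seq(-2, 2, length.out = 41),
                            phi_values = seq(0, 1, length.out = 41),
                            gait = gait_params(),
                            env = environment_params(),
                            sim = sim_config(n_s = 101, rtol = 1e-6,
                                             atol = 1e-8,
                                             samples_per_period = 100),
                            cfg = classifier_config(),
                            verbose = FALSE) {
  nA <- length(A_values); nP <- length(phi_values)
  th <- ga <- ve <- matrix(NA_real_, nA, nP)
  lab <- matrix("transition", nA, nP)
  flags <- matrix("", nA, nP)
  for (i in seq_len(nA)) {
    for (j in seq_len(nP)) {
      g <- gait
      g$A <- A_values[i]
      g$phi <- phi_values[j] %% 1
      res <- tryCatch({
        traj <- simulate_snake(g, env, sim)
        gait_metrics(traj, cfg = cfg)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        flags[i, j] <- conditionMessage(res)
      } else {
        th[i, j] <- res$theta_dot
        ga[i, j] <- res$gamma
        ve[i, j] <- res$v_eff
        lab[i, j] <- res$label
      }
    }
    if (verbose)
      message("phase map row ", i, "/", nA, " (A = ", A_values[i], ")")
  }
  structure(list(A = A_values, phi = phi_values,
                 mu_t_ratio = env$mu_t_ratio,
                 theta_dot = th, gamma = ga, v_eff = ve,
                 label = lab, flags = flags,
                 separatrices = list(
                   theta_dot = zero_contours(A_values, phi_values, th),
                   gamma = zero_contours(A_values, phi_values, ga)),
                 gait = gait, env = env, sim = sim, classifier = cfg),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat("Phase map (", length(x$A), " x ", length(x$phi),
      ") at mu_t/mu_f = ", x$mu_t_ratio, "\n", sep = "")
  print(table(factor(x$label)))
  invisible(x)
}

#' Zero-level contours of a gridded field
#'
#' Marching-squares zero contours with linear interpolation (via
#' `grDevices::contourLines`).  An all-positive or all-negative field
#' yields an empty list.
#'
#' @param x,y axis values (strictly increasing).
#' @param z field matrix, `length(x)` rows by `length(y)` columns; cells
#'   with non-finite values are skipped.
#' @param level contour level (default 0).
#' @return A list of polylines, each a list with `x` and `y` vertex
#'   vectors.
#' @export
zero_contours <- function(x, y, z, level = 0) {
  if (all(!is.finite(z))) return(list())
  rng <- range(z, na.rm = TRUE)
  if (rng[1] > level || rng[2] < level) return(list())
  cl <- grDevices::contourLines(x = x, y = y, z = z, levels = level)
  lapply(cl, function(p) list(x = p$x, y = p$y))
}

#' Behaviour profiles across friction ratios
#'
#' Simulates a set of lifting strategies over a range of transverse
#' friction ratios and tabulates effective speed, steering rate, and
#' pose angle for each combination.  The default strategies are the four
#' stereotypes: no lifting (planar), symmetric lifting (wavenumber ratio
#' 2), asymmetric lifting (ratio 1, phase offset 1/4; the sidewinding
#' template), and curvature-tied lifting (\eqn{e^{-\kappa}}).
#'
#' @param strategies named list of [gait_params()] objects.
#' @param ratios transverse friction ratios \eqn{\mu_t/\mu_f} to scan.
#' @param env base [environment_params()]; `mu_t_ratio` is overridden.
#' @param sim a [sim_config()].
#' @param cfg a [classifier_config()].
#' @return A data frame with one row per (strategy, ratio): columns
#'   `strategy`, `mu_t_ratio`, `v_eff`, `theta_dot`, `gamma`, `label`,
#'   `converged`.
#' @export
friction_ratio_profiles <- function(
    strategies = list(
      no_lift = gait_params(A = 0),
      symmetric = gait_params(A = 1, phi = 0.25, lam = 2),
      asymmetric = gait_params(A = 1, phi = 0.25, lam = 1),
      exp_curvature = gait_params(lifting_model = "exp_curvature")),
    ratios = c(0.5, 1, 2, 4, 10),
    env = environment_params(),
    sim = sim_config(n_s = 101, rtol = 1e-6, atol = 1e-8,
                     samples_per_period = 100),
    cfg = classifier_config()) {
  rows <- list()
  for (nm in names(strategies)) {
    for (r in ratios) {
      e <- env
      e$mu_t_ratio <- r
      res <- tryCatch({
        traj <- simulate_snake(strategies[[nm]], e, sim)
        gait_metrics(traj, cfg = cfg)
      }, error = function(err) err)
      rows[[length(rows) + 1]] <- if (inherits(res, "error"))
        data.frame(strategy = nm, mu_t_ratio = r, v_eff = NA_real_,
                   theta_dot = NA_real_, gamma = NA_real_,
                   label = "failed", converged = NA)
      else
        data.frame(strategy = nm, mu_t_ratio = r, v_eff = res$v_eff,
                   theta_dot = res$theta_dot, gamma = res$gamma,
                   label = res$label, converged = res$converged)
    }
  }
  do.call(rbind, rows)
}
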