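# Serialization: CSV writers with a JSON metadata sidecar.  All numeric
# CSV content is formatted with %.12g so identical configurations give
# byte-identical numeric output; writes are atomic (tempfile + rename).

fmt_num_df <- function(df, digits = "%.12g") {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf(digits, df[[nm]])
  df
}

atomic_write_csv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

# full resolved parameter set for provenance
run_metadata <- function(...) {
  objs <- list(...)
  meta <- lapply(objs, function(o) {
    if (inherits(o, "environment_params")) {
      o <- unclass(o)
      o$friction_map <- if (is.null(o$friction_map)) NULL else
        lapply(o$friction_map$primitives, function(p) {
          p <- unclass(p)
          if (!is.null(p$values)) p$values <- as.vector(p$values)
          p
        })
      o
    } else if (is.list(o)) unclass(o) else o
  })
  meta$package <- "frictiongait"
  meta$version <- as.character(utils::packageVersion("frictiongait"))
  meta
}

write_metadata <- function(meta, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a trajectory to CSV with a metadata sidecar
#'
#' Columns `t, x, y, alpha_bar, vx, vy, alpha_bar_t`; a
#' `<path>.meta.json` sidecar records the full resolved parameter set.
#'
#' @param traj a [simulate_snake()] trajectory.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$time, x = traj$x, y = traj$y,
                   alpha_bar = traj$alpha, vx = traj$vx, vy = traj$vy,
                   alpha_bar_t = traj$alpha_t)
  atomic_write_csv(fmt_num_df(df), path)
  write_metadata(run_metadata(gait = attr(traj, "gait"),
                              env = attr(traj, "env"),
                              sim = attr(traj, "sim")),
                 paste0(path, ".meta.json"))
  invisible(path)
}

#' Write a phase map as long-form CSV plus contour vertices
#'
#' Writes `<prefix>_map.csv` (columns `A, Phi, theta_dot, gamma, v_eff,
#' label, flag`), `<prefix>_contours.csv` (contour id, field, vertex
#' coordinates), and `<prefix>_meta.json`.
#'
#' @param pm a [sweep_phase_map()] result.
#' @param prefix output path prefix.
#' @return The map CSV path, invisibly.
#' @export
write_phase_map <- function(pm, prefix) {
  long <- expand.grid(i = seq_along(pm$A), j = seq_along(pm$phi))
  df <- data.frame(A = pm$A[long$i], Phi = pm$phi[long$j],
                   theta_dot = pm$theta_dot[cbind(long$i, long$j)],
                   gamma = pm$gamma[cbind(long$i, long$j)],
                   v_eff = pm$v_eff[cbind(long$i, long$j)],
                   label = pm$label[cbind(long$i, long$j)],
                   flag = pm$flags[cbind(long$i, long$j)])
  atomic_write_csv(fmt_num_df(df), paste0(prefix, "_map.csv"))
  crows <- list()
  for (fld in names(pm$separatrices)) {
    cs <- pm$separatrices[[fld]]
    for (k in seq_along(cs))
      crows[[length(crows) + 1]] <-
        data.frame(field = fld, contour = k, A = cs[[k]]$x,
                   Phi = cs[[k]]$y)
  }
  cdf <- if (length(crows)) do.call(rbind, crows) else
    data.frame(field = character(), contour = integer(),
               A = numeric(), Phi = numeric())
  atomic_write_csv(fmt_num_df(cdf), paste0(prefix, "_contours.csv"))
  write_metadata(run_metadata(gait = pm$gait, env = pm$env, sim = pm$sim,
                              classifier = pm$classifier,
                              A = pm$A, phi = pm$phi),
                 paste0(prefix, "_meta.json"))
  invisible(paste0(prefix, "_map.csv"))
}

#' Write a single-run metrics row to CSV
#'
#' One row per run with all gait/environment parameters, the metrics,
#' the behaviour label, and the convergence flag.
#'
#' @param metrics a [gait_metrics()] result.
#' @param traj the trajectory the metrics came from.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_metrics <- function(metrics, traj, path) {
  g <- attr(traj, "gait"); e <- attr(traj, "env")
  df <- data.frame(epsilon = g$epsilon, k = g$k, A = g$A, phi = g$phi,
                   lam = g$lam, lifting_model = g$lifting_model,
                   mu_t_ratio = e$mu_t_ratio, mu_b_ratio = e$mu_b_ratio,
                   froude = e$froude, gamma = metrics$gamma,
                   theta_dot = metrics$theta_dot, v_eff = metrics$v_eff,
                   label = metrics$label,
                   converged = isTRUE(metrics$converged))
  atomic_write_csv(fmt_num_df(df), path)
  invisible(path)
}

#' Write ensemble deflection results
#'
#' `<prefix>_deflections.csv` (offset, deflection angle, flags) and
#' `<prefix>_pdf.csv` (binned density), plus a metadata sidecar.
#'
#' @param result a [run_ensemble()] result.
#' @param prefix output path prefix.
#' @param bin_width_deg histogram bin width in degrees.
#' @return The deflections CSV path, invisibly.
#' @export
write_deflections <- function(result, prefix, bin_width_deg = 5) {
  atomic_write_csv(fmt_num_df(as.data.frame(result)),
                   paste0(prefix, "_deflections.csv"))
  atomic_write_csv(fmt_num_df(deflection_pdf(result, bin_width_deg)),
                   paste0(prefix, "_pdf.csv"))
  spec <- attr(result, "spec")
  write_metadata(run_metadata(gait = spec$gait, env = spec$env,
                              sim = spec$sim, offsets = spec$offsets,
                              heading = spec$heading, start = spec$start),
                 paste0(prefix, "_meta.json"))
  invisible(paste0(prefix, "_deflections.csv"))
}
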