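#' Heterogeneous friction landscapes
#'
#' A `friction_map` is an ordered list of geometric primitives, each
#' carrying a multiplicative scale applied to the whole friction
#' coefficient vector of any body node inside it.  Outside all primitives
#' the scale is 1 (the background substrate).  Where primitives overlap,
#' the *last listed* wins — a deterministic, documented rule.  A scale of
#' 0 is allowed (frictionless regions); negative scales are rejected.
#' This is the planar reduction of substrate features: solid posts become
#' high-friction patches, polished strips become low/zero-friction bands,
#' and mounds/valleys become radial friction gradients.
#'
#' @param ... primitives built with [disk()], [strip()],
#'   [radial_gradient()], [raster_map()], or lists thereof.
#' @return An object of class `friction_map`.
#' @examples
#' m <- friction_map(disk(c(3, 0), diameter = 0.4, scale = 50),
#'                   strip(c(5, 0), angle = pi / 2, width = 0.3, scale = 0))
#' local_scale(rbind(c(0, 0), c(3, 0), c(5, 0)), m)
#' @export
friction_map <- function(...) {
  prims <- list(...)
  # flatten lists of primitives (e.g. disk_row() output)
  flat <- list()
  for (p in prims) {
    if (inherits(p, "friction_primitive")) flat[[length(flat) + 1]] <- p
    else if (is.list(p)) for (q in p) {
      if (!inherits(q, "friction_primitive"))
        stop("friction_map() accepts only friction primitives")
      flat[[length(flat) + 1]] <- q
    } else stop("friction_map() accepts only friction primitives")
  }
  structure(list(primitives = flat), class = "friction_map")
}

#' @export
print.friction_map <- function(x, ...) {
  cat("Friction map with", length(x$primitives), "primitive(s):\n")
  for (p in x$primitives) cat("  -", p$type, "scale", format(p$scale), "\n")
  invisible(x)
}

new_primitive <- function(type, scale, ...) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale < 0)
    stop("primitive 'scale' must be a nonnegative number")
  structure(c(list(type = type, scale = scale), list(...)),
            class = "friction_primitive")
}

#' @rdname friction_map
#' @param center,anchor lab-frame 2-vector (body lengths).
#' @param diameter disk or lens diameter (body lengths, > 0).
#' @param scale friction scale inside the primitive (>= 0); for
#'   `radial_gradient` the scale at the centre (the rim blends to 1).
#' @export
disk <- function(center, diameter, scale) {
  if (diameter <= 0) stop("'diameter' must be > 0")
  new_primitive("disk", scale, center = as.numeric(center),
                diameter = diameter)
}

#' @rdname friction_map
#' @param angle strip direction angle (radians); the strip is the set of
#'   points within `width/2` of the line through `anchor` along `angle`.
#' @param width strip width (body lengths, > 0).
#' @export
strip <- function(anchor, angle, width, scale) {
  if (width <= 0) stop("'width' must be > 0")
  new_primitive("strip", scale, anchor = as.numeric(anchor),
                angle = angle, width = width)
}

#' @rdname friction_map
#' @param profile radial blending profile; only `"linear"` (scale at the
#'   centre, 1 at the rim, linear in radius) is implemented.
#' @export
radial_gradient <- function(center, diameter, scale, profile = "linear") {
  profile <- match.arg(profile)
  if (diameter <= 0) stop("'diameter' must be > 0")
  new_primitive("radial_gradient", scale, center = as.numeric(center),
                diameter = diameter, profile = profile)
}

#' @rdname friction_map
#' @param origin lab-frame position of the centre of cell `[1, 1]`.
#' @param cell_size cell edge lengths, scalar or 2-vector `(hx, hy)`.
#' @param values numeric matrix of scales; `values[i, j]` covers the cell
#'   `i` steps along x and `j` steps along y from `origin` (nearest-cell
#'   lookup).  Points outside the raster keep the background scale.
#' @export
raster_map <- function(origin, cell_size, values) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("raster 'values' must be finite and nonnegative")
  cell_size <- rep_len(as.numeric(cell_size), 2)
  if (any(cell_size <= 0)) stop("'cell_size' must be > 0")
  new_primitive("raster", scale = 1, origin = as.numeric(origin),
                cell_size = cell_size, values = values)
}

#' Local friction scale lookup
#'
#' Returns the multiplicative friction scale at lab-frame points: the
#' scale of the last listed primitive containing each point, or 1 when no
#' primitive contains it (or when `map` is `NULL`).
#'
#' @param points a 2-vector or an n x 2 matrix of lab positions.
#' @param map a [friction_map()] or `NULL`.
#' @return Numeric vector of scales, one per point.
#' @export
local_scale <- function(points, map) {
  pts <- if (is.matrix(points)) points else rbind(points)
  out <- rep(1, nrow(pts))
  if (is.null(map)) return(out)
  for (p in map$primitives) {
    switch(p$type,
      disk = {
        d2 <- (pts[, 1] - p$center[1])^2 + (pts[, 2] - p$center[2])^2
        out[d2 <= (p$diameter / 2)^2] <- p$scale
      },
      strip = {
        nv <- c(-sin(p$angle), cos(p$angle))
        d <- abs((pts[, 1] - p$anchor[1]) * nv[1] +
                   (pts[, 2] - p$anchor[2]) * nv[2])
        out[d <= p$width / 2] <- p$scale
      },
      radial_gradient = {
        r <- sqrt((pts[, 1] - p$center[1])^2 + (pts[, 2] - p$center[2])^2)
        R <- p$diameter / 2
        ins <- r <= R
        out[ins] <- p$scale + (1 - p$scale) * (r[ins] / R)
      },
      raster = {
        ix <- floor((pts[, 1] - p$origin[1]) / p$cell_size[1] + 0.5) + 1
        iy <- floor((pts[, 2] - p$origin[2]) / p$cell_size[2] + 0.5) + 1
        ins <- ix >= 1 & ix <= nrow(p$values) & iy >= 1 &
          iy <= ncol(p$values)
        out[ins] <- p$values[cbind(ix[ins], iy[ins])]
      })
  }
  out
}

# encode a friction_map into the plain list form the C++ core consumes
map_to_core <- function(map) {
  if (is.null(map)) return(list())
  lapply(map$primitives, function(p) {
    switch(p$type,
      disk = list(type = 1L, par = c(p$center, p$diameter, p$scale, 0, 0)),
      strip = list(type = 2L,
                   par = c(p$anchor, p$angle, p$width, p$scale, 0)),
      radial_gradient = list(type = 3L,
                             par = c(p$center, p$diameter, p$scale, 0, 0)),
      raster = list(type = 4L,
                    par = c(p$origin, p$cell_size, 0, 0),
                    values = p$values))
  })
}
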