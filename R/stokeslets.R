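#' Collection of regularized point forces
#'
#' Bundles force application points with the force vectors they exert on the
#' fluid.  Forces are per-unit-depth forces (pN/um in physical units), i.e.
#' contour force densities already multiplied by their reference spacing.
#'
#' @param locations numeric n x 2 matrix of points (cell-diameter units).
#' @param forces numeric n x 2 matrix of force vectors.
#' @return an object of class `point_forces`.
#' @export
point_forces <- function(locations, forces) {
  locations <- as_xy_matrix(locations, "locations")
  forces <- as_xy_matrix(forces, "forces")
  if (nrow(locations) != nrow(forces))
    stop("locations and forces must have the same number of rows")
  if (!all(is.finite(locations)) || !all(is.finite(forces)))
    stop("locations and forces must be finite")
  structure(list(locations = locations, forces = forces),
            class = "point_forces")
}

#' Stokes-flow solution generated by regularized point forces
#'
#' Represents the free-space Stokes flow driven by a set of point forces,
#' each smoothed over a blob of width `epsilon`.  Velocity and pressure can
#' be evaluated anywhere (including at the force points) with
#' [velocity_at()] and [pressure_at()].
#'
#' @param source a [point_forces()] object.
#' @param epsilon regularization width (cell diameters), > 0.
#' @param viscosity fluid viscosity, > 0 (normalized to 1 in simulations).
#' @param cutoff outer screening length of the 2D log kernel (the distance
#'   at which the flow of a single point force is taken to vanish).  The
#'   2D Stokeslet velocity is defined only up to an additive constant per
#'   unit force; fixing the constant through a screening length larger
#'   than the simulation domain (default 10 cell diameters) makes every
#'   force drag fluid along its own direction throughout the domain.
#' @return an object of class `fluid_solution`.
#' @export
fluid_solution <- function(source, epsilon, viscosity = 1, cutoff = 10) {
  if (!inherits(source, "point_forces")) source <- do.call(point_forces, source)
  check_epsilon(epsilon)
  if (!is.numeric(viscosity) || length(viscosity) != 1 || viscosity <= 0)
    stop("viscosity must be a positive scalar")
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0)
    stop("cutoff must be a positive scalar")
  structure(list(source = source, epsilon = epsilon, viscosity = viscosity,
                 cutoff = cutoff),
            class = "fluid_solution")
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || !is.finite(epsilon) ||
      epsilon <= 0)
    stop("epsilon must be a positive finite scalar")
  invisible(epsilon)
}

as_xy_matrix <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) == 2) x <- matrix(x, 1, 2)
    else stop(sprintf("%s must be an n x 2 matrix", what))
  }
  x <- as.matrix(x)
  if (ncol(x) != 2) stop(sprintf("%s must be an n x 2 matrix", what))
  storage.mode(x) <- "double"
  x
}

#' Fluid velocity at target points
#'
#' Superposes the regularized-Stokeslet velocity of every source force at
#' each target.  The field is finite everywhere, including at the source
#' points themselves, and is linear in the forces.
#'
#' @param solution a [fluid_solution()].
#' @param targets numeric m x 2 matrix of evaluation points.
#' @return m x 2 matrix of velocities.
#' @export
velocity_at <- function(solution, targets) {
  targets <- as_xy_matrix(targets, "targets")
  if (!all(is.finite(targets))) stop("targets must be finite")
  check_epsilon(solution$epsilon)
  rs_velocity_cpp(solution$source$locations, solution$source$forces,
                  targets, solution$epsilon, solution$viscosity,
                  solution$cutoff)
}

#' Fluid pressure at target points
#'
#' Regularized pressure field of the point forces, with the additive
#' constant fixed by decay at infinity.
#'
#' @inheritParams velocity_at
#' @return numeric vector of pressures (length `nrow(targets)`).
#' @export
pressure_at <- function(solution, targets) {
  targets <- as_xy_matrix(targets, "targets")
  if (!all(is.finite(targets))) stop("targets must be finite")
  check_epsilon(solution$epsilon)
  rs_pressure_cpp(solution$source$locations, solution$source$forces,
                  targets, solution$epsilon)
}

#' Mobility matrix mapping stacked forces to stacked velocities
#'
#' Dense 2n x 2n matrix M such that `M %*% f` (with `f` stacked as
#' x1, y1, x2, y2, ...) equals the velocity at the same points.  M is
#' symmetric and positive semi-definite.
#'
#' @param locations n x 2 matrix of points.
#' @param epsilon regularization width, > 0.
#' @param viscosity fluid viscosity, > 0.
#' @param cutoff outer screening length (see [fluid_solution()]).
#' @return 2n x 2n numeric matrix.
#' @export
mobility_matrix <- function(locations, epsilon, viscosity = 1, cutoff = 10) {
  locations <- as_xy_matrix(locations, "locations")
  if (nrow(locations) < 1) stop("need at least one location")
  check_epsilon(epsilon)
  rs_mobility_cpp(locations, epsilon, viscosity, cutoff)
}

#' Default blob width for a cortex discretization
#'
#' Half the initial cortex node spacing: `pi * diameter / (2 * n_cortex)`.
#' The same value sets the contact threshold (2 eps), the unbinding
#' displacement (2 eps), the geometry-ejection kick (eps) and the
#' equilibrium speed threshold (eps).
#'
#' @param n_cortex number of cortex nodes.
#' @param diameter resting cell diameter (default 1).
#' @return blob width (cell diameters).
#' @export
default_epsilon <- function(n_cortex, diameter = 1) {
  pi * diameter / (2 * n_cortex)
}

#' Sample velocity, pressure and speed on a rectangular grid
#'
#' Produces the gridded fields used for flow-map figures: columns
#' x, y, u, v, p, speed.
#'
#' @param solution a [fluid_solution()].
#' @param xlim,ylim grid extents, length-2 numerics.
#' @param n number of grid points per axis (default 100).
#' @return data.frame with columns x, y, u, v, p, speed.
#' @export
field_map <- function(solution, xlim, ylim, n = 100) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  pts <- cbind(g$x, g$y)
  u <- velocity_at(solution, pts)
  p <- pressure_at(solution, pts)
  data.frame(x = g$x, y = g$y, u = u[, 1], v = u[, 2], p = p,
             speed = sqrt(u[, 1]^2 + u[, 2]^2))
}

#' Write a field map as a delimited table
#'
#' @param fields data.frame from [field_map()].
#' @param path output file path (tab-separated).
#' @export
write_field_map <- function(fields, path) {
  write.table(fields, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
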