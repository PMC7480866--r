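#' Closed elastic contour (cortex or nucleus)
#'
#' A closed polygonal curve with a current configuration, a reference
#' configuration defining the rest arclength, per-node tension stiffness
#' and tangent rest length, and an optional bending rigidity.  Index
#' arithmetic is modulo N (node N is adjacent to node 1).
#'
#' The tension along segment m (between nodes m and m+1) is
#' `T_m = k_m (||tau_m|| - r_m)` where `tau_m` is the tangent with respect
#' to reference arclength; the elastic force density is the centered
#' difference of `T tau` back onto the nodes.
#'
#' @param x numeric N x 2 matrix of current node positions.
#' @param ref numeric N x 2 matrix of reference positions (defaults to `x`).
#' @param k per-node tension stiffness (recycled), > 0.
#' @param r per-node tangent rest length (recycled), in (0, 1].
#' @param Kb bending rigidity, >= 0 (0 disables bending).
#' @return an object of class `contour`.
#' @export
contour <- function(x, ref = x, k = 1, r = 1, Kb = 0) {
  x <- as_xy_matrix(x, "x"); ref <- as_xy_matrix(ref, "ref")
  n <- nrow(x)
  if (n < 3) stop("a contour needs at least 3 nodes")
  if (nrow(ref) != n) stop("ref must match x in size")
  k <- rep_len(as.numeric(k), n); r <- rep_len(as.numeric(r), n)
  if (any(k <= 0)) stop("stiffness k must be positive")
  if (any(r <= 0 | r > 1)) stop("rest length r must be in (0, 1]")
  if (length(Kb) != 1 || Kb < 0) stop("Kb must be a scalar >= 0")
  obj <- list(x = x, ref = ref, k = k, r = r, Kb = Kb)
  class(obj) <- "contour"
  obj
}

#' Equispaced circular contour
#'
#' @param n number of nodes.
#' @param radius circle radius.
#' @param center length-2 center.
#' @param k,r,Kb see [contour()].
#' @export
circle_contour <- function(n, radius = 0.5, center = c(0, 0), k = 1, r = 1,
                           Kb = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  x <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  contour(x, x, k = k, r = r, Kb = Kb)
}

# reference spacing of segment m = |ref[m+1] - ref[m]| (wrapped)
seg_ref_spacing <- function(ref) {
  n <- nrow(ref)
  ip1 <- c(2:n, 1)
  d <- ref[ip1, , drop = FALSE] - ref
  sqrt(d[, 1]^2 + d[, 2]^2)
}

# reference spacing attributed to node m (midpoint rule)
node_ref_spacing <- function(ref) {
  ds <- seg_ref_spacing(ref)
  n <- length(ds)
  im1 <- c(n, seq_len(n - 1))
  (ds + ds[im1]) / 2
}

#' Segment tensions of a contour
#'
#' `T_m = k_m (||tau_m|| - r_m)` on the segment joining nodes m and m+1,
#' with the tangent `tau_m` taken with respect to reference arclength and
#' stiffness/rest length averaged onto the segment midpoint.
#'
#' @param contour a [contour()].
#' @return numeric vector of per-segment tensions (segment m joins m, m+1).
#' @export
tension <- function(contour) {
  with_segments(contour)$Tension
}

# shared segment geometry; errors on degenerate (coincident) nodes
with_segments <- function(cont) {
  x <- cont$x; n <- nrow(x)
  ip1 <- c(2:n, 1)
  ds <- seg_ref_spacing(cont$ref)
  if (any(ds <= 0)) stop("degenerate contour segment: coincident reference nodes")
  d <- x[ip1, , drop = FALSE] - x
  len <- sqrt(d[, 1]^2 + d[, 2]^2)
  if (any(len == 0)) stop("degenerate contour segment: coincident nodes")
  tau <- d / ds
  taunorm <- len / ds
  kseg <- (cont$k + cont$k[ip1]) / 2
  rseg <- (cont$r + cont$r[ip1]) / 2
  list(tau = tau, taunorm = taunorm, Tension = kseg * (taunorm - rseg),
       ds = ds)
}

#' Elastic force density on a contour
#'
#' Centered-difference derivative of (tension x tangent) with respect to
#' reference arclength, evaluated back at the nodes.  Has both normal and
#' tangential components; summed against the node spacings the total force
#' telescopes to zero on any closed contour.
#'
#' @param contour a [contour()].
#' @return N x 2 matrix of force densities.
#' @export
elastic_force_density <- function(contour) {
  s <- with_segments(contour)
  n <- nrow(contour$x)
  im1 <- c(n, seq_len(n - 1))
  Ttau <- s$tau * s$Tension
  dsn <- (s$ds + s$ds[im1]) / 2
  (Ttau - Ttau[im1, , drop = FALSE]) / dsn
}

#' Protrusion descriptor
#'
#' A protrusion is centered at cortex node `center` and pushes along the
#' fixed outward direction `normal` with force-density amplitude `f0`; a
#' balancing backward density is spread over all remaining nodes so that
#' the protrusion exerts zero net force on the fluid.
#'
#' @param center node index of the protrusion tip.
#' @param f0 force-density amplitude, > 0.
#' @param normal length-2 outward unit vector at the center node.
#' @return an object of class `protrusion`.
#' @export
protrusion <- function(center, f0, normal) {
  if (f0 <= 0) stop("f0 must be positive")
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (!isTRUE(all.equal(nn, 1, tolerance = 1e-8)))
    stop("normal must be a unit vector")
  structure(list(center = as.integer(center), f0 = f0, normal = normal / nn),
            class = "protrusion")
}

#' Protrusion force density
#'
#' Force density `f0 n` at the center node, `f0 n / 2` at its two
#' neighbours, and `-2 f0 / (N - 3) n` at every other node, all along the
#' fixed direction `n`; the vector sum over the contour is exactly zero.
#'
#' @param contour a [contour()] with at least 5 nodes.
#' @param p a [protrusion()].
#' @return N x 2 matrix of force densities.
#' @export
protrusion_force_density <- function(contour, p) {
  n <- nrow(contour$x)
  if (n <= 4) stop("protrusions require a contour with at least 5 nodes")
  m <- p$center
  amp <- rep(-2 * p$f0 / (n - 3), n)
  amp[m] <- p$f0
  amp[c(wrap_index(m - 1, n), wrap_index(m + 1, n))] <- p$f0 / 2
  cbind(amp * p$normal[1], amp * p$normal[2])
}

wrap_index <- function(i, n) ((i - 1) %% n) + 1

# per-node preferred curvature: second-difference magnitude of the
# reference configuration (the discrete curvature of the reference circle
# when the reference is an equispaced circular polygon); bitwise zero
# bending force at the reference shape itself
preferred_curvature <- function(ref, ds) {
  n <- nrow(ref)
  ip1 <- c(2:n, 1); im1 <- c(n, seq_len(n - 1))
  D2 <- (ref[ip1, , drop = FALSE] - 2 * ref + ref[im1, , drop = FALSE]) / ds^2
  sqrt(D2[, 1]^2 + D2[, 2]^2)
}

#' Bending force density on a contour
#'
#' Variational derivative of a discrete curvature-penalty energy
#' `E = Kb/2 * sum_m (c_m - c0)^2 ds`, where `c_m` is the norm of the
#' second difference of the positions scaled by the mean reference spacing
#' and `c0` its value on the equispaced reference circle (the preferred
#' curvature).  The force vanishes on any rigid motion of the preferred
#' circle and is zero when `Kb = 0`.
#'
#' @param contour a [contour()].
#' @param Kb optional override of the contour's bending rigidity.
#' @return N x 2 matrix of force densities.
#' @export
bending_force_density <- function(contour, Kb = contour$Kb) {
  x <- contour$x; n <- nrow(x)
  if (Kb == 0) return(matrix(0, n, 2))
  ip1 <- c(2:n, 1); im1 <- c(n, seq_len(n - 1))
  L <- sum(seg_ref_spacing(contour$ref))
  ds <- L / n
  c0 <- preferred_curvature(contour$ref, ds)
  D2 <- (x[ip1, , drop = FALSE] - 2 * x + x[im1, , drop = FALSE]) / ds^2
  cm <- sqrt(D2[, 1]^2 + D2[, 2]^2)
  u <- D2
  nz <- cm > 1e-14
  u[nz, ] <- u[nz, ] / cm[nz]
  u[!nz, ] <- 0
  w <- (cm - c0)                       # dE/dc per node, up to Kb * ds
  wu <- u * w
  grad <- (wu[im1, , drop = FALSE] + wu[ip1, , drop = FALSE] - 2 * wu) / ds^2
  -Kb * grad
}

#' Polygon area enclosed by a contour (shoelace formula)
#'
#' @param contour a [contour()] or an N x 2 matrix.
#' @return signed area made positive.
#' @export
contour_area <- function(contour) {
  x <- if (inherits(contour, "contour")) contour$x else as_xy_matrix(contour)
  n <- nrow(x)
  ip1 <- c(2:n, 1)
  abs(sum(x[, 1] * x[ip1, 2] - x[ip1, 1] * x[, 2]) / 2)
}

#' Centroid (mean of nodes) of a contour
#'
#' @param contour a [contour()] or an N x 2 matrix.
#' @return length-2 numeric.
#' @export
contour_centroid <- function(contour) {
  x <- if (inherits(contour, "contour")) contour$x else as_xy_matrix(contour)
  colMeans(x)
}
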