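#' Delaunay triangulation edge set
#'
#' Incremental Bowyer-Watson triangulation of a 2D point set, returning the
#' unique undirected edges.  Written in-package because no Delaunay
#' implementation is available among the package's dependencies; the
#' result is validated in tests by the empty-circumcircle property.
#'
#' @param nodes n x 2 matrix of points, n >= 3, not all collinear.
#' @return integer m x 2 matrix of node index pairs (i < j).
#' @export
delaunay_edges <- function(nodes) {
  tri <- delaunay_triangles(nodes)
  e <- rbind(tri[, c(1, 2), drop = FALSE], tri[, c(2, 3), drop = FALSE],
             tri[, c(1, 3), drop = FALSE])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# Bowyer-Watson with a super-triangle; returns triangles as index triples.
delaunay_triangles <- function(nodes) {
  p <- as_xy_matrix(nodes, "nodes")
  n <- nrow(p)
  if (n < 3) stop("need at least 3 nodes to triangulate")
  # collinearity check
  a <- p[2, ] - p[1, ]
  cr <- abs((p[, 1] - p[1, 1]) * a[2] - (p[, 2] - p[1, 2]) * a[1])
  scale <- max(apply(p, 2, function(z) diff(range(z))), 1e-12)
  if (all(cr < 1e-12 * scale^2 + 1e-300) && n >= 3) {
    # maybe p1,p2 coincide; more robust global check below
  }
  if (all_collinear(p)) stop("degenerate input: all nodes are collinear")

  cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2]))
  d <- 3 * max(diff(range(p[, 1])), diff(range(p[, 2])), 1e-9)
  super <- rbind(c(cx - 20 * d, cy - d), c(cx + 20 * d, cy - d),
                 c(cx, cy + 20 * d))
  pts <- rbind(p, super)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  for (i in seq_len(n)) {
    bad <- which(vapply(seq_len(nrow(tris)), function(t)
      in_circumcircle(pts, tris[t, ], i), logical(1)))
    if (length(bad) == 0) next   # should not happen inside super-triangle
    edges <- NULL
    for (t in bad) {
      tri <- tris[t, ]
      edges <- rbind(edges, sort(tri[c(1, 2)]), sort(tri[c(2, 3)]),
                     sort(tri[c(1, 3)]))
    }
    # boundary edges of the cavity appear exactly once
    key <- paste(edges[, 1], edges[, 2])
    keep <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    newt <- cbind(keep, i)
    tris <- rbind(tris, newt)
  }
  tris <- tris[apply(tris <= n, 1, all), , drop = FALSE]
  if (nrow(tris) == 0) stop("triangulation failed (degenerate input)")
  tris
}

all_collinear <- function(p) {
  if (nrow(p) < 3) return(TRUE)
  a <- p[1, ]
  for (j in 2:nrow(p)) {
    v <- p[j, ] - a
    if (sum(v^2) > 1e-20) {
      cr <- (p[, 1] - a[1]) * v[2] - (p[, 2] - a[2]) * v[1]
      return(all(abs(cr) < 1e-10 * sqrt(sum(v^2))))
    }
  }
  TRUE
}

in_circumcircle <- function(pts, tri, i) {
  ax <- pts[tri[1], 1]; ay <- pts[tri[1], 2]
  bx <- pts[tri[2], 1]; by <- pts[tri[2], 2]
  cx <- pts[tri[3], 1]; cy <- pts[tri[3], 2]
  dx <- pts[i, 1];      dy <- pts[i, 2]
  # orient triangle counterclockwise
  orient <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  if (orient < 0) { tmp <- bx; bx <- cx; cx <- tmp; tmp <- by; by <- cy; cy <- tmp }
  A <- ax - dx; B <- ay - dy; C <- A^2 + B^2
  D <- bx - dx; E <- by - dy; F <- D^2 + E^2
  G <- cx - dx; H <- cy - dy; I <- G^2 + H^2
  det <- A * (E * I - F * H) - B * (D * I - F * G) + C * (D * H - E * G)
  det > 0
}

#' Generate a random ECM node-spring lattice
#'
#' Uniform rejection sampling of nodes on a rectangular box minus an
#' exclusion disk (where the cell initially sits), with an optional
#' minimum inter-node spacing; the full point set is Delaunay-triangulated
#' once and each triangulation edge carries a virtual spring.  Tether
#' references are precomputed so the lattice is exactly force-free at its
#' initial configuration.
#'
#' @param n_nodes number of nodes (20 for the sparse, 60 for the dense
#'   lattice used in the simulations).
#' @param box lattice domain as c(xmin, xmax, ymin, ymax); default
#'   `c(0, 4, -2, 2)` in cell diameters.
#' @param exclusion list with `center` and `radius` of the excluded disk;
#'   default a disk of radius 0.6 (cell radius plus a small clearance) at
#'   the cell's initial center (0.25, 0), so the cell starts inside the
#'   mesh but clear of all nodes.
#' @param min_spacing minimum allowed inter-node distance.  The default
#'   (`NULL`) uses three quarters of the hexagonal-packing spacing of
#'   `n_nodes` points on the free box area, which reproduces the study's
#'   stated dense-mesh size (mean nearest-node distance about 0.5 for 60
#'   nodes) and spreads sparser lattices as far as uniform sampling
#'   allows.
#' @param seed integer seed; the lattice is reproducible per seed.
#' @param k_ecm spring constant of the lattice springs (default 50).
#' @param k_tether tether (pinning) constant; defaults to `k_ecm`.
#' @param max_tries rejection-sampling attempts per node before failing.
#' @return an object of class `ecm_lattice` with fields `x` (current
#'   positions), `x0` (initial), `ref` (tether references), `edges`,
#'   `k_ecm`, `k_tether`.
#' @export
generate_ecm <- function(n_nodes, box = c(0, 4, -2, 2),
                         exclusion = list(center = c(0.25, 0), radius = 0.6),
                         min_spacing = NULL, seed = NULL, k_ecm = 50,
                         k_tether = k_ecm, max_tries = 40000) {
  if (n_nodes < 3) stop("need at least 3 nodes")
  if (is.null(min_spacing)) {
    area <- (box[2] - box[1]) * (box[4] - box[3])
    if (!is.null(exclusion)) area <- area - pi * exclusion$radius^2
    min_spacing <- 0.75 * sqrt(2 * area / (sqrt(3) * n_nodes))
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  pts <- matrix(NA_real_, n_nodes, 2)
  placed <- 0
  tries <- 0
  while (placed < n_nodes) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("lattice generation failed: could not place ", n_nodes,
           " nodes with min_spacing ", min_spacing)
    cand <- c(runif(1, box[1], box[2]), runif(1, box[3], box[4]))
    if (!is.null(exclusion) &&
        sum((cand - exclusion$center)^2) < exclusion$radius^2) next
    if (placed > 0) {
      d2 <- (pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_spacing^2) next
    }
    placed <- placed + 1
    pts[placed, ] <- cand
  }
  edges <- delaunay_edges(pts)
  lat <- structure(list(x = pts, x0 = pts, ref = NULL, edges = edges,
                        k_ecm = k_ecm, k_tether = k_tether, box = box,
                        exclusion = exclusion, seed = seed),
                   class = "ecm_lattice")
  lat$ref <- compute_pinning(lat)
  lat
}

#' Tether references that pin the lattice at rest
#'
#' Precomputes per-node reference locations such that the total ECM force
#' (springs plus tethers) vanishes exactly at the initial configuration,
#' while rigid translations of the lattice are penalized by the tethers.
#'
#' @param lattice an `ecm_lattice` with `x0` and `edges` set.
#' @return n x 2 matrix of tether reference points.
#' @export
compute_pinning <- function(lattice) {
  x0 <- lattice$x0
  s <- spring_sum(x0, lattice$edges, nrow(x0))
  x0 + (lattice$k_ecm / lattice$k_tether) * s
}

# sum over neighbours of (x_i - x_j) for every node i
spring_sum <- function(x, edges, n) {
  d <- x[edges[, 1], , drop = FALSE] - x[edges[, 2], , drop = FALSE]
  out <- matrix(0, n, 2)
  out[, 1] <- out[, 1] +
    unname(rowsum_safe(d[, 1], edges[, 1], n)) -
    unname(rowsum_safe(d[, 1], edges[, 2], n))
  out[, 2] <- out[, 2] +
    unname(rowsum_safe(d[, 2], edges[, 1], n)) -
    unname(rowsum_safe(d[, 2], edges[, 2], n))
  out
}

rowsum_safe <- function(v, idx, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' ECM node forces (springs plus pinning tethers)
#'
#' `F_i = -k_tether (x_i - ref_i) - k_ecm * sum_{j in N(i)} (x_i - x_j)`,
#' which is exactly zero at the initial configuration by construction of
#' the tether references.
#'
#' @param lattice an `ecm_lattice`.
#' @param x optional positions at which to evaluate (defaults to current).
#' @return n x 2 matrix of forces.
#' @export
ecm_force <- function(lattice, x = lattice$x) {
  if (is.null(lattice$ref))
    stop("lattice has no tether references; run compute_pinning() first")
  -lattice$k_tether * (x - lattice$ref) -
    lattice$k_ecm * spring_sum(x, lattice$edges, nrow(x))
}

#' Lattice spacing statistics
#'
#' Reports both candidate definitions of the mean fiber spacing: the mean
#' nearest-node distance and the mean triangulation edge length.
#'
#' @param lattice an `ecm_lattice`.
#' @return list with `mean_nn` and `mean_edge`.
#' @export
lattice_spacing <- function(lattice) {
  x <- lattice$x0
  dm <- as.matrix(stats::dist(x))
  diag(dm) <- Inf
  el <- sqrt(rowSums((x[lattice$edges[, 1], , drop = FALSE] -
                      x[lattice$edges[, 2], , drop = FALSE])^2))
  list(mean_nn = mean(apply(dm, 1, min)), mean_edge = mean(el))
}

#' Write / read an ECM lattice as delimited tables
#'
#' The node table has columns id, x0, y0, xref, yref; the edge table has
#' columns i, j.
#'
#' @param lattice an `ecm_lattice`.
#' @param node_file,edge_file file paths (tab-separated).
#' @export
write_ecm <- function(lattice, node_file, edge_file) {
  nd <- data.frame(id = seq_len(nrow(lattice$x0)),
                   x0 = lattice$x0[, 1], y0 = lattice$x0[, 2],
                   xref = lattice$ref[, 1], yref = lattice$ref[, 2])
  write.table(nd, node_file, sep = "\t", row.names = FALSE, quote = FALSE)
  ed <- data.frame(i = lattice$edges[, 1], j = lattice$edges[, 2])
  write.table(ed, edge_file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(lattice)
}

#' @rdname write_ecm
#' @param k_ecm,k_tether spring and tether constants for the loaded lattice.
#' @export
read_ecm <- function(node_file, edge_file, k_ecm = 50, k_tether = k_ecm) {
  nd <- read.table(node_file, header = TRUE, sep = "\t")
  ed <- read.table(edge_file, header = TRUE, sep = "\t")
  x0 <- cbind(nd$x0, nd$y0)
  structure(list(x = x0, x0 = x0, ref = cbind(nd$xref, nd$yref),
                 edges = cbind(ed$i, ed$j), k_ecm = k_ecm,
                 k_tether = k_tether, box = NULL, exclusion = NULL,
                 seed = NULL),
            class = "ecm_lattice")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
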