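#' Cortex nodes on the front (+x) half of the cell
#'
#' Eligible protrusion sites: nodes whose outward radial direction about
#' the cortex centroid has a positive x-component (equivalently, nodes to
#' the right of the centroid).  At the resting circular configuration this
#' is exactly the set of nodes whose unit-circle normal points forward.
#'
#' @param cortex a [contour()].
#' @return integer vector of node indices.
#' @export
front_half_nodes <- function(cortex) {
  ctr <- contour_centroid(cortex)
  which(cortex$x[, 1] > ctr[1])
}

#' Place the push-pull protrusion center
#'
#' Chooses a node uniformly at random among the front-half cortex nodes.
#' Draws from the current R random number generator state.
#'
#' @param cortex a [contour()].
#' @return integer node index.
#' @export
place_protrusion_m1 <- function(cortex) {
  elig <- front_half_nodes(cortex)
  elig[sample.int(length(elig), 1)]
}

#' Place the two rear-squeezing protrusion centers
#'
#' The first center is chosen as in the push-pull mechanism.  The second
#' sits at an angular offset of 15-45 degrees from the first, positioned so
#' the pair grows toward two adjacent ECM nodes: when a lattice is
#' supplied, the side and offset within the band are taken toward the
#' angularly nearest reachable node; otherwise the offset is drawn
#' uniformly from the band on a random side (flipped if it would leave the
#' front half).  Angles are measured about the cortex centroid.
#'
#' @param cortex a [contour()].
#' @param lattice optional `ecm_lattice` used to orient the second
#'   protrusion toward the adjacent node.
#' @param reach maximal node distance from the centroid considered
#'   reachable (default 2 cell diameters).
#' @return integer vector of two distinct node indices.
#' @export
place_protrusions_m2 <- function(cortex, lattice = NULL, reach = 2) {
  ctr <- contour_centroid(cortex)
  th <- atan2(cortex$x[, 2] - ctr[2], cortex$x[, 1] - ctr[1])
  m1 <- place_protrusion_m1(cortex)
  band <- c(15, 45) * pi / 180
  target <- NA_real_
  if (!is.null(lattice)) {
    dx <- lattice$x[, 1] - ctr[1]; dy <- lattice$x[, 2] - ctr[2]
    dist <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx)
    off <- atan2(sin(ang - th[m1]), cos(ang - th[m1]))
    ok <- dist <= reach & abs(off) >= band[1] & abs(off) <= band[2] &
      cos(ang) > 0
    if (any(ok)) {
      j <- which(ok)[which.min(abs(off[ok]))]
      target <- th[m1] + off[j]
    }
  }
  if (is.na(target)) {
    o <- runif(1, band[1], band[2])
    side <- if (runif(1) < 0.5) 1 else -1
    target <- th[m1] + side * o
    if (cos(target) <= 0) target <- th[m1] - side * o
  }
  dd <- abs(atan2(sin(th - target), cos(th - target)))
  m2 <- which.min(dd)
  if (m2 == m1) m2 <- wrap_index(m1 + 5L, nrow(cortex$x))
  c(m1, m2)
}

#' Detect contact between a protrusion tip and an ECM node
#'
#' A contact occurs when the tip comes within `threshold` (2 eps by
#' default usage) of an ECM node.  Returns the nearest node within the
#' threshold; ties are broken by the lower node id.
#'
#' @param tip length-2 tip position.
#' @param lattice an `ecm_lattice` (current positions are used).
#' @param threshold contact distance, > 0.
#' @param exclude node ids that may not be bound (e.g. already bound).
#' @return integer node id, or `NA_integer_` if no node is in range.
#' @export
detect_contact <- function(tip, lattice, threshold, exclude = integer(0)) {
  if (threshold <= 0) stop("threshold must be positive")
  x <- lattice$x
  d <- sqrt((x[, 1] - tip[1])^2 + (x[, 2] - tip[2])^2)
  if (length(exclude)) d[exclude] <- Inf
  i <- which(d < threshold)
  if (length(i) == 0) return(NA_integer_)
  i[order(d[i], i)][1]
}

#' Equilibrium test on point speeds
#'
#' True when the largest point speed has dropped below the threshold
#' (numerically "at rest"); by convention the threshold equals the blob
#' width eps.
#'
#' @param speeds numeric vector of point speeds (or an n x 2 velocity
#'   matrix).
#' @param threshold speed threshold, > 0.
#' @return logical.
#' @export
check_equilibrium <- function(speeds, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  if (!is.null(dim(speeds))) speeds <- sqrt(rowSums(speeds^2))
  max(speeds) < threshold
}

#' Partition the cortex into front and rear arcs between two bound tips
#'
#' The two tip nodes split the closed cortex into two arcs; the arc with
#' the greater reference arclength is the rear (contracting) arc.  Tip
#' nodes themselves belong to neither arc and stay relaxed.
#'
#' @param cortex a [contour()].
#' @param tip1,tip2 bound tip node indices.
#' @return list with integer index vectors `rear` and `front`.
#' @export
cortex_arcs <- function(cortex, tip1, tip2) {
  n <- nrow(cortex$x)
  if (tip1 == tip2) stop("tips must be distinct")
  ds <- seg_ref_spacing(cortex$ref)
  steps_fwd <- (tip2 - tip1) %% n
  seg_fwd <- wrap_index(tip1 + seq_len(steps_fwd) - 1L, n)
  len_fwd <- sum(ds[seg_fwd])
  len_bwd <- sum(ds) - len_fwd
  between_fwd <- if (steps_fwd > 1)
    wrap_index(tip1 + seq_len(steps_fwd - 1L), n) else integer(0)
  between_bwd <- setdiff(seq_len(n), c(between_fwd, tip1, tip2))
  if (len_fwd >= len_bwd) list(rear = between_fwd, front = between_bwd)
  else list(rear = between_bwd, front = between_fwd)
}

#' Nucleus bending rigidity for the current motility phase
#'
#' In "computational" mode a small bending rigidity stabilizes the nucleus
#' only while protrusions are forming (preventing it from being squeezed
#' into thin protrusions) and is switched off in contractile phases; in
#' "physical" mode the rigidity is constant through all phases; "none"
#' disables bending.
#'
#' @param mode one of "computational", "physical", "none".
#' @param Kb the configured bending rigidity.
#' @param phase current phase string (e.g. "PROTRUDING").
#' @return the bending rigidity to apply this step.
#' @export
nucleus_bending_rigidity <- function(mode, Kb, phase) {
  switch(mode,
         none = 0,
         physical = Kb,
         computational = if (phase %in% c("PROTRUDING", "RELAXED")) Kb else 0,
         stop("unknown bending mode '", mode, "'"))
}
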