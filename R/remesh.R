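#' Resample a contour at equal arclength
#'
#' Builds the continuous cumulative arclength of the current polygon,
#' samples it at N equal increments starting from the anchor node, and
#' linearly interpolates both the current and the reference positions at
#' the sampled parameters (the same interpolation weights are used for
#' both).  Node count is preserved and the anchor node is left exactly in
#' place, so a bound protrusion tip can be kept pinned through remeshing.
#'
#' @param contour a [contour()].
#' @param anchor index of the node held fixed at arclength zero (default 1).
#' @return a new [contour()] with equispaced nodes.
#' @export
resample_equal_arclength <- function(contour, anchor = 1L) {
  x <- contour$x; ref <- contour$ref; n <- nrow(x)
  rot <- wrap_index(anchor + seq_len(n) - 1L, n)   # anchor becomes node 1
  x <- x[rot, , drop = FALSE]; ref <- ref[rot, , drop = FALSE]
  k <- contour$k[rot]; r <- contour$r[rot]

  ip1 <- c(2:n, 1)
  seg <- x[ip1, , drop = FALSE] - x
  seglen <- sqrt(seg[, 1]^2 + seg[, 2]^2)
  L <- sum(seglen)
  if (L <= 0) stop("zero-length contour cannot be resampled")
  s <- c(0, cumsum(seglen))                        # s at nodes 1..n, then n+1 = L
  starget <- (seq_len(n) - 1) * L / n
  idx <- findInterval(starget, s, rightmost.closed = TRUE)
  idx[idx > n] <- n
  w <- (starget - s[idx]) / seglen[idx]
  w[!is.finite(w)] <- 0
  inext <- ip1[idx]
  newx <- x[idx, , drop = FALSE] * (1 - w) + x[inext, , drop = FALSE] * w
  newref <- ref[idx, , drop = FALSE] * (1 - w) + ref[inext, , drop = FALSE] * w
  # piecewise-constant fields follow the nearest old node
  pick <- ifelse(w < 0.5, idx, inext)
  out <- contour(newx, newref, k = k[pick], r = r[pick], Kb = contour$Kb)
  # rotate back so the anchor keeps its original index
  inv <- wrap_index(seq_len(n) - (anchor - 1L), n)
  contour(out$x[inv, , drop = FALSE], out$ref[inv, , drop = FALSE],
          k = out$k[inv], r = out$r[inv], Kb = out$Kb)
}

#' Remeshing schedule predicate
#'
#' Remeshing runs every `every` time steps, and only while a rear-squeezing
#' cell is attached to two ECM nodes (the phase in which the rear packs and
#' the front stretches).
#'
#' @param step_count steps taken since the start of the bound phase.
#' @param mechanism motility mechanism (1 or 2).
#' @param bound_nodes number of currently bound ECM nodes.
#' @param every remeshing period in steps (default 100).
#' @return logical.
#' @export
remesh_schedule <- function(step_count, mechanism, bound_nodes, every = 100) {
  mechanism == 2 && bound_nodes == 2 && step_count > 0 &&
    step_count %% every == 0
}
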