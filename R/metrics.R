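#' Center of mass of a contour
#'
#' Arithmetic mean of the discrete node positions (not the area centroid);
#' this is how the nucleus is tracked to measure migration distance.
#'
#' @param contour a [contour()] or N x 2 matrix.
#' @return length-2 numeric.
#' @export
nucleus_center_of_mass <- function(contour) {
  contour_centroid(contour)
}

#' Bounding-box aspect ratio of a contour
#'
#' `a = (xmax - xmin) / (ymax - ymin)` over the discrete nodes, folded as
#' `max(a, 1/a)` so the result is always >= 1.
#'
#' @param contour a [contour()] or N x 2 matrix.
#' @return scalar >= 1.
#' @export
aspect_ratio <- function(contour) {
  x <- if (inherits(contour, "contour")) contour$x else as_xy_matrix(contour)
  wx <- diff(range(x[, 1])); wy <- diff(range(x[, 2]))
  if (wy <= 0 || wx <= 0) stop("degenerate contour extent")
  a <- wx / wy
  max(a, 1 / a)
}

#' Fraction of cell points past the ECM gap line
#'
#' Fraction of all cortex-plus-nucleus nodes strictly past the infinite
#' line through the two gap-defining ECM node positions, "past" meaning on
#' the side of the line reached by moving in the +x migration direction.
#'
#' @param cortex,nucleus contours (or N x 2 matrices).
#' @param gap_nodes 2 x 2 matrix: initial positions of the two ECM nodes
#'   bounding the gap the cell moves through.
#' @return scalar in `[0, 1]`, or `NA` if `gap_nodes` is `NULL` (no defined
#'   gap, e.g. an unbound push-pull cell).
#' @export
penetration_fraction <- function(cortex, nucleus, gap_nodes) {
  if (is.null(gap_nodes)) return(NA_real_)
  gap_nodes <- as_xy_matrix(gap_nodes, "gap_nodes")
  xc <- if (inherits(cortex, "contour")) cortex$x else as_xy_matrix(cortex)
  xn <- if (inherits(nucleus, "contour")) nucleus$x else as_xy_matrix(nucleus)
  pts <- rbind(xc, xn)
  d <- gap_nodes[2, ] - gap_nodes[1, ]
  nrm <- c(d[2], -d[1])          # a normal of the gap line
  if (nrm[1] < 0) nrm <- -nrm    # orient toward +x
  if (nrm[1] == 0) stop("gap line is horizontal; migration side undefined")
  s <- (pts[, 1] - gap_nodes[1, 1]) * nrm[1] +
       (pts[, 2] - gap_nodes[1, 2]) * nrm[2]
  mean(s > 0)
}

#' Mean and standard error over replicate records
#'
#' @param values numeric vector (one entry per replicate/cycle).
#' @return list with `mean`, `sem`, `n`.
#' @export
replicate_statistics <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 records for replicate statistics")
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Maximum ECM node displacement from the initial lattice
#'
#' @param lattice an `ecm_lattice`.
#' @param x optional current positions (defaults to `lattice$x`).
#' @return largest node displacement (cell diameters).
#' @export
max_ecm_displacement <- function(lattice, x = lattice$x) {
  max(sqrt(rowSums((x - lattice$x0)^2)))
}
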