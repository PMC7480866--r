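#' Simulation control parameters
#'
#' Numerical and discretization settings for a migration simulation.
#' Defaults follow the study conditions: 80 cortex nodes for the push-pull
#' mechanism and 120 for rear-squeezing, 80 nucleus nodes, time step 0.001
#' refined to 0.0002 for 0.1 time units after the cortex stiffens, blob
#' width 0.1 cell diameters, nucleus diameter 0.9 cell diameters, and a
#' small computational nucleus bending rigidity active only while
#' protrusions form.
#'
#' @param mechanism 1 or 2 (used for mechanism-dependent defaults).
#' @param Nc,Nn cortex / nucleus node counts.
#' @param eps blob width (default 0.1 cell diameters, i.e. a 1 um blob
#'   and a 2 um contact-capture radius for a 10 um cell).
#' @param dt,dt_fine coarse and refined time steps.
#' @param fine_window duration of the refined-step window after binding.
#' @param diameter,nucleus_diameter resting diameters (cell diameters).
#' @param center initial cell center.
#' @param f0 protrusion force-density amplitude; default `20 * k_cs / ds`
#'   with `ds` the cortex node spacing (fast protrusion growth).
#' @param equil_tol equilibrium speed threshold; defaults to 0.02 (the
#'   cortex resolution scale), the numerical notion of "at rest".
#' @param max_phase_time hard cap on any single phase (time units).
#'   Phases that have not rested by then are in slow terminal creep; 20
#'   time units bounds them without affecting completed passages.
#' @param stall_window a growing protrusion that fails to lengthen for
#'   this long (time units) is considered stalled and is retracted; a
#'   stalled finger in elastic balance can never reach a node.
#' @param remesh_every remeshing period in steps (rear-squeezing only).
#' @param snapshot_stride steps between stored snapshots.
#' @param bending nucleus bending mode: "computational", "physical" or
#'   "none".
#' @param Kb nucleus bending rigidity used by the bending mode.
#' @param geometry_guard logical; eject ECM nodes from the cortex polygon
#'   and cortex nodes from the nucleus polygon each step.
#' @param flow_cutoff outer screening length of the 2D flow kernel (see
#'   [fluid_solution()]); must exceed the lattice box size.
#' @param kick_size geometry-guard ejection kick length; defaults to the
#'   resolution scale (0.02), so ejections do not shock the elastic
#'   contours the way blob-scale kicks would.
#' @param max_disp_step displacement limiter: the time step is shortened
#'   whenever the fastest point would move farther than this in one step
#'   (default `eps / 2`), so stiff transients are sub-stepped safely.
#' @return list of class `sim_control`.
#' @export
sim_control <- function(mechanism = 1, Nc = NULL, Nn = 80, eps = NULL,
                        dt = 0.001, dt_fine = 2e-4, fine_window = 0.1,
                        diameter = 1, nucleus_diameter = 0.9,
                        center = c(0.25, 0), f0 = NULL, equil_tol = NULL,
                        max_phase_time = 20, stall_window = 0.5,
                        remesh_every = 100,
                        snapshot_stride = 100, bending = "computational",
                        Kb = 0.05, geometry_guard = TRUE, flow_cutoff = 10,
                        kick_size = 0.02, max_disp_step = NULL) {
  if (is.null(Nc)) Nc <- if (mechanism == 1) 80L else 120L
  if (is.null(eps)) eps <- 0.1 * diameter
  if (is.null(equil_tol)) equil_tol <- 0.02 * diameter
  if (is.null(max_disp_step)) max_disp_step <- eps / 2
  stopifnot(dt > 0, dt_fine > 0, dt_fine <= dt, eps > 0, Nc >= 5, Nn >= 3)
  structure(list(mechanism = mechanism, Nc = as.integer(Nc),
                 Nn = as.integer(Nn), eps = eps, dt = dt, dt_fine = dt_fine,
                 fine_window = fine_window, diameter = diameter,
                 nucleus_diameter = nucleus_diameter, center = center,
                 f0 = f0, equil_tol = equil_tol,
                 max_phase_time = max_phase_time,
                 stall_window = stall_window,
                 remesh_every = remesh_every,
                 snapshot_stride = snapshot_stride, bending = bending,
                 Kb = Kb, geometry_guard = geometry_guard,
                 flow_cutoff = flow_cutoff, kick_size = kick_size,
                 max_disp_step = max_disp_step),
            class = "sim_control")
}

#' Assemble a cell-plus-ECM system ready for time stepping
#'
#' Builds the cortex and nucleus contours at their resting circular
#' configurations, attaches the ECM lattice, initializes the independent
#' random streams (protrusion placement and geometry-ejection kicks) and
#' returns a mutable system environment.
#'
#' @param regime a [regime_config()] (or preset name for [load_preset()]).
#' @param lattice an `ecm_lattice` from [generate_ecm()].
#' @param seed integer seed driving all stochastic choices of the run.
#' @param control a [sim_control()]; defaults to the regime's mechanism.
#' @return an environment of class `cell_system`.
#' @export
new_cell_system <- function(regime, lattice, seed = 1, control = NULL) {
  if (is.character(regime)) regime <- load_preset(regime)
  if (is.null(control)) control <- sim_control(mechanism = regime$mechanism)
  ctl <- control
  sys <- new.env(parent = emptyenv())
  sys$regime <- regime
  sys$ctl <- ctl
  sys$mech <- regime$mechanism
  rad <- ctl$diameter / 2
  cor <- circle_contour(ctl$Nc, rad, ctl$center, k = regime$k_cs, r = 1)
  nuc <- circle_contour(ctl$Nn, ctl$nucleus_diameter / 2, ctl$center,
                        k = regime$k_n, r = 1)
  sys$xc <- cor$x; sys$refc <- cor$ref
  sys$kc <- cor$k; sys$rc <- cor$r
  sys$xn <- nuc$x; sys$refn <- nuc$ref
  sys$kn <- nuc$k; sys$rn <- nuc$r
  lat <- lattice
  lat$x <- lat$x0
  lat$k_ecm <- regime$k_ecm
  if (is.null(lat$ref)) lat$ref <- compute_pinning(lat)
  sys$lat <- lat
  ne <- nrow(lat$x0)
  # dense incidence matrix for fast spring sums
  B <- matrix(0, ne, nrow(lat$edges))
  B[cbind(lat$edges[, 1], seq_len(nrow(lat$edges)))] <- 1
  B[cbind(lat$edges[, 2], seq_len(nrow(lat$edges)))] <- -1
  sys$Binc <- B
  d0 <- lat$x0[lat$edges[, 1], , drop = FALSE] -
        lat$x0[lat$edges[, 2], , drop = FALSE]
  lat$ref <- lat$x0 + (lat$k_ecm / lat$k_tether) * (B %*% d0)
  sys$lat <- lat
  e0 <- lat$x0[lat$edges[, 1], , drop = FALSE] -
        lat$x0[lat$edges[, 2], , drop = FALSE]
  sys$edge_len0 <- sqrt(e0[, 1]^2 + e0[, 2]^2)
  sys$cycle_max_strain <- 0
  sys$eps <- ctl$eps
  sys$t <- 0; sys$step <- 0L; sys$fine_until <- -Inf
  sys$phase <- "RELAXED"
  sys$cycle <- 0L
  sys$prots <- list()
  sys$bound_tips <- integer(0); sys$bound_nodes <- integer(0)
  sys$f0 <- if (is.null(ctl$f0)) 20 * regime$k_cs / (pi * ctl$diameter / ctl$Nc)
            else ctl$f0
  sys$max_speed <- Inf
  sys$events <- list(); sys$snapshots <- list()
  sys$cycles <- list()
  sys$bound_snapshot <- NULL
  sys$cycle_max_ecm <- 0
  sys$seed <- seed
  old <- get_rng_state()
  set.seed(seed);          sys$rng_prot <- get_rng_state()
  set.seed(seed + 499979L); sys$rng_eject <- get_rng_state()
  set_rng_state(old)
  refresh_cortex_cache(sys); refresh_nucleus_cache(sys)
  class(sys) <- c("cell_system", "environment")
  sys
}

with_stream <- function(sys, stream, fn) {
  old <- get_rng_state()
  set_rng_state(sys[[stream]])
  out <- fn()
  sys[[stream]] <- get_rng_state()
  set_rng_state(old)
  out
}

refresh_cortex_cache <- function(sys) {
  n <- nrow(sys$xc)
  sys$c_ip1 <- c(2:n, 1L); sys$c_im1 <- c(n, seq_len(n - 1L))
  sys$c_ds <- seg_ref_spacing(sys$refc)
  sys$c_dsn <- (sys$c_ds + sys$c_ds[sys$c_im1]) / 2
  sys$c_kseg <- (sys$kc + sys$kc[sys$c_ip1]) / 2
  sys$c_rseg <- (sys$rc + sys$rc[sys$c_ip1]) / 2
  invisible(sys)
}

refresh_nucleus_cache <- function(sys) {
  n <- nrow(sys$xn)
  sys$n_ip1 <- c(2:n, 1L); sys$n_im1 <- c(n, seq_len(n - 1L))
  sys$n_ds <- seg_ref_spacing(sys$refn)
  sys$n_dsn <- (sys$n_ds + sys$n_ds[sys$n_im1]) / 2
  sys$n_kseg <- (sys$kn + sys$kn[sys$n_ip1]) / 2
  sys$n_rseg <- (sys$rn + sys$rn[sys$n_ip1]) / 2
  L <- sum(sys$n_ds)
  sys$n_dsm <- L / n
  sys$n_c0 <- preferred_curvature(sys$refn, sys$n_dsm)
  invisible(sys)
}

elastic_force_fast <- function(x, ip1, im1, ds, dsn, kseg, rseg) {
  d <- x[ip1, , drop = FALSE] - x
  len <- sqrt(d[, 1]^2 + d[, 2]^2)
  Tseg <- kseg * (len / ds - rseg)
  ttx <- Tseg * d[, 1] / ds
  tty <- Tseg * d[, 2] / ds
  cbind((ttx - ttx[im1]) / dsn, (tty - tty[im1]) / dsn)
}

bending_force_fast <- function(x, ip1, im1, ds, c0, Kb) {
  D2x <- (x[ip1, 1] - 2 * x[, 1] + x[im1, 1]) / ds^2
  D2y <- (x[ip1, 2] - 2 * x[, 2] + x[im1, 2]) / ds^2
  cm <- sqrt(D2x^2 + D2y^2)
  sc <- ifelse(cm > 1e-14, (cm - c0) / cm, 0)
  wx <- sc * D2x; wy <- sc * D2y
  cbind(-(Kb / ds^2) * (wx[im1] + wx[ip1] - 2 * wx),
        -(Kb / ds^2) * (wy[im1] + wy[ip1] - 2 * wy))
}

# point forces (not densities) for the whole system, stacked
assemble_forces <- function(sys) {
  fc <- elastic_force_fast(sys$xc, sys$c_ip1, sys$c_im1, sys$c_ds,
                           sys$c_dsn, sys$c_kseg, sys$c_rseg)
  for (pr in sys$prots) {
    if (pr$active) {
      n <- nrow(sys$xc)
      amp <- rep(-2 * pr$p$f0 / (n - 3), n)
      amp[pr$tip] <- pr$p$f0
      amp[c(wrap_index(pr$tip - 1L, n), wrap_index(pr$tip + 1L, n))] <-
        pr$p$f0 / 2
      fc <- fc + cbind(amp * pr$p$normal[1], amp * pr$p$normal[2])
    }
  }
  fc <- fc * sys$c_dsn
  fn <- elastic_force_fast(sys$xn, sys$n_ip1, sys$n_im1, sys$n_ds,
                           sys$n_dsn, sys$n_kseg, sys$n_rseg)
  Kb <- nucleus_bending_rigidity(sys$ctl$bending, sys$ctl$Kb, sys$phase)
  if (Kb > 0)
    fn <- fn + bending_force_fast(sys$xn, sys$n_ip1, sys$n_im1, sys$n_dsm,
                                  sys$n_c0, Kb)
  fn <- fn * sys$n_dsn
  dlat <- sys$lat$x[sys$lat$edges[, 1], , drop = FALSE] -
          sys$lat$x[sys$lat$edges[, 2], , drop = FALSE]
  fe <- -sys$lat$k_tether * (sys$lat$x - sys$lat$ref) -
        sys$lat$k_ecm * (sys$Binc %*% dlat)
  list(loc = rbind(sys$xc, sys$xn, sys$lat$x), f = rbind(fc, fn, fe))
}

#' Advance the system by one forward-Euler step
#'
#' Assembles the point forces of cortex, nucleus and ECM, evaluates the
#' regularized-Stokeslet velocity at every immersed point, updates all
#' positions by forward Euler (using the refined time step inside the
#' post-binding window), keeps bound tip/node pairs coincident, and
#' applies the geometry guards.
#'
#' @param sys a `cell_system` from [new_cell_system()].
#' @return the system, invisibly; `sys$max_speed` holds the largest point
#'   speed of the step just taken.
#' @export
advance_step <- function(sys) {
  af <- assemble_forces(sys)
  u <- rs_velocity_self_cpp(af$loc, af$f, sys$eps, 1, sys$ctl$flow_cutoff)
  if (!all(is.finite(u)))
    stop("non-finite velocity at t = ", sys$t, " (phase ", sys$phase, ")")
  sys$max_speed <- sqrt(max(u[, 1]^2 + u[, 2]^2))
  dt <- if (sys$t < sys$fine_until) sys$ctl$dt_fine else sys$ctl$dt
  if (sys$max_speed * dt > sys$ctl$max_disp_step)
    dt <- sys$ctl$max_disp_step / sys$max_speed
  if (isTRUE(getOption("stokescell.trace")) && sys$step %% 2000L == 0L)
    cat(sprintf("[trace] step=%d t=%.4f phase=%s spd=%.3g dt=%.2g\n",
                sys$step, sys$t, sys$phase, sys$max_speed, dt))
  nc <- nrow(sys$xc); nn <- nrow(sys$xn)
  sys$xc <- sys$xc + dt * u[seq_len(nc), , drop = FALSE]
  sys$xn <- sys$xn + dt * u[nc + seq_len(nn), , drop = FALSE]
  sys$lat$x <- sys$lat$x + dt * u[-seq_len(nc + nn), , drop = FALSE]
  if (length(sys$bound_nodes))
    sys$lat$x[sys$bound_nodes, ] <- sys$xc[sys$bound_tips, , drop = FALSE]
  if (sys$ctl$geometry_guard) enforce_geometry(sys)
  sys$cycle_max_ecm <- max(sys$cycle_max_ecm,
                           max_ecm_displacement(sys$lat, sys$lat$x))
  el <- sys$lat$x[sys$lat$edges[, 1], , drop = FALSE] -
        sys$lat$x[sys$lat$edges[, 2], , drop = FALSE]
  sys$cycle_max_strain <- max(sys$cycle_max_strain,
                              max(abs(sqrt(el[, 1]^2 + el[, 2]^2) /
                                      sys$edge_len0 - 1)))
  sys$t <- sys$t + dt
  sys$step <- sys$step + 1L
  if (sys$step %% sys$ctl$snapshot_stride == 0L) record_snapshot(sys)
  maybe_bound_snapshot(sys, af)
  invisible(sys)
}

record_snapshot <- function(sys) {
  sys$snapshots[[length(sys$snapshots) + 1L]] <-
    list(t = sys$t, cycle = sys$cycle, phase = sys$phase, xc = sys$xc,
         xn = sys$xn, xe = sys$lat$x,
         aspect = aspect_ratio(sys$xc),
         area_c = contour_area(sys$xc), area_n = contour_area(sys$xn))
  invisible(sys)
}

maybe_bound_snapshot <- function(sys, af) {
  if (is.null(sys$bound_snapshot) && sys$phase == "BOUND_CONTRACTING" &&
      !is.null(sys$bind_time) && sys$t >= sys$bind_time + 0.15) {
    sys$bound_snapshot <- list(t = sys$t, cycle = sys$cycle,
                               loc = af$loc, f = af$f, eps = sys$eps,
                               xc = sys$xc, xn = sys$xn, xe = sys$lat$x)
  }
  invisible(sys)
}

#' Geometry guards: eject interpenetrating points
#'
#' Any free ECM node strictly inside the cortex polygon is moved by eps in
#' random directions until it is outside; the same is done for cortex
#' nodes inside the nucleus polygon.  Points on an edge count as outside.
#'
#' @param sys a `cell_system`.
#' @param max_kicks abort threshold on ejection attempts per point.
#' @return the system, invisibly.
#' @export
enforce_geometry <- function(sys, max_kicks = 50) {
  free <- setdiff(seq_len(nrow(sys$lat$x)), sys$bound_nodes)
  if (length(free)) {
    inside <- points_in_polygon_cpp(sys$lat$x[free, , drop = FALSE], sys$xc)
    for (i in free[inside])
      sys$lat$x[i, ] <- eject_point(sys, sys$lat$x[i, ], sys$xc, max_kicks)
  }
  inside <- points_in_polygon_cpp(sys$xc, sys$xn)
  for (i in which(inside))
    sys$xc[i, ] <- eject_point(sys, sys$xc[i, ], sys$xn, max_kicks)
  invisible(sys)
}

# random eps-kicks until the point leaves the polygon; if the random walk
# has not escaped after max_kicks (point deep inside), fall back to
# projecting just outside the nearest polygon vertex
eject_point <- function(sys, pt, poly, max_kicks) {
  kicks <- 0
  while (points_in_polygon_cpp(matrix(pt, 1, 2), poly)[1]) {
    kicks <- kicks + 1
    if (kicks > max_kicks) {
      d2 <- (poly[, 1] - pt[1])^2 + (poly[, 2] - pt[2])^2
      j <- which.min(d2)
      out <- poly[j, ] - pt
      nrm <- sqrt(sum(out^2))
      dirv <- if (nrm > 1e-12) out / nrm else c(1, 0)
      pt <- poly[j, ] + sys$eps * dirv
      kicks <- 0
      next
    }
    th <- with_stream(sys, "rng_eject", function() runif(1, 0, 2 * pi))
    pt <- pt + sys$ctl$kick_size * c(cos(th), sin(th))
  }
  pt
}

#' Even-odd point-in-polygon test
#'
#' Ray-crossing (even-odd) rule on a closed polyline; points exactly on an
#' edge count as outside, which prevents ejection loops at the boundary.
#'
#' @param pts n x 2 matrix of query points.
#' @param poly m x 2 matrix of polygon vertices (closed implicitly).
#' @return logical vector of length n.
#' @export
points_in_polygon <- function(pts, poly) {
  as.logical(points_in_polygon_cpp(as_xy_matrix(pts), as_xy_matrix(poly)))
}

log_event <- function(sys, event, i1 = NA, i2 = NA) {
  sys$events[[length(sys$events) + 1L]] <-
    data.frame(time = sys$t, cycle = sys$cycle, phase = sys$phase,
               event = event, i1 = i1, i2 = i2)
  invisible(sys)
}

set_phase <- function(sys, phase) {
  sys$phase <- phase
  sys$phase_start <- sys$t
  sys$phase_step0 <- sys$step
  log_event(sys, paste0("phase:", phase))
  invisible(sys)
}

cortex_contour <- function(sys)
  contour(sys$xc, sys$refc, k = sys$kc, r = sys$rc)
nucleus_contour <- function(sys)
  contour(sys$xn, sys$refn, k = sys$kn, r = sys$rn)

protrusion_length <- function(sys, tip) {
  ctr <- colMeans(sys$xc)
  sqrt(sum((sys$xc[tip, ] - ctr)^2)) - sys$ctl$diameter / 2
}

# tip extension along the protrusion's own normal, relative to the cell
# centroid: insensitive to rigid body motion, so it measures true growth
protrusion_extension <- function(sys, pr) {
  ctr <- colMeans(sys$xc)
  sum((sys$xc[pr$tip, ] - ctr) * pr$p$normal)
}

advance_until_rest <- function(sys) {
  # rest = every point slower than the threshold; additionally, a phase in
  # slow terminal creep (speed within 5x of the threshold and no longer
  # decaying over a 1-time-unit window) is treated as rested
  window <- 1
  last_check <- sys$t
  last_speed <- Inf
  repeat {
    advance_step(sys)
    if (sys$max_speed < sys$ctl$equil_tol) return(TRUE)
    if (sys$t - last_check >= window) {
      if (sys$max_speed < 5 * sys$ctl$equil_tol &&
          sys$max_speed > 0.95 * last_speed) return(TRUE)
      last_check <- sys$t
      last_speed <- sys$max_speed
    }
    if (sys$t - sys$phase_start > sys$ctl$max_phase_time) return(FALSE)
  }
}

start_protrusions <- function(sys) {
  cor <- cortex_contour(sys)
  ctr <- contour_centroid(cor)
  if (sys$mech == 1) {
    m <- with_stream(sys, "rng_prot", function() place_protrusion_m1(cor))
    ms <- m
  } else {
    ms <- with_stream(sys, "rng_prot",
                      function() place_protrusions_m2(cor, sys$lat))
  }
  sys$prots <- lapply(ms, function(m) {
    nrm <- sys$xc[m, ] - ctr
    nrm <- nrm / sqrt(sum(nrm^2))
    list(p = protrusion(m, sys$f0, nrm), tip = m, active = TRUE,
         bound = FALSE, capped = FALSE, node = NA_integer_,
         best_len = -Inf, best_t = sys$t)
  })
  log_event(sys, "protrusion_placed", ms[1], if (length(ms) > 1) ms[2] else NA)
  invisible(sys)
}

bind_tip <- function(sys, ip, node) {
  pr <- sys$prots[[ip]]
  sys$xc[pr$tip, ] <- sys$lat$x[node, ]
  pr$bound <- TRUE; pr$active <- FALSE; pr$node <- node
  sys$prots[[ip]] <- pr
  sys$bound_tips <- c(sys$bound_tips, pr$tip)
  sys$bound_nodes <- c(sys$bound_nodes, node)
  log_event(sys, "bind", pr$tip, node)
  invisible(sys)
}

unbind_all <- function(sys) {
  ctr <- colMeans(sys$xc)
  for (k in seq_along(sys$bound_nodes)) {
    node <- sys$bound_nodes[k]
    dirv <- sys$lat$x[node, ] - ctr
    dirv <- dirv / sqrt(sum(dirv^2))
    sys$lat$x[node, ] <- sys$lat$x[node, ] + 2 * sys$eps * dirv
    log_event(sys, "unbind", sys$bound_tips[k], node)
  }
  sys$bound_tips <- integer(0); sys$bound_nodes <- integer(0)
  invisible(sys)
}

set_cortex_uniform <- function(sys, k, r = 1) {
  sys$kc[] <- k; sys$rc[] <- r
  refresh_cortex_cache(sys)
  invisible(sys)
}

remesh_cell <- function(sys) {
  anchor <- if (length(sys$bound_tips)) sys$bound_tips[1] else 1L
  cor <- resample_equal_arclength(cortex_contour(sys), anchor = anchor)
  sys$xc <- cor$x; sys$refc <- cor$ref
  # remap the second bound tip to the nearest new node and re-pin it
  if (length(sys$bound_tips) == 2) {
    node2 <- sys$bound_nodes[2]
    d2 <- (sys$xc[, 1] - sys$lat$x[node2, 1])^2 +
          (sys$xc[, 2] - sys$lat$x[node2, 2])^2
    tip2 <- which.min(d2)
    if (tip2 == sys$bound_tips[1]) tip2 <- which(rank(d2, ties.method = "first") == 2)
    sys$xc[tip2, ] <- sys$lat$x[node2, ]
    sys$bound_tips[2] <- tip2
    arcs <- cortex_arcs(contour(sys$xc, sys$refc), sys$bound_tips[1], tip2)
    sys$kc[] <- sys$regime$k_cs; sys$rc[] <- 1
    sys$kc[arcs$rear] <- sys$regime$k_cr
    sys$rc[arcs$rear] <- sys$regime$rear_rest_length
  }
  refresh_cortex_cache(sys)
  nuc <- resample_equal_arclength(nucleus_contour(sys), anchor = 1L)
  sys$xn <- nuc$x; sys$refn <- nuc$ref
  refresh_nucleus_cache(sys)
  log_event(sys, "remesh")
  invisible(sys)
}

retract_globally <- function(sys) {
  # failed protrusion: retract by stiffening the cortex globally
  for (i in seq_along(sys$prots)) sys$prots[[i]]$active <- FALSE
  if (length(sys$bound_nodes)) unbind_all(sys)
  set_cortex_uniform(sys, sys$regime$k_cr, 1)
  sys$fine_until <- sys$t + sys$ctl$fine_window
  set_phase(sys, "EQUILIBRATING")
  log_event(sys, "retract_global")
  advance_until_rest(sys)
  set_cortex_uniform(sys, sys$regime$k_cs, 1)
  invisible(sys)
}

run_cycle_m1 <- function(sys) {
  set_phase(sys, "RELAXED")
  start_protrusions(sys)
  set_phase(sys, "PROTRUDING")
  cap <- 4 * sys$ctl$diameter / 2
  success <- FALSE
  repeat {
    advance_step(sys)
    pr <- sys$prots[[1]]
    node <- detect_contact(sys$xc[pr$tip, ], sys$lat, 2 * sys$eps)
    if (!is.na(node)) {
      bind_tip(sys, 1L, node)
      set_cortex_uniform(sys, sys$regime$k_cr, 1)
      sys$fine_until <- sys$t + sys$ctl$fine_window
      sys$bind_time <- sys$t
      set_phase(sys, "BOUND_CONTRACTING")
      advance_until_rest(sys)
      set_phase(sys, "RELEASING")
      unbind_all(sys)
      set_phase(sys, "EQUILIBRATING")
      advance_until_rest(sys)
      set_cortex_uniform(sys, sys$regime$k_cs, 1)
      success <- TRUE
      break
    }
    len <- protrusion_length(sys, pr$tip)
    ext <- protrusion_extension(sys, pr)
    if (ext > pr$best_len + 0.05) {
      pr$best_len <- ext; pr$best_t <- sys$t
      sys$prots[[1]] <- pr
    }
    if (len > cap || sys$t - pr$best_t > sys$ctl$stall_window ||
        sys$t - sys$phase_start > sys$ctl$max_phase_time) {
      log_event(sys, "protrusion_failed", pr$tip)
      retract_globally(sys)
      break
    }
  }
  sys$prots <- list()
  success
}

run_cycle_m2 <- function(sys) {
  # each cycle begins from an equispaced cortex reference configuration
  rad <- sys$ctl$diameter / 2
  sys$refc <- circle_contour(sys$ctl$Nc, rad, c(0, 0))$x
  refresh_cortex_cache(sys)
  set_phase(sys, "RELAXED")
  start_protrusions(sys)
  set_phase(sys, "PROTRUDING")
  cap <- (if (sys$cycle == 1) 3 else 2) * rad
  success <- FALSE
  repeat {
    advance_step(sys)
    for (ip in seq_along(sys$prots)) {
      pr <- sys$prots[[ip]]
      if (pr$bound || pr$capped) next
      node <- detect_contact(sys$xc[pr$tip, ], sys$lat, 2 * sys$eps,
                             exclude = sys$bound_nodes)
      if (!is.na(node)) {
        bind_tip(sys, ip, node)
        next
      }
      len <- protrusion_length(sys, pr$tip)
      ext <- protrusion_extension(sys, pr)
      if (ext > pr$best_len + 0.05) {
        pr$best_len <- ext; pr$best_t <- sys$t
        sys$prots[[ip]] <- pr
      }
      if (len > cap || sys$t - pr$best_t > sys$ctl$stall_window) {
        pr$capped <- TRUE; pr$active <- FALSE
        sys$prots[[ip]] <- pr
        log_event(sys, "protrusion_capped", pr$tip)
      }
    }
    nbound <- sum(vapply(sys$prots, `[[`, logical(1), "bound"))
    if (nbound == 2) {
      arcs <- cortex_arcs(contour(sys$xc, sys$refc),
                          sys$bound_tips[1], sys$bound_tips[2])
      sys$kc[] <- sys$regime$k_cs; sys$rc[] <- 1
      sys$kc[arcs$rear] <- sys$regime$k_cr
      sys$rc[arcs$rear] <- sys$regime$rear_rest_length
      refresh_cortex_cache(sys)
      sys$fine_until <- sys$t + sys$ctl$fine_window
      sys$bind_time <- sys$t
      set_phase(sys, "BOUND_CONTRACTING")
      last_check <- sys$t; last_speed <- Inf
      repeat {
        advance_step(sys)
        if (remesh_schedule(sys$step - sys$phase_step0, 2L, 2L,
                            sys$ctl$remesh_every))
          remesh_cell(sys)
        if (sys$max_speed < sys$ctl$equil_tol) break
        if (sys$t - last_check >= 1) {
          if (sys$max_speed < 5 * sys$ctl$equil_tol &&
              sys$max_speed > 0.95 * last_speed) break
          last_check <- sys$t; last_speed <- sys$max_speed
        }
        if (sys$t - sys$phase_start > sys$ctl$max_phase_time) break
      }
      set_phase(sys, "RELEASING")
      unbind_all(sys)
      set_cortex_uniform(sys, sys$regime$k_cs, 1)
      set_phase(sys, "EQUILIBRATING")
      advance_until_rest(sys)
      success <- TRUE
      break
    }
    allstalled <- all(vapply(sys$prots, function(p) p$bound || p$capped,
                             logical(1)))
    if ((allstalled && nbound < 2) ||
        sys$t - sys$phase_start > sys$ctl$max_phase_time) {
      log_event(sys, "protrusion_failed")
      retract_globally(sys)
      break
    }
  }
  sys$prots <- list()
  success
}

#' Run a multi-cycle migration simulation
#'
#' Top-level driver: builds the system, runs the requested number of
#' motility cycles of the regime's mechanism, and collects per-cycle
#' metrics, the event log and periodic snapshots.
#'
#' @param regime a [regime_config()] or preset name (e.g. `"m2:T>E>N"`).
#' @param lattice an `ecm_lattice`, or `NULL` to generate one.
#' @param cycles number of motility cycles to attempt.
#' @param seed integer seed for protrusion placement and ejection kicks.
#' @param n_ecm lattice size used when `lattice` is `NULL` (60 = dense).
#' @param lattice_seed seed for lattice generation when `lattice` is
#'   `NULL`; defaults to `seed + 104729`.
#' @param control optional [sim_control()].
#' @param stop_after_success stop attempting further cycles once one has
#'   succeeded (used for single-passage measurements).
#' @return an object of class `cellmig`: list with `cycles` (per-cycle
#'   metric table), `events`, `snapshots`, `bound_snapshot`, initial and
#'   final configurations.
#' @export
run_simulation <- function(regime, lattice = NULL, cycles = 1, seed = 1,
                           n_ecm = 60, lattice_seed = seed + 104729L,
                           control = NULL, stop_after_success = FALSE) {
  if (is.character(regime)) regime <- load_preset(regime)
  if (is.null(lattice))
    lattice <- generate_ecm(n_ecm, seed = lattice_seed, k_ecm = regime$k_ecm)
  sys <- new_cell_system(regime, lattice, seed = seed, control = control)
  recs <- vector("list", cycles)
  for (cy in seq_len(cycles)) {
    sys$cycle <- cy
    sys$cycle_max_ecm <- 0
    sys$cycle_max_strain <- 0
    com0 <- colMeans(sys$xn)
    t0 <- sys$t; snap0 <- length(sys$snapshots)
    gap <- NULL
    success <- if (sys$mech == 1) run_cycle_m1(sys) else run_cycle_m2(sys)
    if (sys$mech == 2 && success) {
      bound_ev <- Filter(function(e) e$event == "bind" && e$cycle == cy,
                         sys$events)
      ids <- vapply(bound_ev, `[[`, numeric(1), "i2")
      if (length(ids) == 2) gap <- sys$lat$x0[ids, , drop = FALSE]
    }
    com1 <- colMeans(sys$xn)
    n_new <- length(sys$snapshots) - snap0
    asp <- if (n_new > 0)
      mean(vapply(sys$snapshots[snap0 + seq_len(n_new)], `[[`,
                  numeric(1), "aspect"))
    else aspect_ratio(sys$xc)
    recs[[cy]] <- data.frame(
      cycle = cy, mechanism = sys$mech, regime = sys$regime$label,
      success = success, t_start = t0, t_end = sys$t,
      com_x0 = com0[1], com_y0 = com0[2], com_x1 = com1[1], com_y1 = com1[2],
      distance = sqrt(sum((com1 - com0)^2)), dx = com1[1] - com0[1],
      mean_aspect = asp, max_ecm_disp = sys$cycle_max_ecm,
      max_ecm_strain = sys$cycle_max_strain,
      penetration = penetration_fraction(sys$xc, sys$xn, gap))
    if (stop_after_success && success) break
  }
  record_snapshot(sys)
  out <- list(regime = sys$regime, seed = seed, control = sys$ctl,
              lattice = lattice,
              cycles = do.call(rbind, recs[!vapply(recs, is.null, logical(1))]),
              events = do.call(rbind, sys$events),
              snapshots = sys$snapshots,
              bound_snapshot = sys$bound_snapshot,
              final = list(xc = sys$xc, xn = sys$xn, xe = sys$lat$x),
              t_end = sys$t)
  class(out) <- "cellmig"
  out
}

#' @export
print.cellmig <- function(x, ...) {
  cat("cell migration simulation (mechanism ", x$regime$mechanism,
      ", regime ", x$regime$label, ")\n", sep = "")
  cat(sprintf("  %d cycle(s), %d successful, final t = %.3f\n",
              nrow(x$cycles), sum(x$cycles$success), x$t_end))
  cat(sprintf("  total nuclear displacement: %.3f cell diameters\n",
              total_displacement(x)))
  invisible(x)
}

#' @export
summary.cellmig <- function(object, ...) {
  print(object)
  cat("\nper-cycle metrics:\n")
  print(object$cycles[, c("cycle", "success", "distance", "dx",
                          "mean_aspect", "max_ecm_disp", "penetration")])
  invisible(object$cycles)
}

#' Total nuclear center-of-mass displacement of a run
#'
#' Distance between the nucleus center of mass at the start of the first
#' cycle and at the end of the last.
#'
#' @param run a `cellmig` object.
#' @return scalar displacement (cell diameters).
#' @export
total_displacement <- function(run) {
  cyc <- run$cycles
  sqrt((cyc$com_x1[nrow(cyc)] - cyc$com_x0[1])^2 +
       (cyc$com_y1[nrow(cyc)] - cyc$com_y0[1])^2)
}

#' @export
plot.cellmig <- function(x, which = length(x$snapshots), ...) {
  sn <- x$snapshots[[which]]
  plot(rbind(sn$xc, sn$xe), type = "n", asp = 1, xlab = "x", ylab = "y",
       main = sprintf("t = %.2f (%s)", sn$t, x$regime$label), ...)
  points(x$lattice$x0, pch = 4, col = "grey40")
  points(sn$xe, pch = 19, col = "blue")
  polygon(sn$xc, border = "darkgreen")
  polygon(sn$xn, border = "magenta")
  invisible(x)
}
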