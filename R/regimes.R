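#' @name regime_presets
#' @title Named parameter regimes for the force-ordering study
#'
#' @description
#' The migration behaviour is organised by the ordering of three
#' characteristic force scales: T (cortical contractile tension, set by
#' the contracted-cortex stiffness), E (force to deform the ECM, set by
#' the ECM spring constant), and N (force to deform the nucleus, set by
#' the nuclear stiffness).  Stiffnesses are reported divided by the cell
#' size (pN/um^2), the relaxed cortex has stiffness 1 and the ECM spring
#' constant is 50 in every regime.  Presets are named
#' `"m<mechanism>:<ordering>"`, e.g. `"m1:T>E>N"` or `"m2:N>T>E"`; the
#' immobile regime (E > T, N > T) is also reachable as `"m1:stuck"` /
#' `"m2:stuck"`.
NULL

.regime_table <- list(
  m1 = list(
    "E>T,N>T" = c(k_n = 100, k_cr = 1),
    "T>E>N"   = c(k_n = 1,   k_cr = 100),
    "T>N>E"   = c(k_n = 10,  k_cr = 100),
    "N>T>E"   = c(k_n = 100, k_cr = 50),
    "E>T>N"   = c(k_n = 1,   k_cr = 1)
  ),
  m2 = list(
    "E>T,N>T" = c(k_n = 10,   k_cr = 1),
    "T>E>N"   = c(k_n = 0.1,  k_cr = 100),
    "T>N>E"   = c(k_n = 10,   k_cr = 100),
    "N>T>E"   = c(k_n = 1000, k_cr = 100),
    "E>T>N"   = c(k_n = 0.1,  k_cr = 10)
  )
)

#' Construct a regime configuration
#'
#' @param mechanism 1 (push-pull) or 2 (rear-squeezing).
#' @param label force-ordering label (one of the five studied orderings).
#' @param k_n nuclear stiffness (pN/um^2, cell-size-scaled).
#' @param k_cr contracted-cortex stiffness (pN/um^2).
#' @param k_cs relaxed-cortex stiffness (default 1).
#' @param k_ecm ECM spring constant (default 50).
#' @param rear_rest_length tangent rest length imposed on the contracting
#'   rear arc in mechanism 2 (default 0.1).
#' @return an object of class `regime_config`.
#' @export
regime_config <- function(mechanism, label, k_n, k_cr, k_cs = 1, k_ecm = 50,
                          rear_rest_length = 0.1) {
  stopifnot(mechanism %in% c(1, 2))
  if (any(c(k_n, k_cr, k_cs, k_ecm) <= 0)) stop("stiffnesses must be positive")
  structure(list(mechanism = as.integer(mechanism), label = label,
                 k_n = k_n, k_cr = k_cr, k_cs = k_cs, k_ecm = k_ecm,
                 rear_rest_length = rear_rest_length),
            class = "regime_config")
}

#' Load a named regime preset
#'
#' @param name preset name such as `"m1:T>E>N"`, `"m2:N>T>E"`,
#'   `"m1:stuck"` (alias for `"m1:E>T,N>T"`).
#' @return a [regime_config()].
#' @export
load_preset <- function(name) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  valid <- as.vector(outer(c("m1", "m2"),
                           c(names(.regime_table$m1), "stuck"),
                           paste, sep = ":"))
  if (length(parts) != 2 || !(parts[1] %in% c("m1", "m2")) ||
      !(parts[2] %in% c(names(.regime_table$m1), "stuck")))
    stop("unknown preset '", name, "'; valid presets are: ",
         paste(valid, collapse = ", "))
  mech <- if (parts[1] == "m1") 1L else 2L
  label <- if (parts[2] == "stuck") "E>T,N>T" else parts[2]
  v <- .regime_table[[parts[1]]][[label]]
  regime_config(mech, label, k_n = v[["k_n"]], k_cr = v[["k_cr"]])
}

#' List all regime presets
#'
#' @return data.frame of mechanism, label, nuclear and contracted-cortex
#'   stiffness for every preset.
#' @export
regime_presets <- function() {
  do.call(rbind, lapply(c("m1", "m2"), function(m) {
    do.call(rbind, lapply(names(.regime_table[[m]]), function(lb) {
      v <- .regime_table[[m]][[lb]]
      data.frame(mechanism = if (m == "m1") 1L else 2L, label = lb,
                 k_n = v[["k_n"]], k_cr = v[["k_cr"]], k_cs = 1, k_ecm = 50)
    }))
  }))
}

#' Physical duration of one simulation time unit
#'
#' The simulation normalizes viscosity, cell size and the net tension
#' scale; the corresponding physical time unit is
#' `viscosity * length / force_per_length`.  With the characteristic
#' values for a migrating cell (10 Pa.s, 10 um, net tension 10 pN/um)
#' one time unit is 10 seconds.
#'
#' @param viscosity_Pa_s fluid viscosity in Pa.s (default 10).
#' @param length_um characteristic cell size in um (default 10).
#' @param force_per_length_pN_um net tension scale in pN/um (default 10).
#' @return seconds per simulation time unit.
#' @export
time_unit_seconds <- function(viscosity_Pa_s = 10, length_um = 10,
                              force_per_length_pN_um = 10) {
  # 1 Pa.s = 1 pN.s/um^2, so the ratio is already in seconds
  viscosity_Pa_s * length_um / force_per_length_pN_um
}

#' Convert simulation time to physical seconds
#'
#' @param t simulation time (dimensionless units).
#' @param ... passed to [time_unit_seconds()].
#' @return time in seconds.
#' @export
physical_seconds <- function(t, ...) t * time_unit_seconds(...)
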