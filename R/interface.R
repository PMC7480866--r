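#' Build a full run configuration
#'
#' A run configuration names the regime preset (or explicit stiffnesses),
#' the lattice settings, discretization overrides, cycle count and seeds.
#' Unspecified fields take the study defaults.
#'
#' @param preset preset name such as `"m2:T>E>N"` (see [load_preset()]).
#' @param cycles motility cycles per run.
#' @param seed simulation seed.
#' @param n_ecm lattice size (20 sparse, 60 dense).
#' @param lattice_seed lattice seed (default `seed + 104729`).
#' @param control named list of [sim_control()] overrides.
#' @param out_dir output directory used by [run_bundle()].
#' @return list of class `run_config`.
#' @export
run_config <- function(preset, cycles = 4, seed = 1, n_ecm = 60,
                       lattice_seed = seed + 104729L, control = list(),
                       out_dir = NULL) {
  regime <- load_preset(preset)   # validates the preset name
  structure(list(preset = preset, mechanism = regime$mechanism,
                 cycles = cycles, seed = seed, n_ecm = n_ecm,
                 lattice_seed = lattice_seed, control = control,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Round-trips through [run_config()], so a re-read configuration resolves
#' to identical settings.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  v <- yaml::read_yaml(path)
  run_config(preset = v$preset, cycles = v$cycles, seed = v$seed,
             n_ecm = v$n_ecm, lattice_seed = v$lattice_seed,
             control = if (is.null(v$control)) list() else v$control,
             out_dir = v$out_dir)
}

resolve_control <- function(config) {
  do.call(sim_control, c(list(mechanism = config$mechanism), config$control))
}

#' Execute a configured run and write its output bundle
#'
#' Runs the simulation and, if an output directory is set, writes the
#' resolved configuration, the lattice tables, the event log, the
#' per-cycle metric table and a trajectory table of all snapshots.
#'
#' @param config a [run_config()].
#' @return the `cellmig` run, invisibly.
#' @export
run_bundle <- function(config) {
  ctl <- resolve_control(config)
  run <- run_simulation(config$preset, cycles = config$cycles,
                        seed = config$seed, n_ecm = config$n_ecm,
                        lattice_seed = config$lattice_seed, control = ctl)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(config$out_dir, "config.yaml"))
    write_ecm(run$lattice, file.path(config$out_dir, "ecm_nodes.tsv"),
              file.path(config$out_dir, "ecm_edges.tsv"))
    write.table(run$events, file.path(config$out_dir, "events.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(run$cycles, file.path(config$out_dir, "cycles.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    traj <- do.call(rbind, lapply(run$snapshots, function(sn) {
      rbind(data.frame(time = sn$t, body = "cortex",
                       node = seq_len(nrow(sn$xc)),
                       x = sn$xc[, 1], y = sn$xc[, 2]),
            data.frame(time = sn$t, body = "nucleus",
                       node = seq_len(nrow(sn$xn)),
                       x = sn$xn[, 1], y = sn$xn[, 2]),
            data.frame(time = sn$t, body = "ecm",
                       node = seq_len(nrow(sn$xe)),
                       x = sn$xe[, 1], y = sn$xe[, 2]))
    }))
    write.table(traj, file.path(config$out_dir, "trajectory.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(run)
}

#' Replicate sweep over seeds for one preset
#'
#' Runs `replicates` seeded simulations of a preset (matched lattices are
#' obtained by passing the same `seeds` to different presets) and returns
#' the combined per-cycle table plus summary statistics.
#'
#' @param preset preset name.
#' @param replicates number of replicate runs.
#' @param cycles cycles per run.
#' @param seeds explicit seed vector (default `1:replicates`).
#' @param n_ecm lattice size.
#' @param control optional [sim_control()] overrides as a named list.
#' @return list with `cycles` (table over replicates), `total` (per-run
#'   total displacement) and `summary` (mean and SEM of the totals).
#' @export
sweep_replicates <- function(preset, replicates = 8, cycles = 4,
                             seeds = seq_len(replicates), n_ecm = 60,
                             control = list()) {
  regime <- load_preset(preset)
  ctl <- do.call(sim_control, c(list(mechanism = regime$mechanism), control))
  runs <- lapply(seeds, function(s)
    run_simulation(preset, cycles = cycles, seed = s, n_ecm = n_ecm,
                   control = ctl))
  cyc <- do.call(rbind, lapply(seq_along(runs), function(i)
    cbind(seed = seeds[i], runs[[i]]$cycles)))
  tot <- vapply(runs, total_displacement, numeric(1))
  list(cycles = cyc, total = tot,
       summary = replicate_statistics(tot), runs = runs)
}

#' Run cycles until the first successful one
#'
#' Repeats motility cycles (as a single continuing simulation) until one
#' succeeds or `max_cycles` have been attempted, and returns the run
#' together with the metrics of the first successful cycle.  This mirrors
#' how single-passage quantities (displacement after "the" cycle,
#' penetration, maximum ECM displacement) are measured: unsuccessful
#' protrusion attempts do not move the cell and are not the quantity of
#' interest.
#'
#' @param preset preset name or [regime_config()].
#' @param seed simulation seed.
#' @param max_cycles cap on attempted cycles (default 6).
#' @param lattice optional `ecm_lattice`; generated from
#'   `lattice_seed` otherwise.
#' @param lattice_seed seed for lattice generation.
#' @param n_ecm lattice size.
#' @param control optional [sim_control()].
#' @return list with `run` (the `cellmig`), `cycle` (one-row data.frame of
#'   the first successful cycle, or `NULL` if none succeeded).
#' @export
run_until_success <- function(preset, seed = 1, max_cycles = 6,
                              lattice = NULL, lattice_seed = seed + 104729L,
                              n_ecm = 60, control = NULL) {
  run <- run_simulation(preset, lattice = lattice, cycles = max_cycles,
                        seed = seed, n_ecm = n_ecm,
                        lattice_seed = lattice_seed, control = control,
                        stop_after_success = TRUE)
  ok <- which(run$cycles$success)
  list(run = run,
       cycle = if (length(ok)) run$cycles[ok[1], , drop = FALSE] else NULL)
}
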