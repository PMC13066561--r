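#' Simulation parameters for Langevin dynamics
#'
#' Time is measured in CG time units (one unit ~ 0.05 ps, so the default
#' step of 0.2 units is ~0.01 ps). Friction is the collision frequency in
#' 1/time-unit; `gamma = 0` gives the velocity-Verlet (NVE) limit.
#'
#' @param dt time step, CG units.
#' @param n_steps number of integration steps (>= 1).
#' @param temperature thermostat target, K.
#' @param gamma friction, 1/time-unit.
#' @param seed integer RNG seed (counter-based generator; identical seeds
#'   give bit-identical trajectories, and a saved step index restarts the
#'   stream exactly).
#' @param save_interval store a frame every this many steps.
#' @param equilibration_steps leading segment flagged for exclusion from
#'   analysis.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(dt = 0.2, n_steps = 10000, temperature = 300,
                              gamma = 0.25, seed = 1, save_interval = 100,
                              equilibration_steps = 10000) {
  stopifnot(dt > 0, n_steps >= 1, save_interval >= 1)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 temperature = temperature, gamma = gamma,
                 seed = seed, save_interval = as.integer(save_interval),
                 equilibration_steps = as.integer(equilibration_steps)),
            class = "simulation_params")
}

#' Run Langevin dynamics (BAOAB splitting)
#'
#' Integrates the coarse-grained equations of motion in the NVT ensemble
#' with the BAOAB splitting of the Langevin equation. The thermal noise is a
#' counter-based function of (seed, absolute step, bead); two runs with the
#' same seed and inputs are bit-identical, and a run restarted from a saved
#' frame + velocities + step index reproduces the continuation exactly.
#'
#' @param topology a `cg_topology` with charges assigned.
#' @param initial_state n x 3 coordinates (default: topology coordinates).
#' @param params a [simulation_params()].
#' @param ctx an [electrostatic_context()].
#' @param ff prebuilt [ff_tables()] (built from the topology if NULL).
#' @param velocities optional n x 3 initial velocities; default samples
#'   Maxwell-Boltzmann from the seed.
#' @param start_step absolute step index of the first step (for restarts).
#' @param nlist_every neighbor-list refresh interval, steps.
#' @param skin neighbor-list skin, Angstrom.
#' @return A `cg_trajectory`: coordinate frames (n x 3 x F, including the
#'   initial state as frame 1), step indices, times (ps), per-frame kinetic
#'   and potential energy, final velocities, seed and params.
#' @export
run_langevin <- function(topology, initial_state = NULL, params,
                         ctx = electrostatic_context(), ff = NULL,
                         velocities = NULL, start_step = 0,
                         nlist_every = 20, skin = 2.0) {
  if (is.null(ff)) ff <- ff_tables(topology, ctx)
  if (is.null(initial_state)) initial_state <- bead_positions(topology)
  initial_state <- as.matrix(initial_state)
  kT <- .kB * params$temperature
  if (is.null(velocities))
    velocities <- cg_sample_velocities_cpp(params$seed, ff$mass, kT)
  res <- cg_run_langevin_cpp(initial_state, velocities, ff,
                             params$dt, params$gamma, params$temperature,
                             params$n_steps, params$seed,
                             params$save_interval, start_step,
                             nlist_every, skin)
  n <- nrow(initial_state)
  nf <- length(res$steps)
  frames <- array(NA_real_, dim = c(n, 3, nf + 1))
  frames[, , 1] <- initial_state
  if (nf > 0) frames[, , 1 + seq_len(nf)] <- array(res$frames, c(n, 3, nf))
  steps <- c(start_step, res$steps)
  structure(list(
    frames = frames, steps = steps,
    time_ps = steps * params$dt * .time_unit_ps,
    kinetic = c(NA_real_, res$kinetic), potential = c(NA_real_, res$potential),
    final_pos = res$final_pos, final_vel = res$final_vel,
    final_step = res$final_step,
    seed = params$seed, params = params, topology = topology),
    class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", dim(x$frames)[1], " beads, ", dim(x$frames)[3],
      " frames (steps ", x$steps[1], "..", x$steps[length(x$steps)],
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a `cg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$frames)[3]

#' Frames to analyze after discarding equilibration
#'
#' @param trajectory a `cg_trajectory`.
#' @param equilibration_steps override; default from the trajectory params.
#' @return integer vector of frame indices.
#' @export
analysis_frames <- function(trajectory, equilibration_steps = NULL) {
  if (is.null(equilibration_steps))
    equilibration_steps <- trajectory$params$equilibration_steps
  which(trajectory$steps > equilibration_steps)
}

#' Run independent replicas
#'
#' Replica r uses seed `base_seed + r - 1`; everything else is identical, so
#' each replica is independently reproducible.
#'
#' @param topology a `cg_topology`.
#' @param params a [simulation_params()] (its seed field is ignored).
#' @param n_replicas number of replicas (default 3).
#' @param base_seed first seed.
#' @param ... passed to [run_langevin()].
#' @return A `cg_replica_set`: list of trajectories plus the seeds.
#' @export
run_replicas <- function(topology, params, n_replicas = 3, base_seed = 1,
                         ...) {
  stopifnot(n_replicas >= 1)
  seeds <- base_seed + seq_len(n_replicas) - 1
  if (anyDuplicated(seeds)) stop("duplicate replica seeds")
  trajs <- lapply(seeds, function(s) {
    p <- params; p$seed <- s
    run_langevin(topology, params = p, ...)
  })
  structure(list(trajectories = trajs, seeds = seeds,
                 n_replicas = n_replicas),
            class = "cg_replica_set")
}

#' @export
print.cg_replica_set <- function(x, ...) {
  cat("<cg_replica_set> ", x$n_replicas, " replicas, seeds ",
      paste(x$seeds, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Kinetic temperature of a trajectory
#'
#' \eqn{T_{kin} = 2 KE / (3 N k_B)} averaged over the analyzed frames.
#'
#' @param trajectory a `cg_trajectory`.
#' @param frames frame indices (default: post-equilibration frames).
#' @return temperature, K.
#' @export
kinetic_temperature <- function(trajectory, frames = NULL) {
  if (is.null(frames)) frames <- analysis_frames(trajectory)
  n <- dim(trajectory$frames)[1]
  ke <- trajectory$kinetic[frames]
  mean(2 * ke / (3 * n * .kB), na.rm = TRUE)
}
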