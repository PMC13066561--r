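#' Write a topology to JSON
#'
#' Serialises the bead table, chains, bonded terms, contact sets and region
#' map to a single JSON document.
#'
#' @param topology a `cg_topology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  obj <- list(
    chains = topology$chains, beads = topology$beads,
    bonds = topology$bonds, angles = topology$angles,
    dihedrals = topology$dihedrals,
    native_contacts = topology$native_contacts,
    hbond_pairs = topology$hbond_pairs,
    base_pairs = topology$base_pairs, stacking = topology$stacking,
    region_map = topology$region_map, duplex = topology$duplex,
    params = topology$params)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a topology from JSON
#'
#' @param path file written by [write_topology_json()].
#' @return a `cg_topology`.
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tb <- function(x) if (is.null(x)) NULL else tibble::as_tibble(as.data.frame(x))
  topo <- list(
    chains = tb(obj$chains), beads = tb(obj$beads), bonds = tb(obj$bonds),
    angles = tb(obj$angles), dihedrals = tb(obj$dihedrals),
    native_contacts = tb(obj$native_contacts),
    hbond_pairs = tb(obj$hbond_pairs), base_pairs = tb(obj$base_pairs),
    stacking = tb(obj$stacking),
    region_map = if (is.null(obj$region_map)) NULL else
      list(bp = tb(obj$region_map$bp), tails = tb(obj$region_map$tails)),
    duplex = obj$duplex, params = obj$params)
  structure(topo, class = "cg_topology")
}

#' Write a trajectory as plain-text frames plus a JSON sidecar
#'
#' Coordinates go to a long-format CSV (`frame`, `bead_id`, `x`, `y`, `z`);
#' run metadata (seed, step indices, parameters) to `<path>.json`.
#'
#' @param trajectory a `cg_trajectory`.
#' @param path CSV output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  nf <- n_frames(trajectory)
  n <- dim(trajectory$frames)[1]
  df <- data.frame(
    frame = rep(seq_len(nf), each = n),
    bead_id = rep(seq_len(n), times = nf),
    x = as.numeric(trajectory$frames[, 1, ]),
    y = as.numeric(trajectory$frames[, 2, ]),
    z = as.numeric(trajectory$frames[, 3, ]))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(seed = trajectory$seed, steps = trajectory$steps,
               time_ps = trajectory$time_ps,
               params = unclass(trajectory$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV file (with `<path>.json` sidecar alongside).
#' @param topology the `cg_topology` the frames belong to.
#' @return a `cg_trajectory`.
#' @export
read_trajectory <- function(path, topology) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nf <- max(df$frame); n <- max(df$bead_id)
  frames <- array(NA_real_, c(n, 3, nf))
  ord <- order(df$frame, df$bead_id)
  frames[, 1, ] <- df$x[ord]; frames[, 2, ] <- df$y[ord]
  frames[, 3, ] <- df$z[ord]
  params <- do.call(simulation_params, meta$params[
    c("dt", "n_steps", "temperature", "gamma", "seed", "save_interval",
      "equilibration_steps")])
  structure(list(frames = frames, steps = meta$steps,
                 time_ps = meta$time_ps,
                 kinetic = rep(NA_real_, nf), potential = rep(NA_real_, nf),
                 final_pos = frames[, , nf], final_vel = NULL,
                 final_step = max(meta$steps), seed = meta$seed,
                 params = params, topology = topology),
            class = "cg_trajectory")
}

#' Read C-alpha reference coordinates from a PDB file
#'
#' Thin wrapper over bio3d: extracts per-chain C-alpha coordinates in the
#' layout [build_protein_chain()] expects.
#'
#' @param path PDB file.
#' @return tibble with `chain`, `residue_index`, `resid`, `x`, `y`, `z`.
#' @export
read_reference_calpha <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("bio3d is required to read PDB files")
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  tibble::tibble(chain = ca$chain, residue_index = ca$resno,
                 resid = ca$resid, x = ca$x, y = ca$y, z = ca$z)
}

#' Read a peak table (residue, hn, n[, multiplicity]) from CSV
#'
#' @param path CSV file.
#' @return tibble suitable for [csp_profile()].
#' @export
read_peak_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Read a kinetics series (time_s, intensity) from CSV
#'
#' @param path CSV file.
#' @return tibble suitable for [fit_exponential()].
#' @export
read_kinetics_series <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
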