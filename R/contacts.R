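#' Is a tail residue group in contact with a DNA group in one frame?
#'
#' Contact means any bead-bead distance between the two sets is below the
#' cutoff.
#'
#' @param frame n x 3 coordinate matrix.
#' @param residue_beads,bp_beads integer bead-id vectors (non-empty).
#' @param cutoff distance threshold, Angstrom.
#' @return logical.
#' @export
frame_contact <- function(frame, residue_beads, bp_beads, cutoff = 10) {
  if (length(residue_beads) == 0 || length(bp_beads) == 0)
    stop("bead sets must be non-empty")
  d <- .cross_dist(frame[residue_beads, , drop = FALSE],
                   frame[bp_beads, , drop = FALSE])
  any(d < cutoff)
}

# per-frame minimum distance between each tail residue bead and each bp
# group; returns an (n_res x n_bp) matrix of minima for one frame
.residue_bp_mindist <- function(frame, res_bead_list, bp_bead_list) {
  res_idx <- unlist(res_bead_list)
  bp_idx <- unlist(bp_bead_list)
  d <- .cross_dist(frame[res_idx, , drop = FALSE],
                   frame[bp_idx, , drop = FALSE])
  # collapse bead-level distances to group minima
  rgrp <- rep(seq_along(res_bead_list), lengths(res_bead_list))
  cgrp <- rep(seq_along(bp_bead_list), lengths(bp_bead_list))
  out <- matrix(Inf, length(res_bead_list), length(bp_bead_list))
  for (a in seq_along(res_bead_list)) {
    da <- d[rgrp == a, , drop = FALSE]
    colmin <- apply(da, 2, min)
    mins <- tapply(colmin, factor(cgrp, levels = seq_along(bp_bead_list)), min)
    out[a, ] <- as.numeric(mins)
  }
  out
}

#' Tail-residue versus base-pair contact occupancy map
#'
#' For each residue of a labelled tail and each bp of the duplex, the
#' percentage of analyzed frames in which the residue bead is within the
#' cutoff of any bead of the two paired nucleotides.
#'
#' @param trajectory a `cg_trajectory` whose topology has a region map with
#'   tail labels and a registered duplex.
#' @param tail tail label (row space of the map).
#' @param cutoff contact cutoff, Angstrom (default 10: beads are ~5-6 A
#'   apart, so this captures salt-bridge-scale proximity).
#' @param frames frame indices (default: post-equilibration frames).
#' @return A tibble of class `contact_map` in long format: `residue`, `bp`,
#'   `occupancy` (percent), with attributes `frame_count`, `cutoff`, `tail`.
#' @export
contact_heatmap <- function(trajectory, tail, cutoff = 10, frames = NULL) {
  topo <- trajectory$topology
  rm <- topo$region_map
  if (is.null(rm) || is.null(rm$tails)) stop("topology has no tail labels")
  tl <- rm$tails[rm$tails$label == tail, ]
  if (nrow(tl) != 1) stop("unknown tail label: ", tail)
  if (is.null(frames)) frames <- analysis_frames(trajectory)
  if (length(frames) == 0) stop("no analyzable frames")
  beads <- topo$beads
  res_range <- seq(tl$from, tl$to)
  res_beads <- lapply(res_range, function(r)
    beads$bead_id[beads$chain_id == tl$chain_id & beads$residue_index == r &
                    beads$bead_kind == "amino_acid"])
  bp_beads <- bp_bead_ids(topo)
  counts <- matrix(0, length(res_beads), length(bp_beads))
  for (f in frames) {
    md <- .residue_bp_mindist(trajectory$frames[, , f], res_beads, bp_beads)
    counts <- counts + (md < cutoff)
  }
  occ <- 100 * counts / length(frames)
  out <- tibble::tibble(
    residue = rep(res_range, times = ncol(occ)),
    bp = rep(seq_along(bp_beads), each = nrow(occ)),
    occupancy = as.numeric(occ))
  attr(out, "frame_count") <- length(frames)
  attr(out, "cutoff") <- cutoff
  attr(out, "tail") <- tail
  class(out) <- c("contact_map", class(out))
  out
}

#' Difference of two contact maps
#'
#' Element-wise `mapA - mapB` over matched (residue, bp) cells. Both maps
#' must share shape and cutoff.
#'
#' @param mapA,mapB `contact_map` tibbles.
#' @return tibble of class `difference_map` with column `delta` (percent
#'   points, in [-100, 100]).
#' @export
difference_map <- function(mapA, mapB) {
  if (!identical(attr(mapA, "cutoff"), attr(mapB, "cutoff")))
    stop("contact maps have different cutoffs")
  if (nrow(mapA) != nrow(mapB) ||
      !all(mapA$residue == mapB$residue & mapA$bp == mapB$bp))
    stop("contact maps have different shapes")
  out <- tibble::tibble(residue = mapA$residue, bp = mapA$bp,
                        delta = mapA$occupancy - mapB$occupancy)
  attr(out, "cutoff") <- attr(mapA, "cutoff")
  class(out) <- c("difference_map", class(out))
  out
}

#' Per-region tail contact percentages with replica statistics
#'
#' For each tail label and DNA region (core, proximal linker, distal
#' linker), the percentage of analyzed frames in which at least one tail
#' residue is within the cutoff of at least one bp of that region
#' (any-residue aggregation), averaged over replicas with the sample
#' standard deviation. A combined `linker_any` region (union of the two
#' linkers) is also reported.
#'
#' @param replicas a `cg_replica_set` (or a single `cg_trajectory`).
#' @param tails tail labels to analyze (default: all labelled tails).
#' @param cutoff contact cutoff, Angstrom.
#' @param frames frame indices per trajectory (default: post-equilibration).
#' @return A tibble of class `region_contact_summary`: `tail`, `region`,
#'   `mean`, `sd`, `n_replicas`, plus per-replica columns nested in
#'   attribute `per_replica`.
#' @export
region_percentages <- function(replicas, tails = NULL, cutoff = 10,
                               frames = NULL) {
  if (inherits(replicas, "cg_trajectory"))
    replicas <- structure(list(trajectories = list(replicas),
                               seeds = replicas$seed, n_replicas = 1),
                          class = "cg_replica_set")
  topo <- replicas$trajectories[[1]]$topology
  rm <- topo$region_map
  if (is.null(rm) || is.null(rm$bp)) stop("topology has no region map")
  if (is.null(tails)) tails <- rm$tails$label
  if (!all(tails %in% rm$tails$label))
    stop("unknown tail label: ",
         paste(setdiff(tails, rm$tails$label), collapse = ", "))
  bp_beads <- bp_bead_ids(topo)
  regions <- list(
    core = which(rm$bp$class == "core"),
    linker_proximal = which(rm$bp$class == "linker_proximal"),
    linker_distal = which(rm$bp$class == "linker_distal"))
  regions$linker_any <- c(regions$linker_proximal, regions$linker_distal)
  beads <- topo$beads
  per_rep <- list()
  for (r in seq_along(replicas$trajectories)) {
    tr <- replicas$trajectories[[r]]
    fr <- if (is.null(frames)) analysis_frames(tr) else frames
    if (length(fr) == 0) stop("no analyzable frames in replica ", r)
    for (tail in tails) {
      tl <- rm$tails[rm$tails$label == tail, ]
      tail_beads <- beads$bead_id[beads$chain_id == tl$chain_id &
                                    beads$residue_index >= tl$from &
                                    beads$residue_index <= tl$to &
                                    beads$bead_kind == "amino_acid"]
      for (reg in names(regions)) {
        bps <- regions[[reg]]
        if (length(bps) == 0) {
          pct <- 0
        } else {
          grp <- unlist(bp_beads[bps])
          hits <- vapply(fr, function(f)
            frame_contact(tr$frames[, , f], tail_beads, grp, cutoff), TRUE)
          pct <- 100 * mean(hits)
        }
        per_rep[[length(per_rep) + 1]] <- tibble::tibble(
          replica = r, seed = replicas$seeds[r], tail = tail,
          region = reg, percent = pct)
      }
    }
  }
  per_rep <- dplyr::bind_rows(per_rep)
  out <- per_rep |>
    dplyr::group_by(.data$tail, .data$region) |>
    dplyr::summarise(mean = mean(.data$percent),
                     sd = if (dplyr::n() > 1) stats::sd(.data$percent)
                          else NA_real_,
                     n_replicas = dplyr::n(), .groups = "drop")
  attr(out, "per_replica") <- per_rep
  attr(out, "cutoff") <- cutoff
  class(out) <- c("region_contact_summary", class(out))
  out
}

#' Write a contact map as TSV
#'
#' @param map a `contact_map` or `difference_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
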