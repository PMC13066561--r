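#' Specification of a toy chromatosome-like system
#'
#' A downscaled chromatosome surrogate: a duplex whose core section is bent
#' into a shallow superhelical arc around a rigid central anchor cluster (an
#' octamer surrogate), two straight tangent linkers (the pitch keeps them
#' from crossing), positively charged disordered tails anchored near the DNA
#' entry/exit points, and an optional linker histone-like chain (folded blob
#' bound near the proximal entry, short basic N-tail, long basic C-tail
#' reaching toward the distal exit). The geometry is sufficient for contact
#' logic and sign-level contact asymmetry, not a physical nucleosome.
#'
#' Default tails use the native H3 and H4 N-terminal tail sequences, the
#' H3-like pair anchored at the two DNA exit points (the proximal and
#' distal core/linker junctions), the H4-like pair on the core face.
#'
#' @param core_bp core base pairs (default 40).
#' @param linker_bp linker length per side (default 16).
#' @param wrap_turns fraction of a full turn the core arc covers.
#' @param tails list of tail specs: each a list with `label`, `sequence`
#'   (1-letter), `anchor` (one of "proximal_junction", "distal_junction",
#'   "core_face_proximal", "core_face_distal").
#' @param h1_like logical (default TRUE) or a list with `n_tail`, `globular`,
#'   `c_tail` sequences.
#' @param seed RNG seed for tail growth.
#' @param rise,twist duplex geometry.
#' @param junction_depth_bp how many base pairs inside the core the
#'   junction-anchored tails attach; controls how easily those tails reach
#'   the linkers (shallow anchors saturate linker contact, deep anchors
#'   starve it).
#' @return list of class `toy_system_spec`.
#' @export
toy_system_spec <- function(core_bp = 40, linker_bp = 16, wrap_turns = 0.8,
                            tails = NULL, h1_like = TRUE, seed = 1,
                            rise = 3.38, twist = 34.3,
                            junction_depth_bp = 5.5) {
  stopifnot(core_bp >= 1, linker_bp >= 0, wrap_turns > 0,
            junction_depth_bp > 0)
  if (is.null(tails)) {
    tails <- list(
      list(label = "H3_A", sequence = "ARTKQTARKSTGGKAPRKQLA",
           anchor = "distal_junction"),
      list(label = "H3_B", sequence = "ARTKQTARKSTGGKAPRKQLA",
           anchor = "proximal_junction"),
      list(label = "H4_A", sequence = "SGRGKGGKGLGKGGAKRHRK",
           anchor = "core_face_distal"),
      list(label = "H4_B", sequence = "SGRGKGGKGLGKGGAKRHRK",
           anchor = "core_face_proximal"))
  }
  if (isTRUE(h1_like)) {
    h1_like <- list(n_tail = "ASKKSTKKA",
                    globular = "GAGSAGLAGSAG",
                    c_tail = "KKAKSPKKAKAAKPKKAAKSPAKKAKSPKKAKAAKPKKAKSPKKAAKK")
  }
  structure(list(core_bp = core_bp, linker_bp = linker_bp,
                 wrap_turns = wrap_turns, tails = tails, h1_like = h1_like,
                 seed = seed, rise = rise, twist = twist,
                 junction_depth_bp = junction_depth_bp),
            class = "toy_system_spec")
}

#' Build a toy chromatosome-like system
#'
#' Constructs the bead system described by [toy_system_spec()]: bent duplex
#' with measured (structure-based) bonded reference values, rigid anchor
#' cluster Go-bonded to the core DNA, disordered tails grown by a seeded
#' self-avoiding walk, optional linker histone-like chain bound at the
#' proximal linker. Charges are assigned, the region map is classified
#' (core vs proximal/distal linker on the side the H1-like chain occupies),
#' and tail labels are registered. Deterministic given the seed.
#'
#' @param spec a [toy_system_spec()].
#' @return list with `topology` (a `cg_topology`) and `state` (the initial
#'   coordinates, n x 3).
#' @export
make_toy_chromatosome <- function(spec = toy_system_spec()) {
  L <- spec$core_bp + 2 * spec$linker_bp
  seq_chars <- c("A", "C", "G", "T")
  rng <- .counter_rng(spec$seed * 7919 + 13)
  dna_seq <- paste(seq_chars[1 + floor((vapply(seq_len(L), function(i)
    (rng() + 1) / 2, 1.0)) * 3.9999)], collapse = "")
  duplex <- generate_bdna(dna_seq, rise = spec$rise, twist = spec$twist)

  # --- bend the straight helix axis onto linker / superhelical arc /
  #     linker; the pitch lifts the exit linker out of the entry plane so
  #     the two linkers never cross -------------------------------------
  Lp <- spec$linker_bp * spec$rise               # proximal linker length
  Lc <- spec$core_bp * spec$rise                 # core arc length
  theta_tot <- 2 * pi * spec$wrap_turns
  R <- Lc / theta_tot
  pitch <- 30                                    # total z rise over the arc
  cp <- pitch / theta_tot
  tnorm <- sqrt(R^2 + cp^2)
  curve <- function(s) {
    # returns list(point, tangent, normal); arc centered on the z axis
    if (s <= Lp) {
      # straight proximal linker approaching the arc start tangentially
      tang <- c(0, R, cp) / tnorm
      list(p = c(R, 0, 0) + (s - Lp) * tang, t = tang, n = c(1, 0, 0))
    } else if (s <= Lp + Lc) {
      a <- (s - Lp) / R
      list(p = c(R * cos(a), R * sin(a), cp * a),
           t = c(-R * sin(a), R * cos(a), cp) / tnorm,
           n = c(cos(a), sin(a), 0))
    } else {
      a1 <- theta_tot
      tang <- c(-R * sin(a1), R * cos(a1), cp) / tnorm
      list(p = c(R * cos(a1), R * sin(a1), cp * a1) + (s - Lp - Lc) * tang,
           t = tang, n = c(cos(a1), sin(a1), 0))
    }
  }
  bend_chain <- function(ch) {
    b <- ch$beads
    for (r in seq_len(nrow(b))) {
      s <- b$z[r]
      off <- c(b$x[r], b$y[r])
      fr <- curve(s)
      bnorm <- c(fr$n[2] * fr$t[3] - fr$n[3] * fr$t[2],
                 fr$n[3] * fr$t[1] - fr$n[1] * fr$t[3],
                 fr$n[1] * fr$t[2] - fr$n[2] * fr$t[1])
      p <- fr$p + off[1] * fr$n + off[2] * bnorm
      b$x[r] <- p[1]; b$y[r] <- p[2]; b$z[r] <- p[3]
    }
    ch$beads <- b
    ch
  }
  duplex$watson <- bend_chain(duplex$watson)
  duplex$crick <- bend_chain(duplex$crick)

  # --- anchor cluster (octamer surrogate), on the inside of the arc -------
  n_anchor <- max(4L, spec$core_bp %/% 5L)
  svals <- Lp + Lc * (seq_len(n_anchor) - 0.5) / n_anchor
  anchor_beads <- t(vapply(svals, function(s) {
    fr <- curve(s); fr$p - 14 * fr$n
  }, numeric(3)))
  anchor <- structure(list(
    chain_id = "ANCHOR", molecule_kind = "protein",
    sequence = paste(rep("G", n_anchor), collapse = ""),
    beads = tibble::tibble(
      bead_id = seq_len(n_anchor), residue_index = seq_len(n_anchor),
      bead_kind = "amino_acid", residue_name = "GLY",
      x = anchor_beads[, 1], y = anchor_beads[, 2], z = anchor_beads[, 3],
      disordered = FALSE)), class = "cg_chain")

  # tail attachment sites: offset out of the wrapping plane (below for the
  # proximal-side tails, above for the distal-side ones) so the grown tails
  # start clear of the DNA and of the anchor ring
  tail_site <- function(s, dz) {
    fr <- curve(s)
    list(origin = fr$p + c(0, 0, 14 * dz), dir = c(0, 0, dz))
  }
  # junction sites sit well inside the core so linker contact is a reach
  # excursion (not guaranteed by anchoring); core-face sites are nearby so
  # the two tail types compete for the same core patch
  jd <- spec$junction_depth_bp * spec$rise
  anchor_pos <- list(
    proximal_junction = tail_site(Lp + jd, -1),
    distal_junction = tail_site(Lp + Lc - jd, +1),
    core_face_proximal = tail_site(Lp + 0.25 * Lc, -1),
    core_face_distal = tail_site(Lp + 0.75 * Lc, +1))

  chains <- list(duplex$watson, duplex$crick, anchor)
  tail_rows <- list()
  occupied <- rbind(as.matrix(duplex$watson$beads[, c("x", "y", "z")]),
                    as.matrix(duplex$crick$beads[, c("x", "y", "z")]),
                    anchor_beads)
  for (k in seq_along(spec$tails)) {
    tl <- spec$tails[[k]]
    site <- anchor_pos[[tl$anchor]]
    ch <- build_protein_chain(tl$sequence, chain_id = tl$label,
                              origin = site$origin, direction = site$dir,
                              seed = spec$seed * 131 + k,
                              avoid = occupied)
    chains[[length(chains) + 1]] <- ch
    occupied <- rbind(occupied, as.matrix(ch$beads[, c("x", "y", "z")]))
    tail_rows[[length(tail_rows) + 1]] <- tibble::tibble(
      label = tl$label, chain_id = tl$label, from = 1L,
      to = nchar(tl$sequence))
  }

  has_h1 <- is.list(spec$h1_like)
  if (has_h1) {
    h1 <- spec$h1_like
    nn <- nchar(h1$n_tail); ng <- nchar(h1$globular); ncn <- nchar(h1$c_tail)
    h1_seq <- paste0(h1$n_tail, h1$globular, h1$c_tail)
    # folded blob beside the middle of the proximal linker (the side the
    # linker histone engages), leaving the proximal junction itself free
    blob_center <- curve(0.5 * Lp)$p + c(14, 0, 0)
    # compact helical clump for the globular residues
    gcoords <- t(vapply(seq_len(ng), function(i) {
      ang <- i * 100 * pi / 180
      blob_center + c(4.5 * cos(ang), 4.5 * sin(ang), (i - ng / 2) * 1.2)
    }, numeric(3)))
    # C-tail laid out from the blob across the top of the core wrap and
    # down onto the distal junction corridor / first distal-linker turns;
    # N-tail along the outer face of the proximal linker up to the blob.
    # This encodes the linker-histone arrangement the toy is meant to
    # express: the long basic C-tail engages core + distal linker (coating
    # the corridor through which the distal junction tail would reach its
    # linker), while the short N-tail stays on the proximal linker without
    # blocking the proximal junction.
    ex <- curve(Lp + Lc)
    frj <- curve(Lp + Lc - jd)
    vj <- frj$n + c(0, 0, 1)
    vj <- vj / sqrt(sum(vj^2))
    Ld <- spec$linker_bp * spec$rise
    occ_h1 <- rbind(occupied, gcoords)
    uz <- c(0, 0, 1) - ex$t[3] * ex$t
    uz <- uz / sqrt(sum(uz^2))
    ccoords <- .walk_path(rbind(blob_center + c(0, 0, 8),
                                frj$p + 14 * vj,
                                ex$p + 14 * vj,
                                ex$p + 0.35 * Ld * ex$t + 14 * vj,
                                ex$p + 0.35 * Ld * ex$t + 14 * uz,
                                ex$p + 14 * uz,
                                ex$p + 14 * ex$n,
                                ex$p + 0.35 * Ld * ex$t + 14 * ex$n),
                          ncn, 3.8)
    ccoords <- .declash(ccoords, occ_h1, self_d = 5)
    ncoords <- .walk_path(rbind(curve(0.1 * Lp)$p + c(14, 0, 0),
                                blob_center + c(8, 0, 0)),
                          nn, 3.8)
    ncoords <- .declash(ncoords, rbind(occ_h1, ccoords))
    ref <- tibble::tibble(
      residue_index = seq_len(nn + ng + ncn),
      x = c(ncoords[, 1], gcoords[, 1], ccoords[, 1]),
      y = c(ncoords[, 2], gcoords[, 2], ccoords[, 2]),
      z = c(ncoords[, 3], gcoords[, 3], ccoords[, 3]))
    h1_chain <- build_protein_chain(
      h1_seq, reference_coords = ref,
      disordered_ranges = list(seq_len(nn), nn + ng + seq_len(ncn)),
      chain_id = "H1", seed = spec$seed * 977 + 5)
    chains[[length(chains) + 1]] <- h1_chain
    tail_rows[[length(tail_rows) + 1]] <- tibble::tibble(
      label = "H1_N", chain_id = "H1", from = 1L, to = nn)
    tail_rows[[length(tail_rows) + 1]] <- tibble::tibble(
      label = "H1_GD", chain_id = "H1", from = nn + 1L, to = nn + ng)
    tail_rows[[length(tail_rows) + 1]] <- tibble::tibble(
      label = "H1_C", chain_id = "H1", from = nn + ng + 1L,
      to = nn + ng + ncn)
  }

  topo <- cg_topology(chains)
  topo <- add_duplex_terms(topo, "DNA_W", "DNA_C")
  # tether each tail's first residue to its nearest anchor-cluster bead
  pos_all <- bead_positions(topo)
  anchor_ids <- topo$beads$bead_id[topo$beads$chain_id == "ANCHOR"]
  for (tl in spec$tails) {
    first <- topo$beads$bead_id[topo$beads$chain_id == tl$label &
                                  topo$beads$residue_index == 1]
    d <- sqrt(rowSums(sweep(pos_all[anchor_ids, , drop = FALSE], 2,
                            pos_all[first, ])^2))
    near <- anchor_ids[which.min(d)]
    topo$bonds <- dplyr::bind_rows(
      topo$bonds,
      tibble::tibble(i = near, j = first, r0 = min(d),
                     k = topo$params$bond_k))
  }
  # hold the wrap: strong contacts anchor<->core DNA and anchor<->anchor,
  # plus the H1 blob onto the proximal linker / dyad region
  topo <- detect_native_contacts(topo, cutoff = 18, epsilon = 1.0)
  nc <- topo$native_contacts
  beads <- topo$beads
  keep <- rep(FALSE, nrow(nc))
  ischain <- function(ids, ch) beads$chain_id[ids] %in% ch
  keep <- (ischain(nc$i, "ANCHOR") | ischain(nc$j, "ANCHOR")) |
    ((ischain(nc$i, "H1") & !beads$disordered[nc$i]) |
       (ischain(nc$j, "H1") & !beads$disordered[nc$j]))
  topo$native_contacts <- nc[keep, , drop = FALSE]
  topo <- assign_charges(topo)
  topo <- classify_dna_regions(
    topo, core_bp = spec$linker_bp + seq_len(spec$core_bp),
    h1_proximal_side = "left")
  topo <- define_tails(topo, dplyr::bind_rows(tail_rows))
  list(topology = topo, state = bead_positions(topo))
}

# push points radially off the nearest occupied bead until all clear min_d;
# self_d additionally keeps non-neighbouring points of the path itself apart
.declash <- function(coords, occupied, min_d = 5, iters = 40, self_d = 0) {
  occ <- as.matrix(occupied)
  for (it in seq_len(iters)) {
    moved <- FALSE
    for (r in seq_len(nrow(coords))) {
      d2 <- rowSums(sweep(occ, 2, coords[r, ])^2)
      j <- which.min(d2)
      d <- sqrt(d2[j])
      if (d < min_d) {
        dir <- if (d < 1e-6) c(0, 0, 1) else (coords[r, ] - occ[j, ]) / d
        coords[r, ] <- occ[j, ] + dir * min_d
        moved <- TRUE
      }
      if (self_d > 0 && r > 2) {
        prev <- coords[seq_len(r - 2), , drop = FALSE]
        d2p <- rowSums(sweep(prev, 2, coords[r, ])^2)
        jp <- which.min(d2p)
        dp <- sqrt(d2p[jp])
        if (dp < self_d) {
          dir <- if (dp < 1e-6) c(0, 0, 1) else (coords[r, ] - prev[jp, ]) / dp
          coords[r, ] <- prev[jp, ] + dir * self_d
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  coords
}

# equally spaced points (step apart) along a polyline of waypoints,
# extrapolating along the final segment when the path runs out
.walk_path <- function(waypoints, n, step = 3.8) {
  wp <- as.matrix(waypoints)
  segs <- diff(wp)
  lens <- sqrt(rowSums(segs^2))
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  last_dir <- segs[nrow(segs), ] / lens[length(lens)]
  t(vapply(seq_len(n) - 1, function(k) {
    s <- k * step
    if (s >= total) return(wp[nrow(wp), ] + (s - total) * last_dir)
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    wp[i, ] + (s - cum[i]) / lens[i] * segs[i, ]
  }, numeric(3)))
}

#' Scripted trajectory with exact prescribed contact occupancies
#'
#' Builds frames deterministically (no sampling): for each scheduled
#' (tail, region) pair with target occupancy q over F frames, exactly
#' round(qF) frames place a designated tail bead at half the cutoff from a
#' bead in the middle of the region; in all other frames every tail is
#' parked far from the DNA (three cutoffs and beyond), so realized
#' occupancy equals the target exactly at the analysis cutoff.
#'
#' Schedules whose per-tail occupancies sum to more than 1 are rejected as
#' infeasible (a tail is placed at one region per frame).
#'
#' @param topology a `cg_topology` with region map and tail labels (e.g.
#'   from [make_toy_chromatosome()]).
#' @param schedule data frame with columns `tail`, `region` (one of "core",
#'   "linker_proximal", "linker_distal"), `occupancy` in [0, 1].
#' @param n_frames number of frames.
#' @param cutoff the analysis cutoff the placements are tuned to, Angstrom.
#' @param seed kept for interface symmetry; construction is deterministic.
#' @return a `cg_trajectory` (equilibration 0, save interval 1).
#' @export
make_scripted_trajectory <- function(topology, schedule, n_frames = 100,
                                     cutoff = 10, seed = 1) {
  rm <- topology$region_map
  if (is.null(rm) || is.null(rm$bp)) stop("topology has no region map")
  sch <- tibble::as_tibble(schedule)
  stopifnot(all(c("tail", "region", "occupancy") %in% names(sch)))
  if (any(sch$occupancy < 0 | sch$occupancy > 1))
    stop("occupancies must lie in [0, 1]")
  if (!all(sch$tail %in% rm$tails$label))
    stop("schedule references unknown tail")
  if (!all(sch$region %in% c("core", "linker_proximal", "linker_distal")))
    stop("schedule references unknown region")
  bad <- sch |> dplyr::group_by(.data$tail) |>
    dplyr::summarise(tot = sum(round(.data$occupancy * n_frames)) / n_frames)
  if (any(bad$tot > 1 + 1e-9))
    stop("infeasible schedule: per-tail occupancies exceed 1")

  beads <- topology$beads
  pos0 <- bead_positions(topology)
  center <- colMeans(pos0[beads$bead_kind != "amino_acid", , drop = FALSE])
  bp_beads <- bp_bead_ids(topology)

  # parking spot per tail: far from all DNA, distinct per tail
  tails <- rm$tails
  park <- function(k) center + c(0, 0, 1000 + 200 * k)
  # region target bead: middle bp of the region, sugar-ish first bead
  region_target <- function(region) {
    bps <- which(rm$bp$class == region)
    mid <- bps[ceiling(length(bps) / 2)]
    ids <- bp_beads[[mid]]
    ids[1]
  }

  frames <- array(NA_real_, dim = c(nrow(pos0), 3, n_frames))
  for (f in seq_len(n_frames)) frames[, , f] <- pos0

  # park all tail beads in all frames first
  for (k in seq_len(nrow(tails))) {
    ids <- beads$bead_id[beads$chain_id == tails$chain_id[k] &
                           beads$residue_index >= tails$from[k] &
                           beads$residue_index <= tails$to[k]]
    spot <- park(k)
    for (f in seq_len(n_frames)) {
      frames[ids, 1, f] <- spot[1] + 2 * seq_along(ids)
      frames[ids, 2, f] <- spot[2]
      frames[ids, 3, f] <- spot[3]
    }
  }

  # allocate contact frames per tail sequentially (non-overlapping blocks)
  sch <- sch[order(sch$tail, sch$region), ]
  next_free <- stats::setNames(rep(1L, nrow(tails)), tails$label)
  for (r in seq_len(nrow(sch))) {
    tl <- tails[tails$label == sch$tail[r], ]
    ids <- beads$bead_id[beads$chain_id == tl$chain_id &
                           beads$residue_index >= tl$from &
                           beads$residue_index <= tl$to]
    n_contact <- round(sch$occupancy[r] * n_frames)
    if (n_contact == 0) next
    tgt <- region_target(sch$region[r])
    tgt_pos <- pos0[tgt, ]
    outward <- tgt_pos - center
    outward <- outward / max(sqrt(sum(outward^2)), 1e-9)
    probe <- ids[length(ids)]
    f0 <- next_free[sch$tail[r]]
    fr_idx <- seq(f0, f0 + n_contact - 1)
    if (max(fr_idx) > n_frames) stop("infeasible schedule: frame overflow")
    next_free[sch$tail[r]] <- f0 + n_contact
    for (f in fr_idx) {
      # string the tail outward from the target; probe bead at cutoff/2
      shifts <- cutoff * 3 + 2 * seq_along(ids)
      frames[ids, 1, f] <- tgt_pos[1] + outward[1] * shifts
      frames[ids, 2, f] <- tgt_pos[2] + outward[2] * shifts
      frames[ids, 3, f] <- tgt_pos[3] + outward[3] * shifts
      frames[probe, 1:3, f] <- tgt_pos + outward * (cutoff * 0.5)
    }
  }

  params <- simulation_params(n_steps = n_frames, save_interval = 1,
                              equilibration_steps = 0, seed = seed)
  structure(list(
    frames = frames, steps = seq_len(n_frames),
    time_ps = seq_len(n_frames) * params$dt * .time_unit_ps,
    kinetic = rep(NA_real_, n_frames), potential = rep(NA_real_, n_frames),
    final_pos = frames[, , n_frames], final_vel = NULL,
    final_step = n_frames, seed = seed, params = params,
    topology = topology), class = "cg_trajectory")
}

#' Synthetic exponential decay series with Gaussian noise
#'
#' \eqn{I(t) = e^{-k t} + N(0, \sigma)}, renormalised so I(0) = 1 when
#' noise is present. Seeded and reproducible.
#'
#' @param k rate constant, 1/s (>= 0).
#' @param times time grid, s (strictly increasing, starting at 0).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed RNG seed.
#' @return tibble with `time_s`, `intensity` (class `kinetics_series`).
#' @export
make_decay_series <- function(k, times = seq(0, 4e5, length.out = 25),
                              noise_sd = 0, seed = 1) {
  stopifnot(k >= 0, noise_sd >= 0, length(times) >= 1)
  y <- exp(-k * times)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
    y <- y / y[1]
  }
  out <- tibble::tibble(time_s = as.numeric(times), intensity = y)
  class(out) <- c("kinetics_series", class(out))
  out
}
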