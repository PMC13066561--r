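#' Assemble a coarse-grained topology from chains
#'
#' Concatenates `cg_chain` objects into one bead table with global indices
#' and derives the intra-chain bonded terms (bonds, angles, dihedrals) with
#' reference values measured from the supplied coordinates, so the built
#' conformation is a local minimum of the bonded energy (structure-based
#' parameterisation). Angles/dihedrals that involve a disordered bead are
#' flagged `flexible` and later handled by the tabulated statistical
#' potential instead of harmonic restraints.
#'
#' For DNA strands the connectivity is P(i)-S(i), S(i)-B(i), S(i)-P(i+1)
#' with the backbone angle/dihedral set; for proteins, consecutive C-alpha
#' beads.
#'
#' @param chains list of `cg_chain` objects (order defines global indices).
#' @param bond_k,angle_k,dihedral_k harmonic force constants
#'   (kcal/mol/A^2, kcal/mol/rad^2, kcal/mol).
#' @return A `cg_topology` object: tibbles `beads`, `chains`, `bonds`,
#'   `angles`, `dihedrals`, plus empty `native_contacts`, `hbond_pairs`,
#'   `base_pairs`, `stacking` to be filled by the detection helpers.
#' @export
cg_topology <- function(chains, bond_k = 100, angle_k = 30, dihedral_k = 2) {
  stopifnot(length(chains) >= 1)
  offset <- 0L
  bead_rows <- list(); chain_rows <- list()
  bonds <- list(); angles <- list(); dihedrals <- list()
  for (ch in chains) {
    b <- ch$beads
    if (!"disordered" %in% names(b)) b$disordered <- FALSE
    b$chain_id <- ch$chain_id
    b$global_id <- offset + seq_len(nrow(b))
    bead_rows[[length(bead_rows) + 1]] <- b
    chain_rows[[length(chain_rows) + 1]] <- tibble::tibble(
      chain_id = ch$chain_id, molecule_kind = ch$molecule_kind,
      sequence = ch$sequence, n_beads = nrow(b))
    conn <- .chain_connectivity(b, ch$molecule_kind)
    bonds[[length(bonds) + 1]] <- conn$bonds
    angles[[length(angles) + 1]] <- conn$angles
    dihedrals[[length(dihedrals) + 1]] <- conn$dihedrals
    offset <- offset + nrow(b)
  }
  beads <- dplyr::bind_rows(bead_rows)
  beads <- tibble::tibble(
    bead_id = beads$global_id, chain_id = beads$chain_id,
    residue_index = beads$residue_index, bead_kind = beads$bead_kind,
    residue_name = beads$residue_name, base_charge = 0,
    x = beads$x, y = beads$y, z = beads$z, disordered = beads$disordered)
  topo <- structure(list(
    chains = dplyr::bind_rows(chain_rows),
    beads = beads,
    bonds = .with_cols(dplyr::bind_rows(bonds), c("i", "j")),
    angles = .with_cols(dplyr::bind_rows(angles),
                        c("i", "j", "k"), "flexible"),
    dihedrals = .with_cols(dplyr::bind_rows(dihedrals),
                           c("i", "j", "k", "l"), "flexible"),
    native_contacts = tibble::tibble(i = integer(), j = integer(),
                                     r0 = double(), epsilon = double()),
    hbond_pairs = tibble::tibble(i = integer(), j = integer(),
                                 r0 = double(), depth = double()),
    base_pairs = tibble::tibble(i = integer(), j = integer(), r0 = double()),
    stacking = tibble::tibble(i = integer(), j = integer(), r0 = double()),
    region_map = NULL, duplex = NULL,
    params = list(bond_k = bond_k, angle_k = angle_k, dihedral_k = dihedral_k)),
    class = "cg_topology")
  topo <- .measure_bonded(topo)
  topo
}

# connectivity index tuples for one chain (local ids + offset applied later
# via the global_id column already present in b)
.chain_connectivity <- function(b, kind) {
  gid <- b$global_id
  dis <- b$disordered
  bonds <- angles <- dihedrals <- NULL
  if (kind == "protein") {
    n <- nrow(b)
    if (n >= 2) bonds <- tibble::tibble(i = gid[1:(n - 1)], j = gid[2:n])
    if (n >= 3) angles <- tibble::tibble(
      i = gid[1:(n - 2)], j = gid[2:(n - 1)], k = gid[3:n],
      flexible = dis[1:(n - 2)] | dis[2:(n - 1)] | dis[3:n])
    if (n >= 4) dihedrals <- tibble::tibble(
      i = gid[1:(n - 3)], j = gid[2:(n - 2)], k = gid[3:(n - 1)], l = gid[4:n],
      flexible = dis[1:(n - 3)] | dis[2:(n - 2)] | dis[3:(n - 1)] | dis[4:n])
  } else {
    # DNA strand: per-residue bead ids
    res <- split(seq_len(nrow(b)), b$residue_index)
    L <- length(res)
    idx <- function(r, kindname) {
      k <- which(b$bead_kind[res[[r]]] == kindname)
      if (length(k) == 0) NA_integer_ else gid[res[[r]][k]]
    }
    P <- vapply(seq_len(L), idx, 1L, kindname = "phosphate")
    S <- vapply(seq_len(L), idx, 1L, kindname = "sugar")
    B <- vapply(seq_len(L), idx, 1L, kindname = "base")
    bb <- list(); aa <- list(); dd <- list()
    for (r in seq_len(L)) {
      if (!is.na(P[r])) bb[[length(bb) + 1]] <- c(P[r], S[r])
      bb[[length(bb) + 1]] <- c(S[r], B[r])
      if (r < L) bb[[length(bb) + 1]] <- c(S[r], P[r + 1])
      if (!is.na(P[r])) {
        aa[[length(aa) + 1]] <- c(P[r], S[r], B[r])
        if (r < L) aa[[length(aa) + 1]] <- c(P[r], S[r], P[r + 1])
      }
      if (r < L) {
        aa[[length(aa) + 1]] <- c(B[r], S[r], P[r + 1])
        aa[[length(aa) + 1]] <- c(S[r], P[r + 1], S[r + 1])
        if (!is.na(P[r]))
          dd[[length(dd) + 1]] <- c(P[r], S[r], P[r + 1], S[r + 1])
        if (r < L - 1)
          dd[[length(dd) + 1]] <- c(S[r], P[r + 1], S[r + 1], P[r + 2])
      }
    }
    tomat <- function(lst, nmcols) {
      if (length(lst) == 0) return(NULL)
      m <- do.call(rbind, lst)
      out <- tibble::as_tibble(as.data.frame(m))
      names(out) <- nmcols
      out
    }
    bonds <- tomat(bb, c("i", "j"))
    angles <- tomat(aa, c("i", "j", "k"))
    if (!is.null(angles)) angles$flexible <- FALSE
    dihedrals <- tomat(dd, c("i", "j", "k", "l"))
    if (!is.null(dihedrals)) dihedrals$flexible <- FALSE
  }
  list(bonds = bonds, angles = angles, dihedrals = dihedrals)
}

# guarantee index/flag columns exist even when no chain contributed terms
.with_cols <- function(df, int_cols, lgl_cols = character()) {
  for (nm in int_cols)
    if (!nm %in% names(df)) df[[nm]] <- integer()
  for (nm in lgl_cols)
    if (!nm %in% names(df)) df[[nm]] <- logical()
  df
}

# fill r0/theta0/phi0 from current coordinates
.measure_bonded <- function(topo) {
  pos <- bead_positions(topo)
  p <- topo$params
  b <- topo$bonds
  if (nrow(b)) {
    b$r0 <- sqrt(rowSums((pos[b$i, , drop = FALSE] - pos[b$j, , drop = FALSE])^2))
    b$k <- p$bond_k
  } else { b$r0 <- double(); b$k <- double() }
  a <- topo$angles
  if (nrow(a)) {
    a$theta0 <- .angles_of(pos, a$i, a$j, a$k)
    a$k_theta <- p$angle_k
  } else { a$theta0 <- double(); a$k_theta <- double() }
  d <- topo$dihedrals
  if (nrow(d)) {
    d$phi0 <- .dihedrals_of(pos, d$i, d$j, d$k, d$l)
    d$k_phi <- p$dihedral_k
  } else { d$phi0 <- double(); d$k_phi <- double() }
  topo$bonds <- b; topo$angles <- a; topo$dihedrals <- d
  topo
}

.angles_of <- function(pos, i, j, k) {
  a <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
  b <- pos[k, , drop = FALSE] - pos[j, , drop = FALSE]
  ct <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  acos(pmin(1, pmax(-1, ct)))
}

.dihedrals_of <- function(pos, i, j, k, l) {
  b1 <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
  b2 <- pos[k, , drop = FALSE] - pos[j, , drop = FALSE]
  b3 <- pos[l, , drop = FALSE] - pos[k, , drop = FALSE]
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(rowSums(b2^2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

#' Bead coordinates of a topology
#'
#' @param topology a `cg_topology`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
bead_positions <- function(topology) {
  as.matrix(topology$beads[, c("x", "y", "z")])
}

#' Replace bead coordinates
#'
#' @param topology a `cg_topology`.
#' @param pos n x 3 matrix.
#' @return The topology with updated coordinates (bonded reference values are
#'   not re-measured).
#' @export
set_bead_positions <- function(topology, pos) {
  stopifnot(nrow(pos) == nrow(topology$beads))
  topology$beads$x <- pos[, 1]; topology$beads$y <- pos[, 2]
  topology$beads$z <- pos[, 3]
  topology
}

#' Register duplex pairing and add base-pair/stacking terms
#'
#' Marks two DNA strands as a Watson/Crick duplex (nucleotide i of the
#' Watson strand pairs with nucleotide L+1-i of the Crick strand), and adds
#' Morse base-pairing wells between paired base beads plus intra-strand
#' stacking wells between consecutive base beads, with reference distances
#' measured from the current coordinates.
#'
#' @param topology a `cg_topology`.
#' @param watson,crick chain ids of the two strands.
#' @return The topology with `duplex`, `base_pairs` and `stacking` filled.
#' @export
add_duplex_terms <- function(topology, watson = "DNA_W", crick = "DNA_C") {
  beads <- topology$beads
  pos <- bead_positions(topology)
  wb <- beads[beads$chain_id == watson & beads$bead_kind == "base", ]
  cb <- beads[beads$chain_id == crick & beads$bead_kind == "base", ]
  L <- nrow(wb)
  stopifnot(L == nrow(cb), L >= 1)
  wi <- wb$bead_id[order(wb$residue_index)]
  ci <- cb$bead_id[order(cb$residue_index)]
  pair_j <- ci[L + 1 - seq_len(L)]
  bp <- tibble::tibble(i = wi, j = pair_j)
  bp$r0 <- sqrt(rowSums((pos[bp$i, , drop = FALSE] - pos[bp$j, , drop = FALSE])^2))
  st <- dplyr::bind_rows(
    if (L >= 2) tibble::tibble(i = wi[1:(L - 1)], j = wi[2:L]),
    if (L >= 2) tibble::tibble(i = ci[1:(L - 1)], j = ci[2:L]))
  if (!is.null(st) && nrow(st)) {
    st$r0 <- sqrt(rowSums((pos[st$i, , drop = FALSE] - pos[st$j, , drop = FALSE])^2))
  } else st <- tibble::tibble(i = integer(), j = integer(), r0 = double())
  topology$base_pairs <- bp
  topology$stacking <- st
  topology$duplex <- list(watson = watson, crick = crick, length = L)
  topology
}

#' Assign bead charges
#'
#' Applies the unit-charge rule: Lys/Arg +1 e, Asp/Glu -1 e, all other amino
#' acids 0; acetyl-lysine 0. Phosphate beads carry a base charge of -1 e;
#' the pair-context reduction (-0.6 e against DNA partners, -1.0 e against
#' protein partners, modelling counterion condensation vs release) is applied
#' at energy-evaluation time, not here. An optional table of fitted surface
#' charges may override folded (non-disordered) protein beads; the fitting
#' procedure it comes from is not applicable to disordered beads, so
#' referencing one is an error.
#'
#' @param topology a `cg_topology`.
#' @param respac_table optional data frame with columns `bead_id`, `charge`.
#' @return The topology with `base_charge` filled.
#' @export
assign_charges <- function(topology, respac_table = NULL) {
  beads <- topology$beads
  tab <- hps_parameters()
  q <- rep(0, nrow(beads))
  isaa <- beads$bead_kind == "amino_acid"
  q[isaa] <- tab$charge[match(beads$residue_name[isaa], tab$residue_name)]
  q[beads$bead_kind == "phosphate"] <- -1
  if (!is.null(respac_table)) {
    rt <- as.data.frame(respac_table)
    bad <- beads$disordered[rt$bead_id] | !isaa[rt$bead_id]
    if (any(bad))
      stop("surface-charge table references disordered or non-protein beads")
    q[rt$bead_id] <- rt$charge
  }
  topology$beads$base_charge <- q
  topology
}

#' Acetylate lysines in a chain
#'
#' Models N-epsilon acetylation in the coarse-grained representation: the
#' residue is renamed to acetyl-lysine (ALY) and its +1 e charge is removed;
#' all other interaction parameters are unchanged. Idempotent.
#'
#' @param topology a `cg_topology` (charges already assigned).
#' @param chain_id target protein chain.
#' @param positions residue indices to acetylate (must be Lys, or already
#'   acetyl-Lys).
#' @return The modified topology.
#' @examples
#' \dontrun{topo <- apply_acetylation(topo, "H4", c(5, 8, 12, 16))}
#' @export
apply_acetylation <- function(topology, chain_id, positions) {
  if (length(positions) == 0) return(topology)
  beads <- topology$beads
  sel <- beads$chain_id == chain_id & beads$residue_index %in% positions &
    beads$bead_kind == "amino_acid"
  if (sum(sel) != length(unique(positions)))
    stop("some positions not found in chain ", chain_id)
  rn <- beads$residue_name[sel]
  if (!all(rn %in% c("LYS", "ALY")))
    stop("acetylation target is not lysine at position(s) ",
         paste(beads$residue_index[sel][!rn %in% c("LYS", "ALY")], collapse = ", "))
  topology$beads$residue_name[sel] <- "ALY"
  topology$beads$base_charge[sel] <- 0
  topology
}

#' Detect native contacts from reference coordinates
#'
#' All structured (non-disordered) bead pairs closer than `cutoff` in the
#' reference conformation become attractive 12-10 contacts with the reference
#' distance as minimum position, excluding pairs on the same chain separated
#' by fewer than `chain_separation_min` residue positions. By default only
#' pairs involving at least one protein bead are considered (duplex DNA is
#' held by its own pairing/stacking terms).
#'
#' @param topology a `cg_topology`.
#' @param cutoff contact distance threshold, Angstrom.
#' @param chain_separation_min minimal same-chain residue separation.
#' @param epsilon uniform well depth, kcal/mol (overridable per contact by
#'   editing the returned table).
#' @param dna_dna include DNA-DNA pairs as well.
#' @return The topology with `native_contacts` filled (i < j, no duplicates).
#' @export
detect_native_contacts <- function(topology, cutoff = 6.5,
                                   chain_separation_min = 3,
                                   epsilon = 0.3, dna_dna = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  beads <- topology$beads
  pos <- bead_positions(topology)
  ok <- !beads$disordered
  idx <- which(ok)
  cand <- .pairs_within(pos, idx, cutoff)
  if (nrow(cand)) {
    same <- beads$chain_id[cand$i] == beads$chain_id[cand$j]
    sep <- abs(beads$residue_index[cand$i] - beads$residue_index[cand$j])
    keep <- !(same & sep < chain_separation_min)
    if (!dna_dna) {
      isp <- beads$bead_kind == "amino_acid"
      keep <- keep & (isp[cand$i] | isp[cand$j])
    }
    cand <- cand[keep, , drop = FALSE]
  }
  cand$epsilon <- rep(epsilon, nrow(cand))
  topology$native_contacts <- cand
  topology
}

# all pairs among idx with distance < cutoff; returns tibble(i, j, r0), i < j
.pairs_within <- function(pos, idx, cutoff) {
  if (length(idx) < 2)
    return(tibble::tibble(i = integer(), j = integer(), r0 = double()))
  sub <- pos[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(sub))
  hit <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  tibble::tibble(i = idx[hit[, 1]], j = idx[hit[, 2]],
                 r0 = d[hit])
}

#' Detect hydrogen-bond pairs between amino acids and DNA phosphates
#'
#' Structured amino-acid beads within `cutoff` of a phosphate bead in the
#' reference conformation get a distance-only Morse well (the angular
#' modulation of the full potential is omitted).
#'
#' @param topology a `cg_topology`.
#' @param cutoff detection distance, Angstrom.
#' @param depth well depth, kcal/mol.
#' @return The topology with `hbond_pairs` filled.
#' @export
detect_hbond_pairs <- function(topology, cutoff = 6.0, depth = 1.0) {
  beads <- topology$beads
  pos <- bead_positions(topology)
  aa <- which(beads$bead_kind == "amino_acid" & !beads$disordered)
  ph <- which(beads$bead_kind == "phosphate")
  out <- tibble::tibble(i = integer(), j = integer(), r0 = double())
  if (length(aa) && length(ph)) {
    d <- .cross_dist(pos[aa, , drop = FALSE], pos[ph, , drop = FALSE])
    hit <- which(d < cutoff, arr.ind = TRUE)
    out <- tibble::tibble(i = aa[hit[, 1]], j = ph[hit[, 2]],
                          r0 = d[hit])
  }
  out$depth <- rep(depth, nrow(out))
  topology$hbond_pairs <- out
  topology
}

# cross distance matrix between two coordinate sets
.cross_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Classify duplex base pairs into core and linker regions
#'
#' Partitions the base pairs of the registered duplex into nucleosome core,
#' proximal linker (the side the linker histone engages) and distal linker.
#'
#' @param topology a `cg_topology` with duplex terms added.
#' @param core_bp integer vector of bp indices forming the core (default:
#'   central 147 bp, or the whole duplex if shorter).
#' @param h1_proximal_side `"left"` (bp before the core) or `"right"`.
#' @return The topology with `region_map$bp` set; existing tail labels kept.
#' @export
classify_dna_regions <- function(topology, core_bp = NULL,
                                 h1_proximal_side = c("left", "right")) {
  side <- match.arg(h1_proximal_side)
  if (is.null(topology$duplex)) stop("no duplex registered")
  L <- topology$duplex$length
  if (is.null(core_bp)) {
    w <- min(147L, L)
    start <- (L - w) %/% 2 + 1L
    core_bp <- seq(start, start + w - 1L)
  }
  if (min(core_bp) < 1 || max(core_bp) > L)
    stop("core range exceeds duplex length")
  cls <- rep(NA_character_, L)
  cls[core_bp] <- "core"
  left <- seq_len(L) < min(core_bp)
  right <- seq_len(L) > max(core_bp)
  if (side == "left") {
    cls[left] <- "linker_proximal"; cls[right] <- "linker_distal"
  } else {
    cls[left] <- "linker_distal"; cls[right] <- "linker_proximal"
  }
  rm0 <- topology$region_map
  topology$region_map <- list(
    bp = tibble::tibble(bp = seq_len(L), class = cls),
    tails = if (!is.null(rm0)) rm0$tails else
      tibble::tibble(label = character(), chain_id = character(),
                     from = integer(), to = integer()))
  topology
}

#' Label histone-tail residue ranges
#'
#' @param topology a `cg_topology`.
#' @param tails data frame with columns `label`, `chain_id`, `from`, `to`
#'   (1-based residue ranges; must not overlap within a chain).
#' @return The topology with `region_map$tails` set.
#' @export
define_tails <- function(topology, tails) {
  tails <- tibble::as_tibble(tails)
  for (ch in unique(tails$chain_id)) {
    tt <- tails[tails$chain_id == ch, ]
    covered <- unlist(Map(seq, tt$from, tt$to))
    if (anyDuplicated(covered)) stop("tail ranges overlap within chain ", ch)
  }
  if (is.null(topology$region_map))
    topology$region_map <- list(bp = NULL, tails = NULL)
  topology$region_map$tails <- tails
  topology
}

#' Bead ids of the two paired nucleotides of a base pair
#'
#' Returns for each bp index the ids of all beads (up to six: phosphate,
#' sugar, base on both strands) of the paired nucleotides.
#'
#' @param topology a `cg_topology` with a registered duplex.
#' @return A list of integer vectors indexed by bp.
#' @export
bp_bead_ids <- function(topology) {
  du <- topology$duplex
  if (is.null(du)) stop("no duplex registered")
  beads <- topology$beads
  L <- du$length
  out <- vector("list", L)
  wb <- beads[beads$chain_id == du$watson, ]
  cb <- beads[beads$chain_id == du$crick, ]
  for (i in seq_len(L)) {
    out[[i]] <- c(wb$bead_id[wb$residue_index == i],
                  cb$bead_id[cb$residue_index == L + 1 - i])
  }
  out
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("<cg_topology> ", nrow(x$beads), " beads, ", nrow(x$chains),
      " chains\n", sep = "")
  cat("  bonds: ", nrow(x$bonds), ", angles: ", nrow(x$angles),
      ", dihedrals: ", nrow(x$dihedrals), "\n", sep = "")
  cat("  native contacts: ", nrow(x$native_contacts),
      ", hbond pairs: ", nrow(x$hbond_pairs),
      ", base pairs: ", nrow(x$base_pairs), "\n", sep = "")
  invisible(x)
}
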