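# Shared builders and a finite-difference force oracle used across tests.

# 10-bp duplex with pairing/stacking terms and charges (60 beads)
small_duplex <- function(sequence = "ATCGGACCCT") {
  d <- generate_bdna(sequence)
  topo <- cg_topology(list(d$watson, d$crick))
  topo <- add_duplex_terms(topo, "DNA_W", "DNA_C")
  assign_charges(topo)
}

# two short disordered peptides placed apart (10 beads): HPS + screened
# Coulomb dominated system with flexible local terms
peptide_pair <- function() {
  a <- build_protein_chain("KKRDE", chain_id = "PA", origin = c(0, 0, 0),
                           seed = 3)
  b <- build_protein_chain("EDKRK", chain_id = "PB", origin = c(9, 3, 0),
                           direction = c(0, 1, 0), seed = 4,
                           avoid = dplyr::select(a$beads, x, y, z))
  assign_charges(cg_topology(list(a, b)))
}

# 3-bp duplex + 8-residue peptide (3 structured residues docked near a
# phosphate, 5 disordered): 26 beads, every force-field term populated
composite_system <- function() {
  d <- generate_bdna("ACG")
  topo0 <- cg_topology(list(d$watson, d$crick))
  pos <- bead_positions(topo0)
  ph <- which(topo0$beads$bead_kind == "phosphate")
  anchor <- pos[ph[1], ]
  ref <- data.frame(residue_index = 1:3,
                    x = anchor[1] + c(5, 8.5, 12),
                    y = anchor[2] + c(2, 3, 2),
                    z = anchor[3] + c(0, 1.5, 3))
  prot <- build_protein_chain("KAERKDGS", reference_coords = ref,
                              chain_id = "P", seed = 4,
                              direction = c(1, 0, 0))
  topo <- cg_topology(list(d$watson, d$crick, prot))
  topo <- add_duplex_terms(topo, "DNA_W", "DNA_C")
  topo <- assign_charges(topo)
  topo <- detect_native_contacts(topo, cutoff = 9)
  detect_hbond_pairs(topo, cutoff = 8)
}

# jittered positions so no term sits exactly at its minimum
jittered_positions <- function(topology, sd = 0.3, seed = 2) {
  set.seed(seed)
  bead_positions(topology) +
    matrix(stats::rnorm(3 * nrow(topology$beads), 0, sd), ncol = 3)
}

ff_term_names <- c("bonds", "angles", "dihedrals", "flex_angles",
                   "flex_dihedrals", "contacts", "morse_bp", "morse_st",
                   "morse_hb")

# keep only the named interaction tables; empty out the rest
zero_ff_terms <- function(ff, keep = character()) {
  for (w in setdiff(ff_term_names, keep))
    ff[[w]] <- ff[[w]][0, , drop = FALSE]
  ff
}

disable_nonbonded <- function(ff) {
  ff$ctx$cutoff_elec <- 0.1
  ff$ctx$cutoff_other <- 0.1
  ff
}

# central-difference check of the analytic forces at random (bead, coord)
# probes; returns the maximum absolute error in kcal/mol/Angstrom
fd_max_error <- function(pos, ff, n_probe = 12, probe_seed = 5, h = 1e-5) {
  ef <- chromacg:::cg_energy_forces_cpp(pos, ff)
  set.seed(probe_seed)
  errs <- numeric(n_probe)
  for (t in seq_len(n_probe)) {
    i <- sample(nrow(pos), 1)
    dc <- sample(3, 1)
    pp <- pos; pp[i, dc] <- pp[i, dc] + h
    pm <- pos; pm[i, dc] <- pm[i, dc] - h
    fd <- -(chromacg:::cg_energy_forces_cpp(pp, ff)$energy[["total"]] -
              chromacg:::cg_energy_forces_cpp(pm, ff)$energy[["total"]]) /
      (2 * h)
    errs[t] <- abs(fd - ef$forces[i, dc])
  }
  max(errs)
}
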