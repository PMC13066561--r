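#' Debye length of a monovalent salt solution
#'
#' Closed-form screening length from ionic strength, temperature and
#' relative dielectric constant,
#' \eqn{\lambda_D = \sqrt{\epsilon_0 \epsilon_r k_B T / (2 N_A e^2 I)}}.
#'
#' @param ionic_strength mol/L.
#' @param temperature K.
#' @param eps_r relative dielectric constant.
#' @return Debye length in Angstrom (about 7.9 A at 150 mM, 300 K).
#' @export
debye_length <- function(ionic_strength = 0.150, temperature = 300,
                         eps_r = 78) {
  if (ionic_strength <= 0) stop("ionic strength must be positive")
  eps0 <- 8.8541878128e-12   # F/m
  kB <- 1.380649e-23         # J/K
  NA_ <- 6.02214076e23
  e <- 1.602176634e-19       # C
  I_m3 <- ionic_strength * 1000 * NA_   # ions/m^3 per species
  lam_m <- sqrt(eps0 * eps_r * kB * temperature / (2 * I_m3 * e^2))
  lam_m * 1e10
}

#' Electrostatic context for Debye-Hueckel interactions
#'
#' Collects the screened-Coulomb parameters: ionic strength, temperature,
#' dielectric constant, the derived Debye length, and the pair-context
#' phosphate charges (-0.6 e against DNA partners, modelling counterion
#' condensation along the backbone; -1.0 e against protein partners,
#' modelling counterion release on complex formation).
#'
#' @param ionic_strength mol/L (default 0.150).
#' @param temperature K (default 300).
#' @param eps_r relative dielectric constant (default 78, fixed).
#' @param phosphate_charge_intra_dna,phosphate_charge_protein_dna effective
#'   phosphate charges, e.
#' @param cutoff_elec electrostatic cutoff; default 5 Debye lengths.
#' @param cutoff_other cutoff for excluded volume/HPS, Angstrom.
#' @param ev_eps,ev_sigma excluded-volume strength (kcal/mol) and size (A).
#' @param hps_eps HPS pair-well depth, kcal/mol.
#' @return A list of class `electrostatic_context`.
#' @export
electrostatic_context <- function(ionic_strength = 0.150, temperature = 300,
                                  eps_r = 78,
                                  phosphate_charge_intra_dna = -0.6,
                                  phosphate_charge_protein_dna = -1.0,
                                  cutoff_elec = NULL, cutoff_other = 20,
                                  ev_eps = 0.2, ev_sigma = 4.0,
                                  hps_eps = 0.2) {
  lam <- debye_length(ionic_strength, temperature, eps_r)
  if (is.null(cutoff_elec)) cutoff_elec <- 5 * lam
  structure(list(
    ionic_strength = ionic_strength, temperature = temperature,
    eps_r = eps_r, lambda_D = lam,
    q_phos_dna = phosphate_charge_intra_dna,
    q_phos_protein = phosphate_charge_protein_dna,
    kcoul = .kcoul, cutoff_elec = cutoff_elec, cutoff_other = cutoff_other,
    ev_eps = ev_eps, ev_sigma = ev_sigma, hps_eps = hps_eps),
    class = "electrostatic_context")
}

#' Screened Coulomb (Debye-Hueckel) pair energy
#'
#' \eqn{U = C q_i q_j \exp(-r/\lambda_D) / (\epsilon_r r)} with C the
#' Coulomb constant in kcal A / (mol e^2). If `kind_i`/`kind_j` mark a bead
#' as a DNA phosphate, its charge is replaced by the pair-context value:
#' the intra-DNA charge when the partner is DNA, the protein-DNA charge
#' when the partner is protein.
#'
#' @param q_i,q_j bead charges, e (ignored for phosphates, which use the
#'   context rule).
#' @param r separation, Angstrom (> 0).
#' @param ctx an [electrostatic_context()].
#' @param kind_i,kind_j one of "protein", "phosphate", "dna" (sugar/base).
#' @return list with `energy` (kcal/mol) and `force` (kcal/mol/A, positive =
#'   repulsive, along the pair axis).
#' @export
debye_huckel_energy <- function(q_i, q_j, r, ctx = electrostatic_context(),
                                kind_i = "protein", kind_j = "protein") {
  if (any(r <= 0)) stop("r must be positive")
  dna_kinds <- c("phosphate", "dna")
  qi <- if (kind_i == "phosphate") {
    if (kind_j %in% dna_kinds) ctx$q_phos_dna else ctx$q_phos_protein
  } else q_i
  qj <- if (kind_j == "phosphate") {
    if (kind_i %in% dna_kinds) ctx$q_phos_dna else ctx$q_phos_protein
  } else q_j
  u <- ctx$kcoul * qi * qj * exp(-r / ctx$lambda_D) / (ctx$eps_r * r)
  f <- u * (1 / r + 1 / ctx$lambda_D)
  list(energy = u, force = f)
}

#' Ashbaugh-Hatch (HPS) pair energy
#'
#' Lennard-Jones 12-6 reshaped by the hydrophobicity weight lambda:
#' for \eqn{r \le 2^{1/6}\sigma}, \eqn{U = U_{LJ} + (1-\lambda)\epsilon};
#' beyond, \eqn{U = \lambda U_{LJ}}. lambda is the arithmetic mean of the
#' two residues' hydrophobicity values.
#'
#' @param r separation, Angstrom.
#' @param lambda pair hydrophobicity weight in [0, 1].
#' @param sigma pair size, Angstrom (> 0).
#' @param eps well depth, kcal/mol.
#' @return energy, kcal/mol.
#' @export
hps_pair_energy <- function(r, lambda, sigma, eps = 0.2) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(r <= 0)) stop("r must be positive")
  ulj <- 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  rc <- 2^(1 / 6) * sigma
  ifelse(r <= rc, ulj + (1 - lambda) * eps, lambda * ulj)
}

#' 12-10 structure-based (Go) contact energy
#'
#' \eqn{U = \epsilon (5 (r_0/r)^{12} - 6 (r_0/r)^{10})}: minimum value
#' \eqn{-\epsilon} at \eqn{r = r_0}, vanishing at large separation.
#'
#' @param r,r0 separation and native distance, Angstrom (> 0).
#' @param epsilon well depth, kcal/mol.
#' @return energy, kcal/mol.
#' @export
go_contact_energy <- function(r, r0, epsilon = 0.3) {
  if (any(r <= 0) || any(r0 <= 0)) stop("r and r0 must be positive")
  s <- r0 / r
  epsilon * (5 * s^12 - 6 * s^10)
}

#' Morse well (base pairing, stacking, hydrogen bonds)
#'
#' \eqn{U = D ((1 - e^{-\alpha (r - r_0)})^2 - 1)}: depth -D at r0, zero at
#' large separation.
#'
#' @param r,r0 separation and minimum position, Angstrom.
#' @param D well depth, kcal/mol.
#' @param alpha well width parameter, 1/Angstrom.
#' @return energy, kcal/mol.
#' @export
base_pair_energy <- function(r, r0, D = 4.0, alpha = 1.0) {
  if (any(r <= 0)) stop("r must be positive")
  D * ((1 - exp(-alpha * (r - r0)))^2 - 1)
}

#' Flexible-local statistical potential from a table
#'
#' Catmull-Rom interpolation of a tabulated potential: angle tables on
#' [0, pi] (clamped ends), dihedral tables periodic on [-pi, pi). This is
#' the reference (pure R) evaluation of the same interpolant used by the
#' simulation kernel.
#'
#' @param value angle (rad, wrapped into [0, pi]) or dihedral (rad).
#' @param table numeric vector of energy nodes on a uniform grid.
#' @param periodic TRUE for dihedrals.
#' @return energy, kcal/mol.
#' @export
flexible_local_energy <- function(value, table, periodic = FALSE) {
  nn <- length(table)
  if (periodic) {
    x0 <- -pi; x1 <- pi
    value <- ((value + pi) %% (2 * pi)) - pi
    ncell <- nn
  } else {
    x0 <- 0; x1 <- pi
    if (any(value < -1e-9 | value > pi + 1e-9))
      stop("angle outside [0, pi]")
    value <- pmin(pmax(value, 0), pi)
    ncell <- nn - 1
  }
  h <- (x1 - x0) / ncell
  vapply(value, function(x) {
    t <- (x - x0) / h
    k <- floor(t)
    if (periodic) k <- ((k %% ncell) + ncell) %% ncell
    else k <- min(max(k, 0), ncell - 1)
    u <- (x - (x0 + k * h)) / h
    node <- function(idx) {
      if (periodic) table[((idx %% nn) + nn) %% nn + 1]
      else table[min(max(idx, 0), nn - 1) + 1]
    }
    y0 <- node(k - 1); y1 <- node(k); y2 <- node(k + 1); y3 <- node(k + 2)
    0.5 * ((2 * y1) + (-y0 + y2) * u +
           (2 * y0 - 5 * y1 + 4 * y2 - y3) * u^2 +
           (-y0 + 3 * y1 - 3 * y2 + y3) * u^3)
  }, 1.0)
}

#' Default flexible-local tables for disordered polypeptide stretches
#'
#' A generic coil-statistics potential: a soft single well around the
#' typical C-alpha virtual bond angle (~1.9 rad) and a shallow periodic
#' dihedral profile. Amplitudes are of order kT so disordered tails stay
#' flexible.
#'
#' @param n_angle,n_dihedral number of table nodes.
#' @return list with `angle` and `dihedral` numeric vectors (kcal/mol).
#' @export
default_flexible_tables <- function(n_angle = 30, n_dihedral = 36) {
  th <- seq(0, pi, length.out = n_angle)
  angle <- 1.2 * ((th - 1.9) / 0.6)^2
  # steep walls near collinearity to keep the walk well-conditioned
  angle <- angle + 4 * exp(-(th / 0.35)^2) + 4 * exp(-((pi - th) / 0.25)^2)
  phi <- seq(-pi, pi, length.out = n_dihedral + 1)[1:n_dihedral]
  dihedral <- 0.3 * cos(phi) + 0.2 * cos(2 * phi)
  list(angle = angle, dihedral = dihedral)
}

#' Default per-bead masses (amu) by bead class
#'
#' @param topology a `cg_topology`.
#' @return numeric vector of masses.
#' @export
default_masses <- function(topology) {
  kind <- topology$beads$bead_kind
  m <- c(amino_acid = 110, phosphate = 95, sugar = 99, base = 126)
  unname(m[kind])
}

#' Build the evaluation tables for the simulation kernel
#'
#' Flattens a `cg_topology` plus an [electrostatic_context()] into the plain
#' arrays consumed by the compiled energy/force kernel, including the two
#' nonbonded exclusion sets: topological 1-2/1-3/1-4 neighbours (excluded
#' from all nonbonded terms) and pairs already covered by a specific term
#' (native contact, base pair, stacking, hydrogen bond; excluded from
#' excluded-volume and HPS but still screened-Coulomb interacting).
#'
#' @param topology a `cg_topology` with charges assigned.
#' @param ctx an [electrostatic_context()].
#' @param flexible_tables output of [default_flexible_tables()] or same
#'   shape.
#' @param masses per-bead masses; default by bead class.
#' @param morse_alpha width parameter shared by the Morse terms, 1/A.
#' @param bp_depth,stack_depth Morse depths for base pairing and stacking,
#'   kcal/mol.
#' @return An opaque list for [total_energy_forces()] and [run_langevin()].
#' @export
ff_tables <- function(topology, ctx = electrostatic_context(),
                      flexible_tables = default_flexible_tables(),
                      masses = NULL, morse_alpha = 1.0,
                      bp_depth = 4.0, stack_depth = 3.0) {
  beads <- topology$beads
  n <- nrow(beads)
  hp <- hps_parameters()
  mi <- match(beads$residue_name, hp$residue_name)
  hl <- ifelse(is.na(mi), 0, hp$hps_lambda[mi])
  hsig <- ifelse(is.na(mi), 0, hp$hps_sigma[mi])
  isaa <- beads$bead_kind == "amino_acid"
  hl[!isaa] <- 0; hsig[!isaa] <- 0
  if (is.null(masses)) masses <- default_masses(topology)

  a <- topology$angles; d <- topology$dihedrals
  harm_a <- a[!a$flexible, , drop = FALSE]
  flex_a <- a[a$flexible, , drop = FALSE]
  harm_d <- d[!d$flexible, , drop = FALSE]
  flex_d <- d[d$flexible, , drop = FALSE]

  bonds <- as.matrix(topology$bonds[, c("i", "j", "r0", "k")])
  if (nrow(bonds) == 0) bonds <- matrix(0, 0, 4)
  ang <- as.matrix(harm_a[, c("i", "j", "k", "theta0", "k_theta")])
  if (nrow(ang) == 0) ang <- matrix(0, 0, 5)
  dih <- as.matrix(harm_d[, c("i", "j", "k", "l", "phi0", "k_phi")])
  if (nrow(dih) == 0) dih <- matrix(0, 0, 6)
  fa <- if (nrow(flex_a)) cbind(as.matrix(flex_a[, c("i", "j", "k")]), 1L) else
    matrix(0L, 0, 4)
  fd <- if (nrow(flex_d)) cbind(as.matrix(flex_d[, c("i", "j", "k", "l")]), 1L) else
    matrix(0L, 0, 5)

  nc <- topology$native_contacts
  contacts <- if (nrow(nc)) as.matrix(nc[, c("i", "j", "r0", "epsilon")]) else
    matrix(0, 0, 4)
  bp <- topology$base_pairs
  morse_bp <- if (nrow(bp)) cbind(as.matrix(bp[, c("i", "j", "r0")]),
                                  bp_depth, morse_alpha) else matrix(0, 0, 5)
  st <- topology$stacking
  morse_st <- if (nrow(st)) cbind(as.matrix(st[, c("i", "j", "r0")]),
                                  stack_depth, morse_alpha) else matrix(0, 0, 5)
  hb <- topology$hbond_pairs
  morse_hb <- if (nrow(hb)) cbind(hb$i, hb$j, hb$r0, hb$depth, morse_alpha) else
    matrix(0, 0, 5)

  # exclusion sets
  e12 <- rbind(cbind(topology$bonds$i, topology$bonds$j),
               cbind(a$i, a$k),
               cbind(d$i, d$l))
  eev <- rbind(cbind(nc$i, nc$j), cbind(bp$i, bp$j), cbind(st$i, st$j),
               cbind(hb$i, hb$j))
  norm_pairs <- function(m) {
    if (is.null(m) || nrow(m) == 0)
      return(list(i = integer(), j = integer()))
    lo <- pmin(m[, 1], m[, 2]); hi <- pmax(m[, 1], m[, 2])
    keep <- !duplicated(paste(lo, hi))
    list(i = as.integer(lo[keep]), j = as.integer(hi[keep]))
  }
  e12 <- norm_pairs(e12); eev <- norm_pairs(eev)

  list(
    is_dna = as.integer(beads$bead_kind != "amino_acid"),
    is_phos = as.integer(beads$bead_kind == "phosphate"),
    disordered = as.integer(beads$disordered),
    charge = as.numeric(beads$base_charge),
    hps_lambda = hl, hps_sigma = hsig, mass = as.numeric(masses),
    bonds = bonds, angles = ang, dihedrals = dih,
    flex_angles = matrix(as.integer(fa), ncol = 4),
    flex_dihedrals = matrix(as.integer(fd), ncol = 5),
    angle_tables = matrix(flexible_tables$angle, nrow = 1),
    dihedral_tables = matrix(flexible_tables$dihedral, nrow = 1),
    contacts = contacts, morse_bp = morse_bp, morse_st = morse_st,
    morse_hb = morse_hb,
    excl12_i = e12$i, excl12_j = e12$j,
    exclev_i = eev$i, exclev_j = eev$j,
    ctx = unclass(ctx))
}

#' Total energy and forces of a configuration
#'
#' Evaluates every force-field term (bonded, flexible-local, Go contacts,
#' base pairing, stacking, hydrogen bonds, HPS, excluded volume,
#' Debye-Hueckel electrostatics with the pair-context phosphate charge) and
#' the exact negative gradient.
#'
#' @param state n x 3 coordinate matrix (Angstrom), or NULL to use the
#'   topology's coordinates.
#' @param topology a `cg_topology` with charges assigned.
#' @param ctx an [electrostatic_context()].
#' @param ff prebuilt [ff_tables()] (rebuilt from the topology if NULL).
#' @return list with `energy` (named vector of per-term energies plus
#'   `total`, kcal/mol) and `forces` (n x 3, kcal/mol/A).
#' @export
total_energy_forces <- function(state = NULL, topology,
                                ctx = electrostatic_context(), ff = NULL) {
  if (is.null(ff)) ff <- ff_tables(topology, ctx)
  if (is.null(state)) state <- bead_positions(topology)
  state <- as.matrix(state)
  if (nrow(state) != nrow(topology$beads))
    stop("state size does not match topology")
  cg_energy_forces_cpp(state, ff)
}
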