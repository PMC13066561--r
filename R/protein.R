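#' Per-residue parameters for the one-bead amino acid model
#'
#' Unit charges on the charged residues (+1 e Lys/Arg, -1 e Asp/Glu, all
#' others neutral; acetyl-lysine neutral), together with the published HPS
#' hydrophobicity scale lambda (Kapcha-Rossky derived, normalised to [0, 1])
#' and per-residue sigma used by the Ashbaugh-Hatch pair potential on
#' disordered regions.
#'
#' @return A tibble with columns `code` (1-letter; "k" denotes
#'   acetyl-lysine), `residue_name` (3-letter), `charge`, `hps_lambda`,
#'   `hps_sigma` (Angstrom).
#' @export
hps_parameters <- function() {
  tibble::tribble(
    ~code, ~residue_name, ~charge, ~hps_lambda, ~hps_sigma,
    "A", "ALA",  0, 0.730, 5.04,
    "R", "ARG",  1, 0.000, 6.56,
    "N", "ASN",  0, 0.432, 5.68,
    "D", "ASP", -1, 0.378, 5.58,
    "C", "CYS",  0, 0.595, 5.48,
    "Q", "GLN",  0, 0.514, 6.02,
    "E", "GLU", -1, 0.459, 5.92,
    "G", "GLY",  0, 0.649, 4.50,
    "H", "HIS",  0, 0.514, 6.08,
    "I", "ILE",  0, 0.973, 6.18,
    "L", "LEU",  0, 0.973, 6.18,
    "K", "LYS",  1, 0.514, 6.36,
    "M", "MET",  0, 0.838, 6.18,
    "F", "PHE",  0, 1.000, 6.36,
    "P", "PRO",  0, 1.000, 5.56,
    "S", "SER",  0, 0.595, 5.18,
    "T", "THR",  0, 0.676, 5.62,
    "W", "TRP",  0, 0.946, 6.78,
    "Y", "TYR",  0, 0.865, 6.46,
    "V", "VAL",  0, 0.892, 5.86,
    "k", "ALY",  0, 0.514, 6.36)   # acetyl-lysine: Lys geometry, charge 0
}

#' Net formal charge of a protein sequence under the unit-charge rule
#'
#' @param sequence 1-letter amino-acid string ("k" = acetyl-lysine).
#' @return (#K + #R) - (#D + #E), in elementary charges.
#' @export
sequence_net_charge <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  tab <- hps_parameters()
  sum(tab$charge[match(aa, tab$code)])
}

#' Build a one-bead-per-residue protein chain
#'
#' Residues with reference (C-alpha) coordinates keep them and are treated as
#' structured; residues without are grown as a self-avoiding random walk
#' (3.8 A steps) from the nearest resolved residue and flagged disordered.
#' If no reference is given the whole chain is disordered and grown from the
#' origin (or `origin`).
#'
#' @param sequence 1-letter amino-acid string (non-empty; "k" for
#'   acetyl-lysine).
#' @param reference_coords optional matrix/data.frame with columns
#'   `residue_index`, `x`, `y`, `z` for the resolved subset.
#' @param disordered_ranges optional list of integer vectors (residue ranges)
#'   to flag disordered even when coordinates exist.
#' @param chain_id chain label.
#' @param origin 3-vector used when the chain has no resolved residue.
#' @param direction preferred initial growth direction (unit 3-vector) for
#'   unresolved stretches; jittered per step.
#' @param seed RNG seed for the random-walk growth.
#' @param min_sep minimal distance to previously placed beads, Angstrom.
#' @param avoid optional n x 3 matrix of occupied coordinates (other
#'   molecules) the walk also keeps `min_sep` away from.
#' @return A `cg_chain` with one bead per residue and a `disordered` flag.
#' @export
build_protein_chain <- function(sequence, reference_coords = NULL,
                                disordered_ranges = NULL,
                                chain_id = "PROT", origin = c(0, 0, 0),
                                direction = c(0, 0, 1), seed = 1,
                                min_sep = 3.5, avoid = NULL) {
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  if (L == 0) stop("empty sequence")
  tab <- hps_parameters()
  if (anyNA(match(aa, tab$code))) stop("unknown amino-acid code in sequence")

  coords <- matrix(NA_real_, nrow = L, ncol = 3)
  resolved <- rep(FALSE, L)
  if (!is.null(reference_coords)) {
    rc <- as.data.frame(reference_coords)
    if (any(rc$residue_index < 1 | rc$residue_index > L))
      stop("reference coordinates refer to residues outside the sequence")
    coords[rc$residue_index, ] <- as.matrix(rc[, c("x", "y", "z")])
    resolved[rc$residue_index] <- TRUE
  }
  disordered <- !resolved
  if (!is.null(disordered_ranges)) {
    for (rg in disordered_ranges) disordered[rg] <- TRUE
  }

  # grow unresolved residues by a seeded self-avoiding walk
  rng <- .counter_rng(seed)
  placed <- coords[resolved, , drop = FALSE]
  if (!any(resolved)) {
    coords[1, ] <- origin
    placed <- matrix(origin, nrow = 1)
  }
  if (!is.null(avoid)) placed <- rbind(placed, as.matrix(avoid))
  todo <- which(is.na(coords[, 1]))
  dir0 <- direction / sqrt(sum(direction^2))
  for (i in todo) {
    # nearest placed residue along the chain
    done <- which(!is.na(coords[, 1]))
    anchor <- done[which.min(abs(done - i))]
    base <- coords[anchor, ]
    ok <- FALSE
    best <- base + 3.8 * dir0; best_d <- -Inf
    for (attempt in 1:200) {
      step <- dir0 + 0.9 * c(rng(), rng(), rng())
      step <- 3.8 * step / sqrt(sum(step^2))
      cand <- base + step
      d <- if (nrow(placed) == 0) Inf else
        min(sqrt(rowSums(sweep(placed, 2, cand)^2)))
      if (d >= min_sep * 0.9) { ok <- TRUE; break }
      if (d > best_d) { best_d <- d; best <- cand }
    }
    if (!ok) cand <- best  # least-crowded candidate after retry budget
    coords[i, ] <- cand
    placed <- rbind(placed, cand)
  }

  beads <- tibble::tibble(
    bead_id = seq_len(L),
    residue_index = seq_len(L),
    bead_kind = "amino_acid",
    residue_name = tab$residue_name[match(aa, tab$code)],
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    disordered = disordered)
  structure(list(chain_id = chain_id, molecule_kind = "protein",
                 sequence = sequence, beads = beads),
            class = "cg_chain")
}

# small deterministic uniform(-1,1) generator (keeps build functions
# independent of R's global RNG state); 69069 * 2^32 < 2^53 so the
# arithmetic stays exact in doubles
.counter_rng <- function(seed) {
  state <- as.double(seed) %% 2^32
  function() {
    state <<- (state * 69069 + 1) %% 2^32
    2 * (state / 2^32) - 1
  }
}
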