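#' Ideal B-form duplex DNA in the three-bead representation
#'
#' Builds a double-stranded B-DNA helix in which every nucleotide is reduced
#' to three beads (phosphate, sugar, base). The Watson strand is the input
#' sequence; the Crick strand is its reverse complement, placed antiparallel
#' so that base bead pairs face each other at the canonical pairing distance.
#' The 5'-terminal nucleotide of each strand carries no phosphate bead, the
#' standard convention for three-bead DNA models.
#'
#' The helix is an ideal (sequence-independent) model: uniform rise and twist,
#' beads on fixed cylindrical radii. Defaults give the classic B-form
#' geometry (3.38 A rise, 34.3 deg twist, ~10.5 bp/turn).
#'
#' @param sequence DNA string over A/C/G/T (Watson strand, 5' to 3').
#' @param rise axial rise per base pair, Angstrom.
#' @param twist helical twist per base pair, degrees.
#' @return A list of two `cg_chain` objects (`watson`, `crick`), each holding
#'   a bead tibble (`bead_id` local to the chain, `residue_index`,
#'   `bead_kind`, `residue_name`, `x`, `y`, `z`) and the strand sequence.
#' @examples
#' duplex <- generate_bdna("ACGTACGT")
#' nrow(duplex$watson$beads)  # 3*8 - 1 = 23
#' @export
generate_bdna <- function(sequence, rise = 3.38, twist = 34.3) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (length(bases) < 1) stop("sequence must have length >= 1")
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("invalid sequence: only A, C, G, T are allowed")
  L <- length(bases)
  crick_seq <- reverse_complement(sequence)
  crick_bases <- strsplit(crick_seq, "")[[1]]

  tw <- twist * pi / 180
  # cylindrical placement (radius A, phase offset rad relative to the bp
  # pseudo-axis angle). Chosen so paired base beads sit ~5.5 A apart and
  # consecutive same-strand base beads ~4 A apart (stacking distance).
  r_sugar <- 9.0; r_phos <- 10.0; r_base <- 3.5
  a_sugar <- 60 * pi / 180
  a_base  <- 52 * pi / 180

  cyl <- function(r, ang, z) c(r * cos(ang), r * sin(ang), z)

  strand_beads <- function(bases_local, watson) {
    L <- length(bases_local)
    rows <- list()
    for (j in seq_len(L)) {
      # bp index on the Watson frame this nucleotide belongs to
      i <- if (watson) j else L + 1 - j
      phi <- (i - 1) * tw
      sgn <- if (watson) -1 else +1
      z <- (i - 1) * rise
      if (j > 1) {
        # phosphate sits between this sugar and the previous one (5' side)
        iprev <- if (watson) i - 0.5 else i + 0.5
        rows[[length(rows) + 1]] <- list(
          residue_index = j, bead_kind = "phosphate",
          residue_name = bases_local[j],
          pos = cyl(r_phos, (iprev - 1) * tw + sgn * a_sugar, (iprev - 1) * rise))
      }
      rows[[length(rows) + 1]] <- list(
        residue_index = j, bead_kind = "sugar",
        residue_name = bases_local[j],
        pos = cyl(r_sugar, phi + sgn * a_sugar, z))
      rows[[length(rows) + 1]] <- list(
        residue_index = j, bead_kind = "base",
        residue_name = bases_local[j],
        pos = cyl(r_base, phi + sgn * a_base, z))
    }
    tibble::tibble(
      bead_id = seq_along(rows),
      residue_index = vapply(rows, function(r) r$residue_index, 1L),
      bead_kind = vapply(rows, function(r) r$bead_kind, ""),
      residue_name = vapply(rows, function(r) r$residue_name, ""),
      x = vapply(rows, function(r) r$pos[1], 1.0),
      y = vapply(rows, function(r) r$pos[2], 1.0),
      z = vapply(rows, function(r) r$pos[3], 1.0))
  }

  watson <- structure(list(chain_id = "DNA_W", molecule_kind = "dna_strand",
                           sequence = sequence,
                           beads = strand_beads(bases, TRUE)),
                      class = "cg_chain")
  crick <- structure(list(chain_id = "DNA_C", molecule_kind = "dna_strand",
                          sequence = crick_seq,
                          beads = strand_beads(crick_bases, FALSE)),
                     class = "cg_chain")
  list(watson = watson, crick = crick)
}

#' Reverse complement of a DNA sequence
#'
#' Uses Biostrings when available (the canonical route), with a base-R
#' fallback so the operation works without the Bioconductor stack loaded.
#'
#' @param sequence DNA string over A/C/G/T.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(sequence) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    return(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sequence))))
  }
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(sequence)), "")[[1]]),
        collapse = "")
}

#' Canonical base-pair pairing distance of the ideal helix
#'
#' Distance between the two base beads of a complementary pair in the ideal
#' geometry used by [generate_bdna()].
#'
#' @return Distance in Angstrom.
#' @export
bdna_pairing_distance <- function() {
  2 * 3.5 * sin(52 * pi / 180)
}
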