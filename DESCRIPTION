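Package: chromacg
Title: Coarse-Grained Chromatosome Dynamics and Histone-Tail Contact Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds coarse-grained models of nucleosomes and chromatosomes
    (three beads per DNA nucleotide, one bead per amino acid), evaluates a
    structure-based force field with Debye-Hueckel electrostatics and
    pair-context phosphate charges, runs Langevin dynamics with replica
    management, computes histone tail versus DNA contact maps and per-region
    contact percentages with replica standard deviations, and fits
    single-exponential acetylation kinetics with Monte-Carlo uncertainty
    estimates. Ships synthetic generators (toy chromatosome-like systems,
    scripted trajectories with prescribed contact occupancy, noisy
    exponential decay series) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    bio3d,
    readr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
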