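#' Full-scale reference rate constants for H3 K14 acetylation
#'
#' Apparent single-exponential rate constants (with Monte-Carlo fit
#' uncertainties) for H3 K14 acetylation in four assembly states, recorded
#' as machine-readable targets. These are full-scale quantities: reproducing
#' them requires the underlying time-resolved intensity measurements, so
#' `desk_scale` is `FALSE` for every row. At desk scale the same fitter is
#' validated by the synthetic recovery study instead (see
#' [make_decay_series()] and [fit_exponential()]).
#'
#' @return tibble with `system`, `k_app_per_s`, `uncertainty_per_s`,
#'   `desk_scale` (all `FALSE`).
#' @export
reference_rate_constants <- function() {
  tg <- .reference_targets()
  out <- dplyr::bind_rows(lapply(tg$rate_constants, tibble::as_tibble))
  out$desk_scale <- tg$desk_scale
  out
}

#' Full-scale reference tail-DNA contact percentages
#'
#' Contact percentages of the distal and proximal H3 N-tails with core and
#' linker DNA in the unmodified and H4 tetra-acetylated chromatosome,
#' recorded as machine-readable targets. These are full-scale quantities:
#' reproducing them requires the deposited chromatosome reference structure
#' and multi-microsecond replica trajectories, so `desk_scale` is `FALSE`
#' for every row. The desk-scale surrogate is the sign-level toy experiment
#' built by [make_toy_chromatosome()].
#'
#' @return tibble with `tail`, `region`, `condition`, `percent`,
#'   `desk_scale` (all `FALSE`).
#' @export
reference_contact_percentages <- function() {
  tg <- .reference_targets()
  out <- dplyr::bind_rows(lapply(tg$contact_percentages, tibble::as_tibble))
  out$desk_scale <- tg$desk_scale
  out
}

.reference_targets <- function() {
  path <- system.file("extdata", "reference_targets.json",
                      package = "chromacg", mustWork = TRUE)
  jsonlite::read_json(path)
}
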