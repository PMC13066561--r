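#' Averaged amide chemical-shift difference
#'
#' Combined 1H/15N perturbation \eqn{[(\Delta HN)^2 + (\Delta N/5)^2]^{1/2}},
#' the standard weighting that scales the nitrogen shift by the ratio of
#' spectral widths.
#'
#' @param delta_hn amide proton shift difference, ppm.
#' @param delta_n amide nitrogen shift difference, ppm.
#' @return combined shift difference, ppm (vectorised).
#' @examples
#' csp(0, 1)      # 0.2
#' csp(0.1, 0.5)  # sqrt(0.02)
#' @export
csp <- function(delta_hn, delta_n) {
  if (any(!is.finite(delta_hn)) || any(!is.finite(delta_n)))
    stop("shift differences must be finite")
  sqrt(delta_hn^2 + (delta_n / 5)^2)
}

#' Per-residue chemical-shift-difference profile between two states
#'
#' Pairs peaks by residue label (and multiplicity side, when doublets are
#' present) and applies [csp()] to the paired 1H/15N differences.
#'
#' @param peaks_a,peaks_b data frames with columns `residue`, `hn`, `n`
#'   (ppm) and optionally `multiplicity` (one of "singlet",
#'   "doublet_ncp_side", "doublet_nucleosome_side").
#' @return tibble with `residue`, `multiplicity`, `delta_hn`, `delta_n`,
#'   `csp` (all >= 0 for `csp`).
#' @export
csp_profile <- function(peaks_a, peaks_b) {
  a <- tibble::as_tibble(peaks_a); b <- tibble::as_tibble(peaks_b)
  if (is.null(a[["multiplicity"]])) a$multiplicity <- "singlet"
  if (is.null(b[["multiplicity"]])) b$multiplicity <- "singlet"
  key_a <- paste(a$residue, a$multiplicity)
  key_b <- paste(b$residue, b$multiplicity)
  if (!setequal(key_a, key_b))
    stop("unmatched residues between peak lists: ",
         paste(union(setdiff(key_a, key_b), setdiff(key_b, key_a)),
               collapse = ", "))
  m <- match(key_a, key_b)
  tibble::tibble(
    residue = a$residue,
    multiplicity = a$multiplicity,
    delta_hn = a$hn - b$hn[m],
    delta_n = a$n - b$n[m],
    csp = csp(a$hn - b$hn[m], a$n - b$n[m]))
}

#' Fit a single exponential to a normalized intensity time course
#'
#' Least-squares fit of \eqn{I(t) = A e^{-k t}} (decay; the disappearing
#' substrate peak) or \eqn{I(t) = A (1 - e^{-k t}) + c} (rise; the appearing
#' product peak). The apparent rate constant's uncertainty is estimated by a
#' parametric Monte-Carlo bootstrap: Gaussian noise with the residual RMS of
#' the initial fit is added to the fitted curve, the model is refit, and the
#' standard deviation of k over the iterations is reported.
#'
#' @param series data frame with columns `time_s` (strictly increasing) and
#'   `intensity` (normalized so the first point is ~1), or a list with
#'   `times`/`intensities`.
#' @param direction "decay" or "rise".
#' @param n_mc Monte-Carlo iterations (default 100).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `kinetics_fit`: `k_app` (1/s), `uncertainty`
#'   (1/s), `n_mc`, `residual_rms`, `direction`, coefficients and the data.
#' @export
fit_exponential <- function(series, direction = c("decay", "rise"),
                            n_mc = 100, seed = 1) {
  direction <- match.arg(direction)
  ser <- .as_kinetics_series(series)
  t <- ser$time_s; y <- ser$intensity
  if (length(t) < 4) stop("need at least 4 points")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")

  fit_once <- function(yy) {
    # log-linear / moment start values, then nonlinear least squares
    if (direction == "decay") {
      pos <- yy > 0
      k0 <- if (sum(pos) >= 2)
        max(1e-12, -stats::coef(stats::lm(log(yy[pos]) ~ t[pos]))[2])
      else 1 / max(t)
      df <- data.frame(t = t, y = yy)
      fit <- try(minpack.lm::nlsLM(y ~ A * exp(-k * t), data = df,
                                   start = list(A = max(yy), k = k0),
                                   lower = c(A = 0, k = 0),
                                   control = minpack.lm::nls.lm.control(maxiter = 200)),
                 silent = TRUE)
    } else {
      k0 <- 1 / max(t[t > 0])
      df <- data.frame(t = t, y = yy)
      fit <- try(minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)) + c0, data = df,
                                   start = list(A = max(yy) - min(yy), k = k0,
                                                c0 = min(yy)),
                                   lower = c(A = 0, k = 0, c0 = -Inf),
                                   control = minpack.lm::nls.lm.control(maxiter = 200)),
                 silent = TRUE)
    }
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }

  fit <- fit_once(y)
  if (is.null(fit)) stop("exponential fit failed")
  cf <- stats::coef(fit)
  k_hat <- unname(cf["k"])
  pred <- stats::fitted(fit)
  rms <- sqrt(mean(stats::resid(fit)^2))

  ks <- rep(NA_real_, n_mc)
  if (n_mc > 0) {
    set.seed(seed)
    for (m in seq_len(n_mc)) {
      ymc <- pred + stats::rnorm(length(pred), 0, rms)
      fm <- fit_once(ymc)
      if (!is.null(fm)) ks[m] <- unname(stats::coef(fm)["k"])
    }
  }
  unc <- if (n_mc > 0) stats::sd(ks, na.rm = TRUE) else NA_real_

  structure(list(k_app = k_hat, uncertainty = unc, n_mc = n_mc,
                 residual_rms = rms, direction = direction,
                 coefficients = cf, data = tibble::tibble(time_s = t,
                                                          intensity = y),
                 fitted = pred, mc_k = ks, seed = seed),
            class = "kinetics_fit")
}

.as_kinetics_series <- function(series) {
  if (is.data.frame(series)) {
    stopifnot(all(c("time_s", "intensity") %in% names(series)))
    tibble::tibble(time_s = series$time_s, intensity = series$intensity)
  } else {
    tibble::tibble(time_s = series$times, intensity = series$intensities)
  }
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> %s: k_app = %.4g 1/s +/- %.2g (MC, n = %d)\n",
              x$direction, x$k_app, x$uncertainty, x$n_mc))
  invisible(x)
}

#' Tidy a kinetics fit
#'
#' @param x a `kinetics_fit`.
#' @param ... unused.
#' @return one-row-per-parameter tibble (`term`, `estimate`, `std.error`).
#' @export
tidy.kinetics_fit <- function(x, ...) {
  cf <- x$coefficients
  tibble::tibble(term = names(cf), estimate = unname(cf),
                 std.error = ifelse(names(cf) == "k", x$uncertainty, NA_real_))
}

#' One-row summary of a kinetics fit
#'
#' @param x a `kinetics_fit`.
#' @param ... unused.
#' @return tibble with `k_app`, `uncertainty`, `residual_rms`, `n_mc`,
#'   `n_points`.
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble::tibble(k_app = x$k_app, uncertainty = x$uncertainty,
                 residual_rms = x$residual_rms, n_mc = x$n_mc,
                 n_points = nrow(x$data))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
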