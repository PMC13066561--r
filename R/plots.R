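#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of a tail-DNA contact map
#'
#' @param object a `contact_map`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bp, y = .data$residue,
                                       fill = .data$occupancy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "% frames") +
    ggplot2::labs(x = "base pair", y = "tail residue",
                  title = attr(object, "tail")) +
    ggplot2::theme_minimal()
}

#' Diverging heat map of a contact difference map
#'
#' @param object a `difference_map`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot difference_map
#' @export
autoplot.difference_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bp, y = .data$residue,
                                       fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  limits = c(-100, 100), name = "Δ %") +
    ggplot2::labs(x = "base pair", y = "tail residue") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-region tail contact percentages
#'
#' Replica means with standard-deviation error bars, mirroring the usual
#' per-tail core/linker bar presentation.
#'
#' @param object a `region_contact_summary`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot region_contact_summary
#' @export
autoplot.region_contact_summary <- function(object, ...) {
  df <- dplyr::filter(object, .data$region != "linker_any")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$mean,
                                   fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::facet_wrap(~tail) +
    ggplot2::labs(y = "% frames in contact", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Data and fitted curve of an exponential kinetics fit
#'
#' @param object a `kinetics_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot kinetics_fit
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "normalized intensity",
                  subtitle = sprintf("k_app = %.3g 1/s ± %.2g",
                                     object$k_app, object$uncertainty)) +
    ggplot2::theme_minimal()
}
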