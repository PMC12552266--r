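## ggplot2 presentation methods.

#' Plot a scan set
#'
#' Radial signal profiles coloured by scan time.
#'
#' @param object A `scan_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_set <- function(object, ...) {
  ggplot2::ggplot(object$scans,
                  ggplot2::aes(x = .data$radius_cm, y = .data$signal,
                               group = .data$scan_id,
                               colour = .data$time_s)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c(name = "time (s)") +
    ggplot2::labs(x = "radius (cm)", y = "signal",
                  title = sprintf("Sedimentation scans (%s engine)",
                                  object$engine)) +
    ggplot2::theme_minimal()
}

#' Plot a 2D sedimentation distribution
#'
#' Heat map of the recovered weights on the (R_H, m_b) grid, log axes.
#'
#' @param object A `distribution2d`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distribution2d <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$RH_cm, y = .data$Mb_g,
                               fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(R[H] ~ "(cm)"),
                  y = expression(m^(b) ~ "(g)"),
                  fill = "weight") +
    ggplot2::theme_minimal()
}

#' Plot a fit landscape
#'
#' For two-parameter landscapes, a log-log heat map of Delta%; for one
#' parameter, a profile curve.
#'
#' @param object A `hydfit_landscape` from [profile_landscape()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hydfit_landscape <- function(object, ...) {
  pars <- setdiff(names(object), "delta_percent")
  if (length(pars) >= 2) {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data[[pars[1]]], y = .data[[pars[2]]],
                                 fill = log10(.data$delta_percent))) +
      ggplot2::geom_tile() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::scale_fill_viridis_c(name = expression(log[10] ~ Delta["%"])) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data[[pars[1]]],
                                 y = .data$delta_percent)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(y = expression(Delta["%"])) +
      ggplot2::theme_minimal()
  }
}
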