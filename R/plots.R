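# ggplot2 views of trajectories, dose-response scans, sensitivity tables and
# calibration grids.

#' Plot an ABA-step trajectory
#'
#' @param object An `aba_trajectory`.
#' @param species Species to draw (default the RD29A mRNA readout).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot aba_trajectory
#' @export
autoplot.aba_trajectory <- function(object, species = RD29A_SPECIES, ...) {
  df <- tidy.aba_trajectory(object) |>
    dplyr::filter(.data$species %in% !!species)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$concentration,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time after ABA step (h)", y = "Concentration (uM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response table
#'
#' @param dr Output of [dose_response()].
#' @return A ggplot of peak RD29A mRNA against ABA dose.
#' @export
plot_dose_response <- function(dr) {
  ggplot2::ggplot(dr, ggplot2::aes(.data$dose, .data$peak_value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "ABA dose (uM)", y = "Peak RD29A mRNA (uM)") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity ranking
#'
#' @param sens Output of [local_sensitivity()].
#' @return A ggplot bar chart, most sensitive parameter first.
#' @export
plot_sensitivity <- function(sens) {
  sens <- dplyr::mutate(sens,
                        parameter = stats::reorder(.data$parameter,
                                                   .data$sensitivity))
  ggplot2::ggplot(sens, ggplot2::aes(.data$parameter, .data$sensitivity)) +
    ggplot2::geom_col() + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = "Normalised sensitivity of RD29A mRNA (0-24 h)") +
    ggplot2::theme_minimal()
}

#' Plot a calibration grid
#'
#' @param object An `aba_calibration`.
#' @param ... Unused.
#' @return A ggplot of the transient-feasible region over (kf26, kf27),
#'   faceted by kf28.
#' @method autoplot aba_calibration
#' @export
autoplot.aba_calibration <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(.data$kf26, .data$kf27,
                               fill = .data$is_transient)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$kf28),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "kf26 (1/h)", y = "kf27 (1/h)",
                  fill = "transient") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
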