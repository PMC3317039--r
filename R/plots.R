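#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-plane puncta measures
#'
#' @param object a `puncta_measurement`.
#' @param ... unused.
#' @return A ggplot: pixel counts per channel and colocalization across the
#'   z-series.
#' @export
autoplot.puncta_measurement <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_plane,
                              dplyr::any_of(c("receptor_px", "marker_px",
                                              "coloc_px")),
                              names_to = "measure", values_to = "pixels")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$pixels,
                                     colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "z plane", y = "thresholded pixels",
                  colour = NULL, title = "Neuropil puncta by plane") +
    ggplot2::theme_minimal()
}

#' Plot a membrane fraction band with its receptor pools
#'
#' @param object a `membrane_fraction`.
#' @param ... unused.
#' @return A ggplot raster of the band with synaptic/extrasynaptic pixels
#'   coloured.
#' @export
autoplot.membrane_fraction <- function(object, ...) {
  d <- dim(object$band_mask)
  lab <- matrix("outside", d[1], d[2])
  lab[object$band_mask] <- "band"
  lab[object$extrasynaptic_mask] <- "extrasynaptic"
  lab[object$synaptic_mask] <- "synaptic"
  df <- tibble::tibble(
    y = rep(0:(d[1] - 1), times = d[2]),
    x = rep(0:(d[2] - 1), each = d[1]),
    pool = factor(as.vector(lab),
                  levels = c("outside", "band", "extrasynaptic", "synaptic")))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$pool)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(outside = "grey95", band = "grey70",
                                          extrasynaptic = "#D55E00",
                                          synaptic = "#0072B2")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Membrane band, plane %d", object$plane_index),
                  x = "x (px)", y = "y (px)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Dose-response plot of a cohort measurement
#'
#' @param records cohort measurement tibble (see [measure_cohort()] or
#'   [simulate_cohort_counts()]).
#' @param outcome outcome column name.
#' @return A ggplot: subject-level means by dose and side.
#' @export
plot_dose_response <- function(records, outcome) {
  subj <- records |>
    dplyr::group_by(.data$subject_id, .data$dose_um, .data$side) |>
    dplyr::summarise(.y = mean(.data[[outcome]]), .groups = "drop")
  ggplot2::ggplot(subj, ggplot2::aes(x = factor(.data$dose_um), y = .data$.y,
                                     colour = .data$side)) +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::labs(x = "dose (uM)", y = outcome, colour = NULL,
                  title = "Dose response (subject means)") +
    ggplot2::theme_minimal()
}
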