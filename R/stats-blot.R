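#' Normalize a receptor band against its loading control
#'
#' The densitometry normalization step: receptor band intensity divided by
#' the loading-control (membrane marker) band intensity from the same lane.
#' Vectorized over lanes.
#'
#' @param receptor_intensity positive receptor band intensities.
#' @param control_intensity positive loading-control intensities.
#' @return `receptor_intensity / control_intensity`.
#' @export
normalize_blot <- function(receptor_intensity, control_intensity) {
  if (any(control_intensity <= 0)) {
    stop_punctate("control intensity must be positive",
                  "punctate_validation_error")
  }
  receptor_intensity / control_intensity
}

#' Average normalized blot ratios across replicate runs
#'
#' Computes the normalized ratio per lane and run, then averages the per-run
#' ratios within each sample (lane/condition), mirroring counterbalanced
#' replicate gels averaged after normalization.
#'
#' @param lanes tibble with columns `lane_id`, `condition`, `run`,
#'   `receptor_band_intensity`, `loading_control_intensity`.
#' @return Tibble with one row per `lane_id` x `condition`:
#'   `normalized_ratio` = mean of per-run ratios, and `n_runs`.
#' @export
average_blot_runs <- function(lanes) {
  needed <- c("lane_id", "condition", "run",
              "receptor_band_intensity", "loading_control_intensity")
  if (!all(needed %in% names(lanes))) {
    stop_punctate(paste("lane table needs columns:",
                        paste(needed, collapse = ", ")),
                  "punctate_validation_error")
  }
  lanes |>
    dplyr::mutate(ratio = normalize_blot(.data$receptor_band_intensity,
                                         .data$loading_control_intensity)) |>
    dplyr::group_by(.data$lane_id, .data$condition) |>
    dplyr::summarise(normalized_ratio = mean(.data$ratio),
                     n_runs = dplyr::n(), .groups = "drop")
}

#' Linear-range R-squared of an antibody dilution curve
#'
#' Ordinary least-squares R-squared of band intensity on loaded protein
#' amount; the quantitative-blot validity check that intensities sit in the
#' antibody's linear range.
#'
#' @param loadings protein amounts loaded (>= 3 points).
#' @param intensities measured band intensities, same length.
#' @return Scalar R-squared.
#' @export
linear_range_r2 <- function(loadings, intensities) {
  if (length(loadings) < 3L || length(intensities) != length(loadings)) {
    stop_punctate("need >= 3 matched (loading, intensity) points",
                  "punctate_validation_error")
  }
  summary(stats::lm(intensities ~ loadings))$r.squared
}

#' Background-correct a lane profile around a band
#'
#' Subtracts local background estimated as the mean of the median pixel
#' densities above and below the band from the band's integrated intensity:
#' `corrected = sum(profile[band]) - width * mean(median(above), median(below))`.
#'
#' @param lane_profile numeric vector of pixel densities along the lane.
#' @param band_interval integer `(start, end)`, 1-based inclusive indices of
#'   the band; must lie strictly inside the profile so that both flanking
#'   segments are non-empty.
#' @return Background-corrected integrated band intensity.
#' @export
band_background_correct <- function(lane_profile, band_interval) {
  start <- band_interval[1]; end <- band_interval[2]
  n <- length(lane_profile)
  if (start <= 1L || end >= n || start > end) {
    stop_punctate("band interval must lie strictly inside the profile",
                  "punctate_validation_error")
  }
  width <- end - start + 1L
  bg <- mean(c(stats::median(lane_profile[seq_len(start - 1L)]),
               stats::median(lane_profile[(end + 1L):n])))
  sum(lane_profile[start:end]) - width * bg
}
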