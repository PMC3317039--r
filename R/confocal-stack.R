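#' Calibrated multi-channel confocal stack
#'
#' A `confocal_stack` bundles a 4-axis intensity array with its channel labels
#' and physical calibration. The axis convention used throughout the package is
#' `(channel, z, y, x)`: pixel coordinates are 0-based in all user-facing
#' tables, `y` increases downward, and `z = 0` is the first acquired plane.
#' No other function re-infers axes.
#'
#' @param voxels numeric 4-d array indexed `(channel, z, y, x)`, all values
#'   non-negative.
#' @param channel_names character vector of channel labels, one per channel.
#'   Analysis functions look up the labels `"receptor"` and `"marker"`.
#' @param pixel_size_um lateral pixel pitch in micrometres per pixel
#'   (x and y spacing are assumed equal). Default 0.14 um/px, a typical
#'   sampling for a 63x/1.4 NA confocal objective at 2x zoom.
#' @param z_step_um axial spacing between planes in micrometres.
#'
#' @return An object of class `confocal_stack`.
#' @export
confocal_stack <- function(voxels, channel_names,
                           pixel_size_um = 0.14, z_step_um = 0.5) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L) {
    stop_punctate("`voxels` must be a 4-d array indexed (channel, z, y, x)",
                  "punctate_validation_error")
  }
  if (any(voxels < 0)) {
    stop_punctate("stack intensities must be non-negative",
                  "punctate_validation_error")
  }
  if (length(channel_names) != dim(voxels)[1L]) {
    stop_punctate("`channel_names` length must equal the channel axis length",
                  "punctate_validation_error")
  }
  if (dim(voxels)[2L] < 1L) {
    stop_punctate("stack must contain at least one z-plane",
                  "punctate_validation_error")
  }
  assert_positive_scalar(pixel_size_um, "pixel_size_um")
  assert_positive_scalar(z_step_um, "z_step_um")
  structure(
    list(voxels = voxels,
         channel_names = as.character(channel_names),
         pixel_size_um = pixel_size_um,
         z_step_um = z_step_um),
    class = "confocal_stack"
  )
}

#' @export
print.confocal_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<confocal_stack> %d channel(s) [%s], %d plane(s), %d x %d px\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  calibration: %.4g um/px lateral, %.4g um z-step\n",
              x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' @export
dim.confocal_stack <- function(x) dim(x$voxels)

# Extract one channel as a (z, y, x) 3-d array.
#' Extract a channel from a stack
#'
#' @param stack a [confocal_stack()].
#' @param channel channel label, e.g. `"receptor"`.
#' @return 3-d numeric array indexed `(z, y, x)`.
#' @export
stack_channel <- function(stack, channel) {
  idx <- match(channel, stack$channel_names)
  if (is.na(idx)) {
    stop_punctate(sprintf("channel '%s' not present (have: %s)", channel,
                          paste(stack$channel_names, collapse = ", ")),
                  "punctate_configuration_error")
  }
  arr <- stack$voxels[idx, , , , drop = FALSE]
  dim(arr) <- dim(stack$voxels)[-1L]
  arr
}

# One plane of one channel as a (y, x) matrix.
stack_plane <- function(stack, channel, z) {
  ch <- stack_channel(stack, channel)
  plane <- ch[z + 1L, , , drop = FALSE]
  dim(plane) <- dim(ch)[-1L]
  plane
}

#' Per-scene metadata record
#'
#' Experimental design factors attached to one imaged neuron: the cytokine dose
#' delivered on the injected side, which hemicord the neuron sits in, and its
#' signed rostrocaudal distance from the injection centre.
#'
#' @param subject_id,neuron_id identifier strings.
#' @param dose_um dose in micromolar; 0 denotes the albumin vehicle.
#' @param side `"injected"` or `"contralateral"`.
#' @param distance_um signed rostrocaudal offset from the injection centre, in
#'   micrometres; the sampling design spans -600 to +600.
#' @return A one-row tibble.
#' @export
scene_metadata <- function(subject_id, neuron_id, dose_um, side, distance_um) {
  side <- match.arg(side, c("injected", "contralateral"))
  if (dose_um < 0) {
    stop_punctate("`dose_um` must be >= 0", "punctate_validation_error")
  }
  if (abs(distance_um) > 600) {
    stop_punctate("`distance_um` must lie within +/-600 um",
                  "punctate_validation_error")
  }
  tibble::tibble(subject_id = as.character(subject_id),
                 neuron_id = as.character(neuron_id),
                 dose_um = as.numeric(dose_um),
                 side = side,
                 distance_um = as.numeric(distance_um))
}
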