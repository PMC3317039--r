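#' Point-spread-function model
#'
#' Either a parametric 3-d Gaussian (lateral and axial sigmas in um, converted
#' to voxel units against the stack calibration at use time) or an explicitly
#' supplied 3-d kernel.
#'
#' @param kind `"gaussian_parametric"` or `"supplied_kernel"`.
#' @param sigma_lateral_um,sigma_axial_um Gaussian sigmas (parametric kind).
#' @param kernel non-negative 3-d array summing to 1 (supplied kind).
#' @return A list of class `psf_model`.
#' @export
psf_model <- function(kind = c("gaussian_parametric", "supplied_kernel"),
                      sigma_lateral_um = 0.2, sigma_axial_um = 0.4,
                      kernel = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian_parametric") {
    assert_positive_scalar(sigma_lateral_um, "sigma_lateral_um")
    assert_positive_scalar(sigma_axial_um, "sigma_axial_um")
  } else {
    if (is.null(kernel) || length(dim(kernel)) != 3L) {
      stop_punctate("supplied kernel must be a 3-d array",
                    "punctate_validation_error")
    }
    if (any(kernel < 0) || abs(sum(kernel) - 1) > 1e-9) {
      stop_punctate("kernel must be non-negative and sum to 1 (tol 1e-9)",
                    "punctate_validation_error")
    }
  }
  structure(list(kind = kind, sigma_lateral_um = sigma_lateral_um,
                 sigma_axial_um = sigma_axial_um, kernel = kernel),
            class = "psf_model")
}

# Convolve (z, y, x) array with the PSF using reflective boundaries.
psf_convolve <- function(arr, psf, pixel_size_um, z_step_um) {
  if (psf$kind == "gaussian_parametric") {
    gaussian_blur_3d(arr, psf$sigma_lateral_um / pixel_size_um,
                     psf$sigma_axial_um / z_step_um)
  } else {
    kernel_convolve_3d(arr, psf$kernel)
  }
}

# Direct 3-d convolution by kernel-offset accumulation (kernels are small).
kernel_convolve_3d <- function(arr, kernel) {
  d <- dim(arr); kd <- dim(kernel)
  rz <- (kd[1] - 1L) %/% 2L; ry <- (kd[2] - 1L) %/% 2L; rx <- (kd[3] - 1L) %/% 2L
  out <- array(0, dim = d)
  for (iz in seq_len(kd[1])) {
    zi <- reflect_index(seq_len(d[1]) + iz - rz - 1L, d[1])
    for (iy in seq_len(kd[2])) {
      yi <- reflect_index(seq_len(d[2]) + iy - ry - 1L, d[2])
      for (ix in seq_len(kd[3])) {
        w <- kernel[iz, iy, ix]
        if (w == 0) next
        xi <- reflect_index(seq_len(d[3]) + ix - rx - 1L, d[3])
        out <- out + w * arr[zi, yi, xi, drop = FALSE]
      }
    }
  }
  out
}

#' Richardson–Lucy deconvolution of one channel
#'
#' The standard multiplicative Richardson–Lucy update applied a fixed number
#' of times, the iterative-deconvolution step applied to confocal stacks
#' before quantification. Three iterations is the default, the iteration count
#' used for receptor-label stacks in the original protocol. Boundaries are
#' handled reflectively so edge planes are not dimmed, and total intensity is
#' conserved to well within 0.1% per iteration.
#'
#' @param stack_channel 3-d `(z, y, x)` non-negative intensity array.
#' @param psf a [psf_model()].
#' @param iterations number of updates; 0 returns the input unchanged.
#' @param pixel_size_um,z_step_um calibration used to convert parametric PSF
#'   sigmas to voxel units.
#' @return Deconvolved 3-d array, non-negative, same shape.
#' @export
richardson_lucy <- function(stack_channel, psf, iterations = 3L,
                            pixel_size_um = 0.14, z_step_um = 0.5) {
  if (any(stack_channel < 0)) {
    stop_punctate("input intensities must be non-negative",
                  "punctate_validation_error")
  }
  if (iterations < 0) {
    stop_punctate("iterations must be >= 0", "punctate_validation_error")
  }
  if (iterations == 0L) return(stack_channel)
  est <- stack_channel
  eps <- 1e-12
  for (i in seq_len(iterations)) {
    blurred <- psf_convolve(est, psf, pixel_size_um, z_step_um)
    ratio <- stack_channel / pmax(blurred, eps)
    # Gaussian/centro-symmetric PSFs equal their adjoint, so the correlation
    # step reuses the same convolution.
    est <- est * psf_convolve(ratio, psf, pixel_size_um, z_step_um)
    est[est < 0] <- 0
  }
  est
}

#' Deconvolve a full stack channel-wise
#'
#' Applies [richardson_lucy()] independently to each channel (or a stated
#' subset), returning a new calibrated stack.
#'
#' @param stack a [confocal_stack()].
#' @param psf a [psf_model()].
#' @param iterations Richardson–Lucy iterations (default 3).
#' @param channels channel labels to deconvolve; default all.
#' @return A [confocal_stack()] of the same shape.
#' @export
deconvolve_stack <- function(stack, psf, iterations = 3L,
                             channels = stack$channel_names) {
  v <- stack$voxels
  storage.mode(v) <- "double"   # deconvolved intensities are continuous
  for (ch in channels) {
    idx <- match(ch, stack$channel_names)
    if (is.na(idx)) {
      stop_punctate(sprintf("channel '%s' not present", ch),
                    "punctate_configuration_error")
    }
    arr <- stack_channel(stack, ch)
    v[idx, , , ] <- richardson_lucy(arr, psf, iterations,
                                    pixel_size_um = stack$pixel_size_um,
                                    z_step_um = stack$z_step_um)
  }
  out <- stack
  out$voxels <- v
  out
}
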