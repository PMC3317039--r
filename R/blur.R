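# Separable Gaussian filtering with symmetric (reflective) boundary handling.
# Shared by the scene generator (PSF emulation) and Richardson-Lucy.

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Reflect an index vector into 1..n (edge-repeating / Neumann boundary).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  idx <- ((idx - 1L) %% period + period) %% period + 1L
  ifelse(idx > n, period - idx + 1L, idx)
}

# Convolve a (z, y, x) array with a 1-d kernel along one axis.
convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr * kernel)
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim = d)
  base <- seq_len(n)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- reflect_index(base + off, n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kernel[j] * shifted
  }
  out
}

# Gaussian blur of a (z, y, x) array; sigmas given in voxel units
# (sigma_z planes, sigma_xy pixels).
gaussian_blur_3d <- function(arr, sigma_xy, sigma_z) {
  kz <- gaussian_kernel_1d(sigma_z)
  kxy <- gaussian_kernel_1d(sigma_xy)
  arr <- convolve_axis(arr, kz, 1L)
  arr <- convolve_axis(arr, kxy, 2L)
  convolve_axis(arr, kxy, 3L)
}
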