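psf <- psf_model(sigma_lateral_um = 0.28, sigma_axial_um = 0.5)

test_that("zero iterations returns the input unchanged", {
  arr <- array(runif(5 * 8 * 8, 0, 100), c(5, 8, 8))
  expect_identical(richardson_lucy(arr, psf, 0L), arr)
})

test_that("a uniform image is a fixed point under a symmetric PSF", {
  u <- array(5, c(5, 8, 8))
  out <- richardson_lucy(u, psf, 3L, pixel_size_um = 0.14, z_step_um = 0.5)
  expect_equal(out, u, tolerance = 1e-10)
})

test_that("flux is conserved within 0.1% per iteration and stays non-negative", {
  withr::with_seed(17, {
    arr <- array(rpois(7 * 24 * 24, 20), c(7, 24, 24))
  })
  prev <- sum(arr)
  for (i in 1:5) {
    out <- richardson_lucy(arr, psf, i, pixel_size_um = 0.14, z_step_um = 0.5)
    expect_true(all(out >= 0))
    expect_lt(abs(sum(out) - prev) / prev, 0.001 * i)
  }
})

test_that("deconvolving a blurred delta spike sharpens its peak monotonically", {
  arr <- array(0, c(9, 33, 33)); arr[5, 17, 17] <- 1000
  blurred <- gaussian_blur_3d(arr, 2, 1)
  peaks <- vapply(1:25, function(i) {
    max(richardson_lucy(blurred, psf_model(sigma_lateral_um = 0.28,
                                           sigma_axial_um = 0.5),
                        i, pixel_size_um = 0.14, z_step_um = 0.5))
  }, 0)
  expect_true(all(diff(peaks) > 0))
  # mass concentrates onto the spike voxel
  final <- richardson_lucy(blurred, psf, 25L, pixel_size_um = 0.14,
                           z_step_um = 0.5)
  expect_equal(which.max(final), which.max(arr))
})

test_that("input and kernel contracts are enforced", {
  bad <- array(1, c(2, 4, 4)); bad[1, 1, 1] <- -1
  expect_error(richardson_lucy(bad, psf, 3L),
               class = "punctate_validation_error")
  expect_error(richardson_lucy(array(1, c(2, 4, 4)), psf, -1),
               class = "punctate_validation_error")
  k <- array(1, c(3, 3, 3))
  expect_error(psf_model(kind = "supplied_kernel", kernel = k),
               class = "punctate_validation_error")
  expect_silent(psf_model(kind = "supplied_kernel", kernel = k / sum(k)))
})

test_that("supplied-kernel convolution agrees with the separable Gaussian path", {
  s_xy <- 1.1; s_z <- 0.8
  kz <- punctate:::gaussian_kernel_1d(s_z)
  kxy <- punctate:::gaussian_kernel_1d(s_xy)
  kern <- outer(outer(kz, kxy), kxy)
  withr::with_seed(4, arr <- array(runif(6 * 20 * 20, 0, 50), c(6, 20, 20)))
  sep <- gaussian_blur_3d(arr, s_xy, s_z)
  direct <- punctate:::kernel_convolve_3d(arr, kern)
  expect_equal(direct, sep, tolerance = 1e-10)
})

test_that("deconvolve_stack treats channels independently", {
  sc <- generate_scene(small_scene_params(seed = 13))
  out <- deconvolve_stack(sc$stack, psf, 2L, channels = "receptor")
  expect_equal(stack_channel(out, "marker"),
               stack_channel(sc$stack, "marker"),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_false(identical(stack_channel(out, "receptor"),
                         stack_channel(sc$stack, "receptor")))
  expect_error(deconvolve_stack(sc$stack, psf, 2L, channels = "nope"),
               class = "punctate_configuration_error")
})
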