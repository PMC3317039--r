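test_that("max-colocalization plane selection and its tie-break", {
  # construct planes with known overlap: plane 3 (0-based) gets the most
  v <- array(0, c(2, 5, 16, 16))
  overlap_px <- c(2, 5, 1, 9, 4)
  for (z in 1:5) {
    n <- overlap_px[z]
    v[1, z, 1, seq_len(n)] <- 100
    v[2, z, 1, seq_len(n)] <- 100
  }
  s <- confocal_stack(v, c("receptor", "marker"))
  expect_equal(select_max_coloc_plane(s, threshold_spec(50, 50)), 3L)

  single <- confocal_stack(array(0, c(2, 1, 8, 8)), c("receptor", "marker"))
  expect_equal(select_max_coloc_plane(single, threshold_spec(0, 0)), 0L)
  zeros <- confocal_stack(array(0, c(2, 4, 8, 8)), c("receptor", "marker"))
  expect_equal(select_max_coloc_plane(zeros, threshold_spec(0, 0)), 0L)
})

test_that("plane selection agrees with brute-force maximization on scenes", {
  withr::with_seed(41, {
    for (i in 1:3) {
      sc <- generate_scene(small_scene_params(seed = 100 + i))
      th <- threshold_spec(59, 59)
      want <- brute_neuropil(sc$stack, 59, 59)
      expect_equal(select_max_coloc_plane(sc$stack, th),
                   want$z[which.max(want$coloc_px)])
    }
  })
})

test_that("auto-trace recovers a synthetic annulus to within a pixel", {
  m <- matrix(0, 96, 96)
  d <- sqrt((row(m) - 1 - 47)^2 + (col(m) - 1 - 49)^2)
  m[abs(d - 30) <= 2] <- 100
  ct <- trace_membrane(m, 50)
  expect_s3_class(ct, "membrane_contour")
  expect_equal(ct$source, "auto_traced")
  cen <- colMeans(ct$vertices)
  expect_lt(abs(cen[1] - 47), 1)
  expect_lt(abs(cen[2] - 49), 1)
  radii <- sqrt((ct$vertices[, 1] - cen[1])^2 + (ct$vertices[, 2] - cen[2])^2)
  expect_lt(abs(mean(radii) - 32), 1)  # outer ring radius 30 + 2

  expect_error(trace_membrane(matrix(0, 32, 32), 10),
               class = "punctate_trace_error")
  manual <- contour_manual(cbind(c(0, 0, 5), c(0, 5, 0)))
  expect_equal(manual$source, "manual")
  expect_error(contour_manual(cbind(0, 1)), class = "punctate_validation_error")
})

test_that("band area matches the analytic annulus within 3%", {
  for (R in c(20, 50, 80)) {
    for (pxs in c(0.1, 0.2, 0.3)) {
      ang <- seq(0, 2 * pi, length.out = 257)[-257]
      ct <- contour_manual(cbind(109.5 + R * sin(ang), 109.5 + R * cos(ang)))
      band <- band_from_contour(ct, 2, pxs, c(220, 220))
      half <- 1 / pxs
      analytic <- pi * ((R + half)^2 - (R - half)^2)
      expect_lt(abs(sum(band) - analytic) / analytic, 0.03)
    }
  }
})

test_that("bands nest monotonically in thickness and honour the pixel floor", {
  ang <- seq(0, 2 * pi, length.out = 65)[-65]
  ct <- contour_manual(cbind(31.5 + 20 * sin(ang), 31.5 + 20 * cos(ang)))
  b1 <- band_from_contour(ct, 2, 0.2, c(64, 64))
  b2 <- band_from_contour(ct, 4, 0.2, c(64, 64))
  expect_true(all(b2[b1]))
  expect_gt(sum(b2), sum(b1))
  # one-pixel band hugs the outline: a band pixel sits within 1 px of every
  # vertex, and the thin band nests inside the 2 um band
  thin <- band_from_contour(ct, 0.2, 0.2, c(64, 64))
  on <- which(thin, arr.ind = TRUE) - 1
  for (i in seq_len(nrow(ct$vertices))) {
    d <- sqrt((on[, 1] - ct$vertices[i, 1])^2 + (on[, 2] - ct$vertices[i, 2])^2)
    expect_lt(min(d), 1)
  }
  expect_true(all(!(thin & !b1)))
  expect_error(band_from_contour(ct, 0.1, 0.2, c(64, 64)),
               class = "punctate_validation_error")
})

test_that("membrane measures recover planted footprints exactly when noiseless", {
  p <- clean_scene_params(n_synaptic = 4, n_extrasynaptic = 3,
                          n_intracellular = 5, seed = 14)
  sc <- generate_scene(p)
  mb <- membrane_measures(sc$stack, exact_thresholds(),
                          contour = sc$truth$contour_true)
  zi <- sc$truth$peak_plane_true + 1
  fs <- sc$truth$footprints$synaptic[zi, , ]
  fe <- sc$truth$footprints$extrasynaptic[zi, , ]
  expect_identical(mb$synaptic_mask, fs & mb$band_mask)
  expect_identical(mb$extrasynaptic_mask, fe & mb$band_mask)
  expect_equal(mb$plane_index, sc$truth$peak_plane_true)
})

test_that("synaptic and extrasynaptic pools partition receptor pixels in the band", {
  withr::with_seed(42, {
    for (i in 1:3) {
      s <- random_stack(nz = 3, ny = 48, nx = 48)
      ang <- seq(0, 2 * pi, length.out = 33)[-33]
      ct <- contour_manual(cbind(23.5 + 12 * sin(ang), 23.5 + 12 * cos(ang)))
      th <- threshold_spec(40, 40)
      mb <- membrane_measures(s, th, contour = ct)
      rp <- stack_plane(s, "receptor", mb$plane_index)
      in_band_receptor <- sum(binarize(rp, 40) & mb$band_mask)
      expect_equal(mb$synaptic_px + mb$extrasynaptic_px, in_band_receptor)
    }
  })
})

test_that("scene with no on-ring receptor puncta yields empty membrane pools", {
  p <- clean_scene_params(n_synaptic = 0, n_extrasynaptic = 0,
                          n_intracellular = 6, seed = 15)
  sc <- generate_scene(p)
  mb <- membrane_measures(sc$stack, exact_thresholds(),
                          contour = sc$truth$contour_true)
  expect_equal(mb$synaptic_px, 0L)
  expect_equal(mb$extrasynaptic_px, 0L)
})

test_that("trace failure without a manual contour instructs manual tracing", {
  zeros <- confocal_stack(array(0, c(2, 2, 16, 16)), c("receptor", "marker"))
  err <- expect_error(membrane_measures(zeros, threshold_spec(1, 1)),
                      class = "punctate_trace_error")
  expect_match(conditionMessage(err), "manual")
})

test_that("plane override is honoured and recorded", {
  sc <- generate_scene(small_scene_params(seed = 16))
  th <- threshold_spec(59, 59, min_component_px = 1)
  mb <- membrane_measures(sc$stack, th, contour = sc$truth$contour_true,
                          plane_override = 0L)
  expect_equal(mb$plane_index, 0L)
  expect_true(mb$plane_overridden)
})
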