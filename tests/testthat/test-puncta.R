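test_that("control-derived threshold is mean + k * population sd", {
  const <- confocal_stack(array(10, c(1, 1, 2, 2)), "receptor")
  expect_equal(derive_threshold(const, "receptor", k = 2), 10)

  v <- array(c(0, 0, 0, 4), c(1, 1, 2, 2))
  s <- confocal_stack(v, "receptor")
  expect_equal(derive_threshold(s, "receptor", k = 1), 1 + sqrt(3))

  # pooling two identical controls changes nothing
  expect_equal(derive_threshold(list(s, s), "receptor", k = 1),
               derive_threshold(s, "receptor", k = 1))
  expect_error(derive_threshold(list(), "receptor"),
               class = "punctate_validation_error")
})

test_that("binarization is strict and matches a pixel loop oracle", {
  expect_false(any(binarize(matrix(0, 4, 4), 0)))
  expect_identical(binarize(matrix(c(1, 5, 5, 1), 2, 2, byrow = TRUE), 4),
                   matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2, byrow = TRUE))
  withr::with_seed(31, {
    for (i in 1:5) {
      plane <- matrix(sample(0:50, 32 * 32, TRUE), 32, 32)
      t <- sample(0:50, 1)
      expect_identical(binarize(plane, t), brute_binarize(plane, t))
    }
  })
  expect_error(binarize(matrix(0, 2, 2), -1),
               class = "punctate_validation_error")
})

test_that("colocalization is pixel-wise AND", {
  withr::with_seed(32, {
    a <- matrix(runif(32 * 32) > 0.5, 32, 32)
    b <- matrix(runif(32 * 32) > 0.5, 32, 32)
  })
  expect_identical(colocalize(a, a), a)
  expect_false(any(colocalize(a, !a)))
  expect_identical(colocalize(a, b), brute_colocalize(a, b))
  expect_error(colocalize(a, b[1:10, ]), class = "punctate_validation_error")
})

test_that("component labelling is 8-connected with a size floor", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE   # touch only diagonally
  expect_equal(count_components(m), 1L)
  m[5, 5] <- TRUE
  expect_equal(count_components(m), 2L)
  expect_equal(count_components(m, min_px = 2L), 1L)
  expect_equal(count_components(matrix(FALSE, 3, 3)), 0L)
})

test_that("neuropil measures match the triple-loop oracle on random stacks", {
  withr::with_seed(33, {
    for (i in 1:5) {
      s <- random_stack(nz = 4, ny = 24, nx = 24)
      tr <- sample(0:80, 1); tm <- sample(0:80, 1)
      got <- neuropil_measures(s, threshold_spec(tr, tm))
      want <- brute_neuropil(s, tr, tm)
      expect_equal(as.data.frame(got$per_plane), want)
      expect_equal(got$totals$receptor_px_total, sum(want$receptor_px))
      expect_equal(got$totals$coloc_px_total, sum(want$coloc_px))
    }
  })
})

test_that("neuropil totals are additive over duplicated planes", {
  s <- random_stack(nz = 3, ny = 16, nx = 16)
  v2 <- array(0, c(2, 6, 16, 16))
  v2[, 1:3, , ] <- s$voxels
  v2[, 4:6, , ] <- s$voxels
  s2 <- confocal_stack(v2, s$channel_names, s$pixel_size_um, s$z_step_um)
  th <- threshold_spec(40, 40)
  expect_equal(neuropil_measures(s2, th)$totals$receptor_px_total,
               2L * neuropil_measures(s, th)$totals$receptor_px_total)
  zero <- confocal_stack(array(0, c(2, 2, 8, 8)), c("receptor", "marker"))
  tot <- neuropil_measures(zero, th)$totals
  expect_true(all(unlist(tot) == 0))
})

test_that("coloc is bounded by each channel and monotone in threshold", {
  withr::with_seed(34, {
    for (i in 1:5) {
      s <- random_stack(nz = 3, ny = 20, nx = 20)
      m <- neuropil_measures(s, threshold_spec(30, 30))$per_plane
      expect_true(all(m$coloc_px <= pmin(m$receptor_px, m$marker_px)))
      hi <- neuropil_measures(s, threshold_spec(60, 30))$per_plane
      expect_true(all(hi$receptor_px <= m$receptor_px))
      expect_true(all(hi$coloc_px <= m$coloc_px))
    }
  })
})

test_that("planted synaptic puncta are counted exactly on a noiseless scene", {
  p <- clean_scene_params(n_synaptic = 5, n_extrasynaptic = 0,
                          n_intracellular = 0, n_marker_only = 0, seed = 12)
  sc <- generate_scene(p)
  got <- neuropil_measures(sc$stack, exact_thresholds(), count_puncta = TRUE)
  expect_equal(got$components$coloc_component_count, 5L)
  expect_error(neuropil_measures(
    confocal_stack(array(0, c(1, 1, 4, 4)), "receptor"),
    exact_thresholds()), class = "punctate_configuration_error")
})
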