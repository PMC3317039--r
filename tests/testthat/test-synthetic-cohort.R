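test_that("cohort design matches the sampling protocol", {
  rc <- simulate_cohort_counts(null_dose_model(), n_subjects_per_dose = 4,
                               neurons_per_side = 13, seed = 1)
  # 3 doses x 4 subjects x 2 sides x 13 sampling points
  expect_equal(nrow(rc), 3 * 4 * 2 * 13)
  expect_setequal(unique(rc$distance_um), seq(-600, 600, by = 100))
  expect_setequal(unique(rc$dose_um), c(0.01, 0.1, 1.0))
  expect_equal(dplyr::n_distinct(rc$subject_id), 12)
  per_subj <- dplyr::count(rc, subject_id, side)
  expect_true(all(per_subj$n == 13))
})

test_that("degenerate dose model yields deterministic baseline counts", {
  m <- null_dose_model(dispersion = 0)
  rc <- simulate_cohort_counts(m, 2, 3, seed = 1)
  contra <- rc[rc$side == "contralateral", ]
  expect_true(all(contra$n_synaptic_true == m$baseline[["synaptic"]]))
  total <- sum(m$baseline)
  expect_true(all((contra$n_synaptic_true + contra$n_extrasynaptic_true +
                     contra$n_intracellular_true) == total))
})

test_that("U-shaped dose model orders injected-side mean totals high > low > mid", {
  rc <- simulate_cohort_counts(dose_model(), n_subjects_per_dose = 20,
                               neurons_per_side = 5, seed = 11)
  inj <- rc[rc$side == "injected", ]
  means <- tapply(inj$neuropil_total_px, inj$dose_um, mean)
  expect_gt(means[["1"]], means[["0.01"]])
  expect_gt(means[["0.01"]], means[["0.1"]])
})

test_that("high-dose spread carries the effect onto the contralateral side", {
  m <- dose_model(dispersion = 0)
  rc <- simulate_cohort_counts(m, 1, 3, seed = 2)
  con <- rc[rc$side == "contralateral", ]
  base_total <- sum(m$baseline)
  # near-full spread at the high dose, weak at the low dose
  high <- mean(con$neuropil_total_px[con$dose_um == 1]) / 13
  low <- mean(con$neuropil_total_px[con$dose_um == 0.01]) / 13
  expect_gt(high / base_total, 1.5)
  expect_lt(low / base_total, 1.1)
})

test_that("cohort generation is reproducible and respects drawn counts", {
  m <- dose_model(dispersion = 0.05)
  co <- generate_cohort(m, n_subjects_per_dose = 1, neurons_per_side = 1,
                        scene_template = small_scene_params(), seed = 31)
  co2 <- generate_cohort(m, n_subjects_per_dose = 1, neurons_per_side = 1,
                         scene_template = small_scene_params(), seed = 31)
  expect_equal(length(co$scenes), nrow(co$records))
  expect_identical(co$scenes[[1]]$stack$voxels, co2$scenes[[1]]$stack$voxels)
  for (i in seq_along(co$scenes)) {
    expect_equal(co$scenes[[i]]$truth$counts_true[["synaptic"]],
                 co$records$n_synaptic_true[i])
  }
  expect_error(simulate_cohort_counts(null_dose_model(), 0, 3, seed = 1),
               class = "punctate_validation_error")
  expect_error(dose_model(doses_um = numeric()),
               class = "punctate_validation_error")
})
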