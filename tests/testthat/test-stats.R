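test_that("mixed ANOVA uses classical strata when balanced, lmer when not", {
  rc <- simulate_cohort_counts(dose_model(), 4, 5, seed = 3)
  a <- mixed_anova(rc, "membrane_synaptic_px")
  expect_equal(a$engine, "aov_strata")
  expect_setequal(a$table$term, c("dose", "side", "distance", "dose:side"))
  expect_lt(a$table$p.value[a$table$term == "dose"], 0.05)

  expect_warning(a2 <- mixed_anova(rc[-1, ], "membrane_synaptic_px"),
                 "unbalanced")
  expect_equal(a2$engine, "lmer")
  expect_lt(a2$table$p.value[a2$table$term == "dose"], 0.05)
})

test_that("classical and mixed-model dose F agree on balanced Gaussian data", {
  withr::with_seed(8, {
    rc <- simulate_cohort_counts(null_dose_model(), 4, 5, seed = 8)
    subj_eff <- rnorm(12, sd = 6)
    names(subj_eff) <- unique(rc$subject_id)
    rc$y <- rnorm(nrow(rc), sd = 3) + subj_eff[rc$subject_id] + 50
  })
  a <- mixed_anova(rc, "y")
  cells <- aggregate_cells(rc, "y")
  cells$.y <- cells$y
  fit <- suppressMessages(lmerTest::lmer(
    .y ~ dose * side_f + distance_f + (1 | subject_id), data = cells))
  at <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  expect_equal(a$table$statistic[a$table$term == "dose"],
               at["dose", "F value"], tolerance = 1e-6)
  expect_equal(a$table$den_df[a$table$term == "dose"], at["dose", "DenDF"],
               tolerance = 1e-6)
})

test_that("degenerate constant outcome reports p = 1", {
  rc <- simulate_cohort_counts(null_dose_model(dispersion = 0), 2, 3, seed = 1)
  a <- mixed_anova(rc, "membrane_synaptic_px")
  expect_true(all(a$table$p.value == 1))
  expect_true(all(a$table$statistic == 0))
})

test_that("design contracts are enforced", {
  rc <- simulate_cohort_counts(null_dose_model(), 2, 3, seed = 2)
  one_dose <- rc[rc$dose_um == 0.01, ]
  expect_error(mixed_anova(one_dose, "membrane_synaptic_px"),
               class = "punctate_validation_error")
  one_side <- rc[rc$side == "injected", ]
  expect_error(mixed_anova(one_side, "membrane_synaptic_px"),
               class = "punctate_validation_error")
  two_doses <- rc[rc$dose_um != 1, ]
  expect_error(tukey_posthoc(two_doses, "membrane_synaptic_px"),
               class = "punctate_validation_error")
})

test_that("Tukey flags the planted U-shape contrasts", {
  rc <- simulate_cohort_counts(dose_model(), 4, 13, seed = 5)
  tk <- tukey_posthoc(rc, "neuropil_total_px")
  expect_equal(nrow(tk), 3)
  lowmid <- tk[tk$contrast == "0.1-0.01", ]   # mid minus low
  highmid <- tk[tk$contrast == "1-0.1", ]     # high minus mid
  expect_lt(lowmid$estimate, 0)
  expect_lt(lowmid$adj.p.value, 0.05)
  expect_gt(highmid$estimate, 0)
  expect_lt(highmid$adj.p.value, 0.05)
})

test_that("ANCOVA recovers a planted covariate slope and the dose effect", {
  withr::with_seed(9, {
    rc <- simulate_cohort_counts(null_dose_model(), 20, 5, seed = 9)
    eff <- c("0.01" = 0, "0.1" = -15, "1" = 40)
    rc$syn <- 0.5 * rc$neuropil_total_px + eff[as.character(rc$dose_um)] +
      rnorm(nrow(rc), sd = 10)
  })
  ac <- ancova(rc, "syn", "neuropil_total_px")
  expect_equal(ac$slope, 0.5, tolerance = 0.1)  # 0.45..0.55
  expect_lt(abs(ac$slope - 0.5), 0.05)
  expect_lt(ac$table$p.value[ac$table$term == "dose"], 0.05)
})

test_that("ANCOVA rejects a constant covariate", {
  rc <- simulate_cohort_counts(null_dose_model(), 2, 3, seed = 10)
  rc$flat <- 7
  expect_error(ancova(rc, "membrane_synaptic_px", "flat"),
               class = "punctate_validation_error")
})

test_that("blot normalization arithmetic", {
  expect_equal(normalize_blot(10, 5), 2.0)
  expect_equal(normalize_blot(3 * 10, 3 * 5), 2.0)  # scale invariance
  expect_error(normalize_blot(10, 0), class = "punctate_validation_error")

  lanes <- tibble::tibble(
    lane_id = rep(c("s1", "s2"), each = 2),
    condition = rep(c("TNFa", "albumin"), each = 2),
    run = rep(1:2, 2),
    receptor_band_intensity = c(10, 20, 8, 8),
    loading_control_intensity = c(5, 5, 4, 2))
  avg <- average_blot_runs(lanes)
  expect_equal(avg$normalized_ratio[avg$lane_id == "s1"], mean(c(2, 4)))
  expect_equal(avg$normalized_ratio[avg$lane_id == "s2"], mean(c(2, 4)))
  expect_true(all(avg$n_runs == 2))
})

test_that("linear-range R2 behaves like OLS", {
  x <- c(1, 2, 4, 8, 16)
  expect_equal(suppressWarnings(linear_range_r2(x, 3 + 2 * x)), 1.0)
  expect_equal(suppressWarnings(linear_range_r2(rep(x, 2), rep(3 + 2 * x, 2))),
               1.0)
  expect_error(linear_range_r2(1:2, 1:2), class = "punctate_validation_error")
  withr::with_seed(11, {
    r2 <- replicate(50, linear_range_r2(runif(200), runif(200)))
  })
  expect_lt(mean(r2), 0.05)
})

test_that("lane background correction subtracts flanking medians", {
  flat <- rep(5, 20)
  expect_equal(band_background_correct(flat, c(8, 12)), 0)
  prof <- rep(5, 20); prof[8:12] <- 5 + 3
  expect_equal(band_background_correct(prof, c(8, 12)), 3 * 5)
  expect_equal(band_background_correct(2 * prof, c(8, 12)),
               2 * band_background_correct(prof, c(8, 12)))
  expect_error(band_background_correct(prof, c(1, 5)),
               class = "punctate_validation_error")
})
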