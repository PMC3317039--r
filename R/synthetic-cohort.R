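#' Dose–response model for simulated cohorts
#'
#' Encodes the experimental design and the planted biology: three TNFa doses
#' (plus a contralateral vehicle side within each subject), per-pool baseline
#' puncta counts, multiplicative dose effects per pool, a contralateral
#' "spread" fraction, and negative-binomial overdispersion of per-neuron
#' counts.
#'
#' The default effect profile is U-shaped in the total and extrasynaptic
#' pools (middle dose below the low dose, high dose above both) and
#' high-dose-dominant in the synaptic pool, with spread near 1 at the high
#' dose — i.e. the high-dose effect extends essentially undiminished onto the
#' contralateral side — and small spread at the low dose. Effect magnitudes
#' are simulation parameters, not measured values.
#'
#' @param doses_um ordered dose levels in micromolar.
#' @param baseline named per-pool expected counts at dose 0
#'   (`synaptic`, `extrasynaptic`, `intracellular`).
#' @param total_factor,synaptic_factor,extrasynaptic_factor multiplicative
#'   effect per dose (same order as `doses_um`) for the total receptor pool
#'   and the two membrane pools. The intracellular factor is derived so the
#'   pool sum matches `total_factor`.
#' @param spread per-dose fraction of the injected-side effect expressed on
#'   the contralateral side: the contralateral factor is
#'   `1 + (f - 1) * spread`.
#' @param dispersion negative-binomial overdispersion: counts have variance
#'   `mu + dispersion * mu^2`. `0` makes planted counts deterministic
#'   (`round(mu)`).
#' @param distance_taper_um e-folding scale of a Gaussian taper of the effect
#'   with rostrocaudal distance; `Inf` (default) models the observed
#'   widespread effect with no distance decay.
#' @return A list of class `dose_model`.
#' @export
dose_model <- function(doses_um = c(0.01, 0.1, 1.0),
                       baseline = c(synaptic = 12, extrasynaptic = 8,
                                    intracellular = 20),
                       total_factor = c(1.3, 0.8, 1.8),
                       synaptic_factor = c(1.1, 1.0, 2.0),
                       extrasynaptic_factor = c(1.4, 0.8, 1.9),
                       spread = c(0.1, 0.5, 0.95),
                       dispersion = 0.05,
                       distance_taper_um = Inf) {
  if (length(doses_um) == 0L) {
    stop_punctate("dose set must be non-empty", "punctate_validation_error")
  }
  n <- length(doses_um)
  stopifnot(length(total_factor) == n, length(synaptic_factor) == n,
            length(extrasynaptic_factor) == n, length(spread) == n)
  if (dispersion < 0) {
    stop_punctate("dispersion must be >= 0", "punctate_validation_error")
  }
  if (!all(c("synaptic", "extrasynaptic", "intracellular") %in% names(baseline))) {
    stop_punctate("baseline needs synaptic, extrasynaptic, intracellular",
                  "punctate_validation_error")
  }
  structure(list(doses_um = doses_um, baseline = baseline,
                 total_factor = total_factor,
                 synaptic_factor = synaptic_factor,
                 extrasynaptic_factor = extrasynaptic_factor,
                 spread = spread, dispersion = dispersion,
                 distance_taper_um = distance_taper_um),
            class = "dose_model")
}

#' A dose model with no effect anywhere (for null simulations)
#' @inheritParams dose_model
#' @param ... passed on to [dose_model()].
#' @return A `dose_model` whose effect factors are all 1 and spread 0.
#' @export
null_dose_model <- function(doses_um = c(0.01, 0.1, 1.0), ...) {
  n <- length(doses_um)
  dose_model(doses_um = doses_um, total_factor = rep(1, n),
             synaptic_factor = rep(1, n), extrasynaptic_factor = rep(1, n),
             spread = rep(0, n), ...)
}

# Expected per-pool counts for one neuron.
expected_counts <- function(model, dose_um, side, distance_um) {
  i <- match(dose_um, model$doses_um)
  if (is.na(i)) {
    stop_punctate(sprintf("dose %g not in model", dose_um),
                  "punctate_validation_error")
  }
  b <- model$baseline
  btot <- sum(b)
  f_syn <- model$synaptic_factor[i]
  f_ext <- model$extrasynaptic_factor[i]
  f_tot <- model$total_factor[i]
  f_int <- (f_tot * btot - f_syn * b[["synaptic"]] - f_ext * b[["extrasynaptic"]]) /
    b[["intracellular"]]
  f_int <- max(f_int, 0.05)
  f <- c(synaptic = f_syn, extrasynaptic = f_ext, intracellular = f_int)
  taper <- if (is.finite(model$distance_taper_um)) {
    exp(-distance_um^2 / (2 * model$distance_taper_um^2))
  } else 1
  f <- 1 + (f - 1) * taper
  if (side == "contralateral") f <- 1 + (f - 1) * model$spread[i]
  b * f
}

draw_counts <- function(model, mu) {
  if (model$dispersion == 0) return(round(mu))
  vapply(mu, function(m) {
    stats::rnbinom(1L, size = 1 / model$dispersion, mu = m)
  }, 0)
}

# Distance grid: `n` sampling points spaced 100 um, centred on the injection.
distance_grid <- function(n) {
  100 * (seq_len(n) - (n + 1) / 2)
}

#' Simulate a cohort at the count level
#'
#' Draws planted per-pool puncta counts for every neuron of a full design —
#' `n_subjects_per_dose` subjects per dose, both hemicord sides per subject,
#' one neuron per 100 um rostrocaudal sampling point — without rendering
#' images. Count-level cohorts drive the Monte-Carlo statistics (type-I
#' calibration, power, dose-pattern replication); the rendered image pipeline
#' uses the identical dose model.
#'
#' Pixel-scaled outcome columns (`*_px`) are the planted counts times a
#' nominal punctum footprint area, giving the same units the image pipeline
#' reports.
#'
#' @param model a [dose_model()].
#' @param n_subjects_per_dose subjects per dose group (default 4).
#' @param neurons_per_side sampling points per hemicord (default 13:
#'   -600..600 um at 100 um spacing).
#' @param seed integer seed.
#' @param punctum_area_px nominal footprint area used for the `*_px` columns.
#' @return A tibble with one row per neuron: design factors, planted counts
#'   (`n_synaptic_true` etc.) and outcome columns `neuropil_total_px`,
#'   `neuropil_synaptic_px`, `membrane_synaptic_px`,
#'   `membrane_extrasynaptic_px`.
#' @export
simulate_cohort_counts <- function(model, n_subjects_per_dose = 4L,
                                   neurons_per_side = 13L, seed = 1L,
                                   punctum_area_px = 13) {
  stopifnot(inherits(model, "dose_model"))
  if (n_subjects_per_dose < 1L) {
    stop_punctate("need at least one subject per dose", "punctate_validation_error")
  }
  withr::with_seed(seed, {
    dists <- distance_grid(neurons_per_side)
    grid <- tidyr::expand_grid(
      dose_um = model$doses_um,
      subject = seq_len(n_subjects_per_dose),
      side = c("injected", "contralateral"),
      distance_um = dists)
    grid$subject_id <- sprintf("d%g_s%d", grid$dose_um, grid$subject)
    counts <- purrr::pmap(
      list(grid$dose_um, grid$side, grid$distance_um),
      function(dose, side, dist) {
        mu <- expected_counts(model, dose, side, dist)
        draw_counts(model, mu)
      })
    grid$n_synaptic_true <- vapply(counts, `[[`, 0, "synaptic")
    grid$n_extrasynaptic_true <- vapply(counts, `[[`, 0, "extrasynaptic")
    grid$n_intracellular_true <- vapply(counts, `[[`, 0, "intracellular")
    grid$neuron_id <- sprintf("%s_%s_%+05.0f", grid$subject_id,
                              substr(grid$side, 1, 3), grid$distance_um)
    total <- grid$n_synaptic_true + grid$n_extrasynaptic_true +
      grid$n_intracellular_true
    out <- tibble::as_tibble(grid[, c("subject_id", "neuron_id", "dose_um",
                                      "side", "distance_um",
                                      "n_synaptic_true", "n_extrasynaptic_true",
                                      "n_intracellular_true")])
    out$neuropil_total_px <- total * punctum_area_px
    out$neuropil_synaptic_px <- out$n_synaptic_true * punctum_area_px
    out$membrane_synaptic_px <- out$n_synaptic_true * punctum_area_px
    out$membrane_extrasynaptic_px <- out$n_extrasynaptic_true * punctum_area_px
    out
  })
}

#' Generate a rendered synthetic cohort
#'
#' Draws planted counts from the dose model exactly as
#' [simulate_cohort_counts()] does, then renders each neuron as a full
#' two-channel scene via [generate_scene()]. Reproducible: every scene gets a
#' seed derived deterministically from `seed` and its row index.
#'
#' @inheritParams simulate_cohort_counts
#' @param scene_template a [scene_params()] object; its per-pool counts are
#'   overridden per neuron by the dose-model draws.
#' @return A list with `records` (the count-level tibble) and `scenes` (a list
#'   of `list(stack, truth, metadata)` in row order).
#' @export
generate_cohort <- function(model, n_subjects_per_dose = 4L,
                            neurons_per_side = 13L,
                            scene_template = scene_params(),
                            seed = 1L) {
  records <- simulate_cohort_counts(model, n_subjects_per_dose,
                                    neurons_per_side, seed = seed)
  scenes <- purrr::map(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    p <- scene_template
    p$n_synaptic <- as.integer(r$n_synaptic_true)
    p$n_extrasynaptic <- as.integer(r$n_extrasynaptic_true)
    p$n_intracellular <- as.integer(r$n_intracellular_true)
    p$seed <- child_seed(seed, i)
    sc <- generate_scene(p)
    meta <- scene_metadata(r$subject_id, r$neuron_id, r$dose_um, r$side,
                           r$distance_um)
    list(stack = sc$stack, truth = sc$truth, metadata = meta)
  })
  list(records = records, scenes = scenes)
}
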