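#' Build a pipeline run configuration
#'
#' Collects every knob of a full simulate-measure-analyze run into one
#' serializable list. All randomized stages draw from seeds derived from the
#' single `seed`, so a configuration identifies its outputs exactly.
#'
#' @param seed master integer seed.
#' @param scene a [scene_params()] object (template for rendered neurons).
#' @param model a [dose_model()].
#' @param n_subjects_per_dose,neurons_per_side cohort design.
#' @param threshold_k control-threshold sd multiplier.
#' @param min_component_px punctum size floor in pixels.
#' @param deconvolve logical; run Richardson-Lucy before quantification.
#' @param rl_iterations Richardson-Lucy iteration count (default 3).
#' @param psf a [psf_model()] used when deconvolving.
#' @param band_thickness_um membrane band thickness.
#' @param outcome,covariate columns analyzed by the mixed ANOVA / ANCOVA.
#' @param output_dir directory for tables and logs; created if missing.
#'   `NULL` keeps everything in memory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       scene = scene_params(),
                       model = dose_model(),
                       n_subjects_per_dose = 2L,
                       neurons_per_side = 3L,
                       threshold_k = 3,
                       min_component_px = 4L,
                       deconvolve = FALSE,
                       rl_iterations = 3L,
                       psf = psf_model(),
                       band_thickness_um = 2,
                       outcome = "membrane_synaptic_px",
                       covariate = "neuropil_total_px",
                       output_dir = NULL) {
  structure(list(seed = as.integer(seed), scene = scene, model = model,
                 n_subjects_per_dose = as.integer(n_subjects_per_dose),
                 neurons_per_side = as.integer(neurons_per_side),
                 threshold_k = threshold_k,
                 min_component_px = as.integer(min_component_px),
                 deconvolve = isTRUE(deconvolve),
                 rl_iterations = as.integer(rl_iterations), psf = psf,
                 band_thickness_um = band_thickness_um,
                 outcome = outcome, covariate = covariate,
                 output_dir = output_dir),
            class = "run_config")
}

stage_abort <- function(stage, e, record = NULL) {
  where <- if (is.null(record)) stage else sprintf("%s [record %s]", stage, record)
  stop_punctate(sprintf("pipeline stage '%s' failed: %s", where,
                        conditionMessage(e)),
                "punctate_pipeline_error")
}

#' Run the full simulate-measure-analyze pipeline
#'
#' Orchestrates: cohort simulation (rendered scenes), control-based threshold
#' derivation, optional Richardson-Lucy deconvolution, neuropil and
#' membrane-band quantification, and the statistical battery (mixed ANOVA,
#' Tukey post-hoc, ANCOVA). Deterministic given the configuration seed. When
#' `config$output_dir` is set, the measurement table, stats tables, the
#' verbatim configuration and a log are written there; a cached measurement
#' table from an identical configuration is reused so the statistics can be
#' re-run without re-imaging.
#'
#' @param config a [run_config()].
#' @return A list: `measurements` (tibble), `thresholds`, `anova`, `tukey`,
#'   `ancova`, `log` (character vector of stage messages).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  cfg_hash <- rlang::hash(config[setdiff(names(config), "output_dir")])
  say("config hash %s", cfg_hash)

  out_dir <- config$output_dir
  cache <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cache_path <- file.path(out_dir, "measurements.tsv")
    hash_path <- file.path(out_dir, "config_hash.txt")
    if (file.exists(cache_path) && file.exists(hash_path) &&
        readLines(hash_path)[1] == cfg_hash) {
      cache <- readr::read_tsv(cache_path, show_col_types = FALSE,
                               comment = "#")
      say("stage simulate+measure: reusing cached measurements.tsv")
    }
  }

  thresholds <- NULL
  if (is.null(cache)) {
    # -- simulate ----------------------------------------------------------
    cohort <- tryCatch(
      generate_cohort(config$model, config$n_subjects_per_dose,
                      config$neurons_per_side,
                      scene_template = config$scene, seed = config$seed),
      error = function(e) stage_abort("simulate", e))
    say("stage simulate: %d scenes", length(cohort$scenes))

    # control scene: background only, same optics/noise
    ctrl_params <- config$scene
    ctrl_params$n_synaptic <- ctrl_params$n_extrasynaptic <- 0L
    ctrl_params$n_intracellular <- ctrl_params$n_marker_only <- 0L
    ctrl_params$ring_amplitude <- 0
    ctrl_params$seed <- child_seed(config$seed, 999L)
    control <- tryCatch(generate_scene(ctrl_params)$stack,
                        error = function(e) stage_abort("simulate-control", e))

    # -- deconvolve --------------------------------------------------------
    if (config$deconvolve) {
      control <- tryCatch(
        deconvolve_stack(control, config$psf, config$rl_iterations),
        error = function(e) stage_abort("deconvolve", e))
      cohort$scenes <- purrr::imap(cohort$scenes, function(sc, i) {
        sc$stack <- tryCatch(
          deconvolve_stack(sc$stack, config$psf, config$rl_iterations),
          error = function(e) stage_abort("deconvolve", e, i))
        sc
      })
      say("stage deconvolve: %d Richardson-Lucy iterations",
          config$rl_iterations)
    }

    # -- thresholds --------------------------------------------------------
    thresholds <- tryCatch(
      threshold_spec(
        derive_threshold(control, "receptor", config$threshold_k),
        derive_threshold(control, "marker", config$threshold_k),
        method = "control_mean_plus_k_sd", k = config$threshold_k,
        min_component_px = config$min_component_px),
      error = function(e) stage_abort("derive-threshold", e))
    say("stage derive-threshold: receptor %.4g, marker %.4g (k = %g)",
        thresholds$receptor_threshold, thresholds$marker_threshold,
        config$threshold_k)

    # -- quantify ----------------------------------------------------------
    if (!all(c("receptor", "marker") %in% cohort$scenes[[1]]$stack$channel_names)) {
      stage_abort("quantify-neuropil",
                  simpleError("stack lacks receptor/marker channels"))
    }
    measurements <- tryCatch(
      measure_cohort(cohort$scenes, thresholds,
                     thickness_um = config$band_thickness_um,
                     recover_counts = TRUE),
      error = function(e) stage_abort("quantify-membrane", e))
    say("stage quantify: %d records", nrow(measurements))

    if (!is.null(out_dir)) {
      readr::write_tsv(measurements, file.path(out_dir, "measurements.tsv"))
      writeLines(cfg_hash, file.path(out_dir, "config_hash.txt"))
      writeLines(yaml::as.yaml(serialize_config(config)),
                 file.path(out_dir, "config.yaml"))
      writeLines(sprintf("receptor_threshold=%.10g\nmarker_threshold=%.10g",
                         thresholds$receptor_threshold,
                         thresholds$marker_threshold),
                 file.path(out_dir, "thresholds.txt"))
    }
  } else {
    measurements <- cache
  }

  # -- analyze -------------------------------------------------------------
  res_anova <- tryCatch(mixed_anova(measurements, config$outcome),
                        error = function(e) stage_abort("analyze-anova", e))
  res_tukey <- tryCatch(tukey_posthoc(measurements, config$outcome),
                        error = function(e) stage_abort("analyze-tukey", e))
  res_ancova <- tryCatch(
    ancova(measurements, config$outcome, config$covariate),
    error = function(e) stage_abort("analyze-ancova", e))
  say("stage analyze: outcome %s, covariate %s", config$outcome,
      config$covariate)

  if (!is.null(out_dir)) {
    readr::write_tsv(tidy(res_anova), file.path(out_dir, "anova.tsv"))
    readr::write_tsv(res_tukey, file.path(out_dir, "tukey.tsv"))
    readr::write_tsv(tidy(res_ancova), file.path(out_dir, "ancova.tsv"))
    writeLines(log, file.path(out_dir, "run.log"))
  }

  list(measurements = measurements, thresholds = thresholds,
       anova = res_anova, tukey = res_tukey, ancova = res_ancova, log = log)
}

# Flatten the config into plain lists for YAML serialization.
serialize_config <- function(config) {
  lapply(unclass(config), function(x) {
    if (inherits(x, c("scene_params", "dose_model", "psf_model"))) {
      lapply(unclass(x), function(v) if (is.null(v)) NULL else unname(v))
    } else x
  })
}
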