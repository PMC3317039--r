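#' Recover per-class puncta counts from one scene
#'
#' Classifies discrete receptor puncta into the three pools using only the
#' measurement pipeline (no ground truth): binarize the z-maximum projection
#' of each channel, label 8-connected receptor components of at least
#' `thresholds$min_component_px` pixels, build the membrane band on the
#' max-colocalization plane, and assign each component by overlap — band and
#' marker-positive = synaptic; band and marker-negative = extrasynaptic;
#' off-band = intracellular. The maximum projection collapses axial PSF
#' spread so each planted punctum is counted once.
#'
#' @inheritParams membrane_measures
#' @return One-row tibble: `synaptic`, `extrasynaptic`, `intracellular`,
#'   `plane_index`.
#' @export
recover_scene_counts <- function(stack, thresholds, contour = NULL,
                                 thickness_um = 2, close_radius_px = 0L) {
  rec <- stack_channel(stack, "receptor")
  mrk <- stack_channel(stack, "marker")
  rproj <- apply(rec, c(2, 3), max)
  mproj <- apply(mrk, c(2, 3), max)
  rmask <- binarize(rproj, thresholds$receptor_threshold)
  mmask <- binarize(mproj, thresholds$marker_threshold)

  plane <- select_max_coloc_plane(stack, thresholds)
  if (is.null(contour)) {
    contour <- trace_membrane(stack_plane(stack, "marker", plane),
                              thresholds$marker_threshold,
                              min_component_px = thresholds$min_component_px,
                              close_radius_px = close_radius_px)
  }
  band <- band_from_contour(contour, thickness_um, stack$pixel_size_um,
                            dim(rproj))
  lab <- label_components(rmask)
  n <- max(lab)
  counts <- c(synaptic = 0L, extrasynaptic = 0L, intracellular = 0L)
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = n)
    for (i in seq_len(n)) {
      if (sizes[i] < thresholds$min_component_px) next
      sel <- lab == i
      if (any(sel & band)) {
        # classify by the marker status of the component's band pixels
        if (sum(sel & band & mmask) >= sum(sel & band & !mmask)) {
          counts["synaptic"] <- counts["synaptic"] + 1L
        } else {
          counts["extrasynaptic"] <- counts["extrasynaptic"] + 1L
        }
      } else {
        counts["intracellular"] <- counts["intracellular"] + 1L
      }
    }
  }
  tibble::tibble(synaptic = counts[["synaptic"]],
                 extrasynaptic = counts[["extrasynaptic"]],
                 intracellular = counts[["intracellular"]],
                 plane_index = plane)
}

#' Measure every scene of a cohort
#'
#' Runs the neuropil macro and the membrane macro over a list of scenes and
#' joins the results to the design metadata, producing the analysis-ready
#' cohort table. The ground-truth contour plays the role of the blinded
#' manual membrane trace when `use_true_contour = TRUE` (default); set it
#' `FALSE` to auto-trace the marker ring instead.
#'
#' @param scenes list of `list(stack, truth, metadata)` entries, as produced
#'   by [generate_cohort()]`$scenes`.
#' @param thresholds a [threshold_spec()].
#' @param thickness_um membrane band thickness (default 2 um).
#' @param use_true_contour use the ground-truth contour as the manual trace.
#' @param close_radius_px closing radius for auto-tracing.
#' @param recover_counts also run [recover_scene_counts()] per scene.
#' @return Tibble with one row per neuron: metadata columns, neuropil totals
#'   (`neuropil_total_px`, `neuropil_synaptic_px`), membrane-band counts
#'   (`membrane_synaptic_px`, `membrane_extrasynaptic_px`, `plane_index`),
#'   planted ground-truth counts, and (optionally) recovered counts.
#' @export
measure_cohort <- function(scenes, thresholds, thickness_um = 2,
                           use_true_contour = TRUE, close_radius_px = 0L,
                           recover_counts = FALSE) {
  rows <- purrr::map(scenes, function(sc) {
    contour <- if (use_true_contour) sc$truth$contour_true else NULL
    np <- neuropil_measures(sc$stack, thresholds)
    mb <- membrane_measures(sc$stack, thresholds, contour = contour,
                            thickness_um = thickness_um,
                            close_radius_px = close_radius_px)
    out <- dplyr::bind_cols(
      sc$metadata,
      tibble::tibble(
        neuropil_total_px = np$totals$receptor_px_total,
        neuropil_synaptic_px = np$totals$coloc_px_total,
        membrane_synaptic_px = mb$synaptic_px,
        membrane_extrasynaptic_px = mb$extrasynaptic_px,
        plane_index = mb$plane_index,
        n_synaptic_true = sc$truth$counts_true[["synaptic"]],
        n_extrasynaptic_true = sc$truth$counts_true[["extrasynaptic"]],
        n_intracellular_true = sc$truth$counts_true[["intracellular"]]))
    if (recover_counts) {
      rc <- recover_scene_counts(sc$stack, thresholds, contour = contour,
                                 thickness_um = thickness_um,
                                 close_radius_px = close_radius_px)
      out$recovered_synaptic <- rc$synaptic
      out$recovered_extrasynaptic <- rc$extrasynaptic
      out$recovered_intracellular <- rc$intracellular
    }
    out
  })
  dplyr::bind_rows(rows)
}
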