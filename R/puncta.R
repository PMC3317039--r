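#' Per-channel binarization thresholds
#'
#' Thresholds are applied with a strict inequality: a pixel counts as signal
#' when its raw stored intensity *exceeds* the cutoff. Cutoffs are either fixed
#' or derived from negative-control stacks as mean + k * sd (see
#' [derive_threshold()]).
#'
#' @param receptor_threshold,marker_threshold intensity cutoffs (>= 0).
#' @param method `"fixed"` or `"control_mean_plus_k_sd"` (bookkeeping: how the
#'   cutoffs were obtained).
#' @param k the sd multiplier used when control-derived. Default 3.
#' @param min_component_px minimum in-plane connected-component size (pixels)
#'   for a component to count as a punctum.
#' @return A list of class `threshold_spec`.
#' @export
threshold_spec <- function(receptor_threshold, marker_threshold,
                           method = c("fixed", "control_mean_plus_k_sd"),
                           k = 3, min_component_px = 1L) {
  method <- match.arg(method)
  if (receptor_threshold < 0 || marker_threshold < 0) {
    stop_punctate("thresholds must be >= 0", "punctate_validation_error")
  }
  if (method == "control_mean_plus_k_sd" && k <= 0) {
    stop_punctate("`k` must be positive", "punctate_validation_error")
  }
  if (min_component_px < 1L) {
    stop_punctate("`min_component_px` must be >= 1", "punctate_validation_error")
  }
  structure(list(receptor_threshold = receptor_threshold,
                 marker_threshold = marker_threshold,
                 method = method, k = k,
                 min_component_px = as.integer(min_component_px)),
            class = "threshold_spec")
}

#' Derive a channel threshold from negative-control stacks
#'
#' Pools every voxel of the named channel across the control stacks and
#' returns mean + k * sd, with sd the population (divide-by-n) standard
#' deviation of the pooled voxels. This is the "predetermined pixel threshold
#' based on control tissue" rule: control tissue carries no specific label, so
#' signal is whatever exceeds its intensity distribution by k sigmas.
#'
#' @param control_stacks list of [confocal_stack()] objects (>= 1).
#' @param channel channel label to pool.
#' @param k positive sd multiplier; default 3.
#' @return A scalar intensity cutoff.
#' @export
derive_threshold <- function(control_stacks, channel, k = 3) {
  if (inherits(control_stacks, "confocal_stack")) {
    control_stacks <- list(control_stacks)
  }
  if (length(control_stacks) == 0L) {
    stop_punctate("need at least one control stack", "punctate_validation_error")
  }
  assert_positive_scalar(k, "k")
  voxels <- unlist(lapply(control_stacks, function(s) {
    as.numeric(stack_channel(s, channel))
  }))
  mean(voxels) + k * pop_sd(voxels)
}

#' Binarize an intensity plane
#'
#' @param plane 2-d numeric matrix `(y, x)`.
#' @param threshold cutoff; the mask is `plane > threshold` (strict).
#' @return Logical matrix of the same shape.
#' @export
binarize <- function(plane, threshold) {
  if (threshold < 0) {
    stop_punctate("threshold must be >= 0", "punctate_validation_error")
  }
  plane > threshold
}

#' Pixel-wise colocalization of two binary masks
#'
#' @param mask_a,mask_b logical matrices of identical shape.
#' @return Logical AND of the two masks.
#' @export
colocalize <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop_punctate("masks must have identical shapes", "punctate_validation_error")
  }
  mask_a & mask_b
}

# 8-connected in-plane component labelling. EBImage::bwlabel is 4-connected,
# so labels that touch only diagonally are merged afterwards via the label
# adjacency graph.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  a <- lab[-nrow(lab), -ncol(lab)]; b <- lab[-1, -1]          # \ diagonal
  c_ <- lab[-nrow(lab), -1]; d <- lab[-1, -ncol(lab)]         # / diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  remap <- seq_len(nl)
  remap[as.integer(names(memb))] <- nl + memb   # merged groups share fresh ids
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  # compact to 1..n
  ids <- sort(unique(out[out > 0]))
  out[out > 0] <- match(out[out > 0], ids)
  out
}

# Count 8-connected components of at least min_px pixels.
count_components <- function(mask, min_px = 1L) {
  if (!any(mask)) return(0L)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= min_px)
}

#' Neuropil-level puncta quantification
#'
#' The first analysis macro: for every plane of the z-stack, binarize the
#' receptor and marker channels, count signal pixels in each, and count their
#' colocalized (AND) pixels; totals are the column sums over planes. This
#' yields the neuropil-level measures: total receptor signal (intracellular
#' plus membrane puncta, all planes) and synaptically localized receptor
#' signal (receptor-marker colocalization). Optionally also counts discrete
#' puncta as 8-connected in-plane components of at least
#' `thresholds$min_component_px` pixels.
#'
#' @param stack a [confocal_stack()] with `"receptor"` and `"marker"` channels.
#' @param thresholds a [threshold_spec()].
#' @param count_puncta logical; also report connected-component counts.
#' @return An object of class `puncta_measurement`: a list with `per_plane`
#'   (tibble: `z`, `receptor_px`, `marker_px`, `coloc_px`), `totals` (one-row
#'   tibble), and `components` (one-row tibble or `NULL`).
#' @export
neuropil_measures <- function(stack, thresholds, count_puncta = FALSE) {
  stopifnot(inherits(thresholds, "threshold_spec"))
  rec <- stack_channel(stack, "receptor")
  mrk <- stack_channel(stack, "marker")
  nz <- dim(rec)[1]
  rows <- lapply(seq_len(nz), function(zi) {
    rp <- rec[zi, , ]; dim(rp) <- dim(rec)[-1]
    mp <- mrk[zi, , ]; dim(mp) <- dim(mrk)[-1]
    rm <- binarize(rp, thresholds$receptor_threshold)
    mm <- binarize(mp, thresholds$marker_threshold)
    cm <- colocalize(rm, mm)
    comp <- if (count_puncta) {
      c(count_components(rm, thresholds$min_component_px),
        count_components(cm, thresholds$min_component_px))
    } else c(NA_integer_, NA_integer_)
    tibble::tibble(z = zi - 1L,
                   receptor_px = sum(rm), marker_px = sum(mm),
                   coloc_px = sum(cm),
                   receptor_components = comp[1], coloc_components = comp[2])
  })
  per_plane <- dplyr::bind_rows(rows)
  totals <- tibble::tibble(
    receptor_px_total = sum(per_plane$receptor_px),
    marker_px_total = sum(per_plane$marker_px),
    coloc_px_total = sum(per_plane$coloc_px))
  components <- if (count_puncta) {
    tibble::tibble(
      receptor_component_count = sum(per_plane$receptor_components),
      coloc_component_count = sum(per_plane$coloc_components))
  }
  if (!count_puncta) {
    per_plane$receptor_components <- NULL
    per_plane$coloc_components <- NULL
  }
  structure(list(per_plane = per_plane, totals = totals,
                 components = components, thresholds = thresholds),
            class = "puncta_measurement")
}

#' @export
print.puncta_measurement <- function(x, ...) {
  cat(sprintf("<puncta_measurement> %d plane(s)\n", nrow(x$per_plane)))
  cat(sprintf("  totals: receptor %d px, marker %d px, colocalized %d px\n",
              x$totals$receptor_px_total, x$totals$marker_px_total,
              x$totals$coloc_px_total))
  if (!is.null(x$components)) {
    cat(sprintf("  components: %d receptor, %d colocalized\n",
                x$components$receptor_component_count,
                x$components$coloc_component_count))
  }
  invisible(x)
}
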