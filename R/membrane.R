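#' Somatic membrane contour
#'
#' A closed polygon tracing the plasma membrane in one plane, in 0-based
#' `(y, x)` pixel coordinates. Manual contours mirror the study design where a
#' blinded researcher traces the marker-labelled cell outline; auto-traced
#' contours come from [trace_membrane()].
#'
#' @param vertices numeric matrix with two columns `(y, x)`, >= 3 rows; the
#'   polygon is closed implicitly (last vertex connects to the first).
#' @return A list of class `membrane_contour` with `source = "manual"`.
#' @export
contour_manual <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop_punctate("a contour needs a (y, x) matrix of >= 3 vertices",
                  "punctate_validation_error")
  }
  colnames(vertices) <- c("y", "x")
  structure(list(vertices = vertices, closed = TRUE, source = "manual"),
            class = "membrane_contour")
}

#' @export
print.membrane_contour <- function(x, ...) {
  cat(sprintf("<membrane_contour> %d vertices (%s)\n",
              nrow(x$vertices), x$source))
  invisible(x)
}

#' Select the plane with maximal receptor/marker colocalization
#'
#' Scans the z-series and returns the 0-based index of the plane with the
#' largest colocalized pixel count; ties break to the lowest index. This is
#' the plane-selection step of the membrane macro: the equatorial plane of a
#' soma carries the widest membrane profile and hence the most synaptic
#' colocalization.
#'
#' @inheritParams neuropil_measures
#' @return Integer 0-based plane index.
#' @export
select_max_coloc_plane <- function(stack, thresholds) {
  pm <- neuropil_measures(stack, thresholds)
  as.integer(pm$per_plane$z[which.max(pm$per_plane$coloc_px)])
}

#' Auto-trace the membrane ring in a marker plane
#'
#' Thresholds the marker plane, optionally applies a morphological closing to
#' bridge small breaks in the ring, keeps the largest 8-connected component,
#' fills its interior, and returns the outer boundary polygon (simplified to
#' at most `max_vertices` vertices).
#'
#' @param marker_plane 2-d `(y, x)` intensity matrix.
#' @param threshold marker intensity cutoff (strict `>`).
#' @param min_component_px smallest component accepted as a ring; below this a
#'   trace-failure error is raised and the caller should fall back to a manual
#'   contour.
#' @param close_radius_px radius (pixels) of the disc brush used for closing;
#'   0 disables closing.
#' @param max_vertices upper bound on returned polygon vertices.
#' @return A `membrane_contour` with `source = "auto_traced"`.
#' @export
trace_membrane <- function(marker_plane, threshold, min_component_px = 20L,
                           close_radius_px = 0L, max_vertices = 256L) {
  mask <- binarize(marker_plane, threshold)
  if (close_radius_px > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(close_radius_px) + 1L, "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0
  }
  lab <- label_components(mask)
  if (max(lab) == 0L) {
    stop_punctate("membrane trace failed: no thresholded component found",
                  "punctate_trace_error")
  }
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) < min_component_px) {
    stop_punctate(sprintf(
      "membrane trace failed: largest component (%d px) below min_component_px",
      max(sizes)), "punctate_trace_error")
  }
  keep <- lab == which.max(sizes)
  filled <- EBImage::fillHull(keep * 1)
  oc <- EBImage::ocontour(filled)[[1]]
  # EBImage indexes (dim1, dim2) 0-based; our matrices are (y, x)
  verts <- cbind(y = oc[, 1], x = oc[, 2])
  if (nrow(verts) > max_vertices) {
    idx <- unique(round(seq(1, nrow(verts), length.out = max_vertices)))
    verts <- verts[idx, , drop = FALSE]
  }
  out <- contour_manual(verts)
  out$source <- "auto_traced"
  out
}

# Minimum distance (pixels) from every pixel centre of an (ny, nx) image to a
# closed polygon outline. Exact point-to-segment distances, vectorized per
# segment.
distance_to_outline <- function(vertices, image_shape) {
  ny <- image_shape[1]; nx <- image_shape[2]
  py <- rep(0:(ny - 1), times = nx)
  px <- rep(0:(nx - 1), each = ny)
  v <- rbind(vertices, vertices[1, , drop = FALSE])
  dmin <- rep(Inf, ny * nx)
  for (i in seq_len(nrow(v) - 1L)) {
    ay <- v[i, 1]; ax <- v[i, 2]
    by <- v[i + 1L, 1]; bx <- v[i + 1L, 2]
    dy <- by - ay; dx <- bx - ax
    len2 <- dy * dy + dx * dx
    if (len2 == 0) {
      d2 <- (py - ay)^2 + (px - ax)^2
    } else {
      t <- ((py - ay) * dy + (px - ax) * dx) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (py - (ay + t * dy))^2 + (px - (ax + t * dx))^2
    }
    dmin <- pmin(dmin, d2)
  }
  matrix(sqrt(dmin), ny, nx)
}

#' Rasterize a fixed-thickness membrane band
#'
#' Builds the "image-based subcellular fraction": the set of pixels whose
#' centre lies within `thickness_um / 2` of the traced membrane outline, i.e.
#' a band of the stated physical thickness centred on the contour (half
#' inside the cell, half outside). Anchoring can be shifted fully inside or
#' outside the trace.
#'
#' @param contour a `membrane_contour`.
#' @param thickness_um band thickness in micrometres (default 2).
#' @param pixel_size_um lateral calibration (um/px).
#' @param image_shape `(ny, nx)` of the target plane.
#' @param anchor `"centered"` (default), `"inside"`, or `"outside"`.
#' @return Logical `(ny, nx)` mask.
#' @export
band_from_contour <- function(contour, thickness_um = 2,
                              pixel_size_um, image_shape,
                              anchor = c("centered", "inside", "outside")) {
  anchor <- match.arg(anchor)
  assert_positive_scalar(pixel_size_um, "pixel_size_um")
  thickness_px <- thickness_um / pixel_size_um
  if (thickness_px < 1) {
    stop_punctate("band thickness is below one pixel at this calibration",
                  "punctate_validation_error")
  }
  d <- distance_to_outline(contour$vertices, image_shape)
  half <- thickness_px / 2
  if (anchor == "centered") return(d <= half)
  # Signed side via point-in-polygon on the pixel grid.
  inside <- polygon_interior(contour$vertices, image_shape)
  if (anchor == "inside") (d <= thickness_px) & (inside | d <= 0.5)
  else (d <= thickness_px) & (!inside | d <= 0.5)
}

# Even-odd point-in-polygon rasterization for pixel centres.
polygon_interior <- function(vertices, image_shape) {
  ny <- image_shape[1]; nx <- image_shape[2]
  py <- rep(0:(ny - 1), times = nx)
  px <- rep(0:(nx - 1), each = ny)
  v <- rbind(vertices, vertices[1, , drop = FALSE])
  crossings <- rep(0L, ny * nx)
  for (i in seq_len(nrow(v) - 1L)) {
    ay <- v[i, 1]; ax <- v[i, 2]
    by <- v[i + 1L, 1]; bx <- v[i + 1L, 2]
    cond <- (ay > py) != (by > py)
    if (!any(cond)) next
    xint <- ax + (py - ay) / (by - ay) * (bx - ax)
    crossings <- crossings + as.integer(cond & px < xint)
  }
  matrix(crossings %% 2L == 1L, ny, nx)
}

#' Membrane-fraction quantification
#'
#' The second analysis macro end-to-end: select the plane of maximal
#' receptor/marker colocalization, obtain the somatic contour (a supplied
#' manual contour takes priority; otherwise the marker ring is auto-traced),
#' rasterize the fixed-thickness band around it, and partition the receptor
#' pixels inside the band into synaptic (colocalized with marker) and
#' extrasynaptic (marker-negative) pools.
#'
#' @inheritParams neuropil_measures
#' @param contour optional `membrane_contour`; when `NULL` the membrane is
#'   auto-traced on the selected plane.
#' @param thickness_um band thickness (default 2 um).
#' @param plane_override optional 0-based plane index; when supplied it
#'   replaces automatic plane selection (the supervised-override step) and is
#'   recorded in the result.
#' @param close_radius_px closing radius passed to [trace_membrane()].
#' @param anchor band anchoring, see [band_from_contour()].
#' @return An object of class `membrane_fraction`: `plane_index`, `contour`,
#'   `band_mask`, `band_thickness_um`, `band_px`, `synaptic_px`,
#'   `extrasynaptic_px`, `plane_overridden`.
#' @export
membrane_measures <- function(stack, thresholds, contour = NULL,
                              thickness_um = 2, plane_override = NULL,
                              close_radius_px = 0L,
                              anchor = "centered") {
  stopifnot(inherits(thresholds, "threshold_spec"))
  plane <- plane_override %||% select_max_coloc_plane(stack, thresholds)
  rp <- stack_plane(stack, "receptor", plane)
  mp <- stack_plane(stack, "marker", plane)
  if (is.null(contour)) {
    contour <- tryCatch(
      trace_membrane(mp, thresholds$marker_threshold,
                     min_component_px = thresholds$min_component_px,
                     close_radius_px = close_radius_px),
      punctate_trace_error = function(e) {
        stop_punctate(paste0(conditionMessage(e),
                             "; supply a manually traced contour"),
                      "punctate_trace_error")
      })
  }
  band <- band_from_contour(contour, thickness_um, stack$pixel_size_um,
                            dim(rp), anchor = anchor)
  rmask <- binarize(rp, thresholds$receptor_threshold)
  mmask <- binarize(mp, thresholds$marker_threshold)
  syn <- rmask & mmask & band
  ext <- rmask & !mmask & band
  structure(list(plane_index = plane, contour = contour, band_mask = band,
                 band_thickness_um = thickness_um, band_px = sum(band),
                 synaptic_px = sum(syn), extrasynaptic_px = sum(ext),
                 synaptic_mask = syn, extrasynaptic_mask = ext,
                 plane_overridden = !is.null(plane_override)),
            class = "membrane_fraction")
}

#' @export
print.membrane_fraction <- function(x, ...) {
  cat(sprintf(
    "<membrane_fraction> plane %d%s, %.3g um band (%d px): %d synaptic, %d extrasynaptic px\n",
    x$plane_index, if (x$plane_overridden) " (override)" else "",
    x$band_thickness_um, x$band_px, x$synaptic_px, x$extrasynaptic_px))
  invisible(x)
}
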