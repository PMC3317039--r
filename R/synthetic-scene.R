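#' Parameters for one synthetic confocal scene
#'
#' Describes a single simulated motor-neuron soma: a spherical cell whose
#' plasma membrane is outlined by a presynaptic-marker ring (the synaptophysin
#' "outline" used to identify large ventral motor neurons), with receptor
#' puncta planted in three pools. Synaptic puncta carry both receptor and
#' marker signal at the same centre on the membrane ring; extrasynaptic puncta
#' sit on the ring at planted gaps in the marker signal; intracellular puncta
#' lie in the soma interior. The rendered scene is optionally blurred with a
#' Gaussian point-spread function and corrupted with shot/read noise.
#'
#' All physical parameters are in micrometres, so the same scene description
#' renders consistently at any pixel pitch.
#'
#' @param image_shape integer `(z, y, x)` voxel counts.
#' @param pixel_size_um,z_step_um calibration (um/px lateral, um between
#'   planes).
#' @param soma_diameter_um soma diameter; the sampling criterion for large
#'   ventral motor neurons is a diameter above 40 um.
#' @param ring_thickness_um radial thickness of the marker ring.
#' @param n_synaptic,n_extrasynaptic,n_intracellular planted puncta per pool.
#' @param n_marker_only marker-only puncta on the ring (presynaptic terminals
#'   without receptor signal).
#' @param punctum_radius_um punctum footprint radius; intensity falls off as a
#'   Gaussian (sigma = radius/2) truncated at this radius, so the noiseless
#'   footprint is exactly the set of pixel centres within the radius.
#' @param punctum_amplitude peak punctum intensity (arbitrary photon-count
#'   units).
#' @param ring_amplitude marker-ring intensity.
#' @param psf_sigma_um `c(lateral, axial)` Gaussian PSF sigmas in um.
#' @param apply_psf logical; `FALSE` renders the geometric scene unblurred.
#' @param background_level mean background intensity added to both channels.
#' @param noise_model one of `"none"`, `"poisson"`, `"gaussian"`,
#'   `"poisson+gaussian"`.
#' @param gaussian_sd read-noise standard deviation for the Gaussian models.
#' @param min_separation_um minimum centre-to-centre distance between planted
#'   puncta in the xy projection (keeps footprints disjoint and components
#'   countable).
#' @param gap_margin_um extra angular clearance of a marker-ring gap beyond the
#'   punctum footprint it hosts.
#' @param seed integer RNG seed; identical parameters and seed give an
#'   identical scene.
#'
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(image_shape = c(9L, 160L, 160L),
                         pixel_size_um = 0.35,
                         z_step_um = 0.5,
                         soma_diameter_um = 42,
                         ring_thickness_um = 1.0,
                         n_synaptic = 12L,
                         n_extrasynaptic = 8L,
                         n_intracellular = 20L,
                         n_marker_only = 6L,
                         punctum_radius_um = 0.7,
                         punctum_amplitude = 800,
                         ring_amplitude = 500,
                         psf_sigma_um = c(0.2, 0.4),
                         apply_psf = TRUE,
                         background_level = 40,
                         noise_model = c("poisson", "none", "gaussian",
                                         "poisson+gaussian"),
                         gaussian_sd = 5,
                         min_separation_um = 2.2,
                         gap_margin_um = 0.5,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  p <- list(image_shape = as.integer(image_shape),
            pixel_size_um = pixel_size_um, z_step_um = z_step_um,
            soma_diameter_um = soma_diameter_um,
            ring_thickness_um = ring_thickness_um,
            n_synaptic = as.integer(n_synaptic),
            n_extrasynaptic = as.integer(n_extrasynaptic),
            n_intracellular = as.integer(n_intracellular),
            n_marker_only = as.integer(n_marker_only),
            punctum_radius_um = punctum_radius_um,
            punctum_amplitude = punctum_amplitude,
            ring_amplitude = ring_amplitude,
            psf_sigma_um = psf_sigma_um, apply_psf = apply_psf,
            background_level = background_level,
            noise_model = noise_model, gaussian_sd = gaussian_sd,
            min_separation_um = min_separation_um,
            gap_margin_um = gap_margin_um,
            seed = as.integer(seed))
  class(p) <- "scene_params"
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  assert_positive_scalar(p$pixel_size_um, "pixel_size_um")
  assert_positive_scalar(p$z_step_um, "z_step_um")
  if (length(p$image_shape) != 3L || any(p$image_shape < 1L)) {
    stop_punctate("image_shape must be positive (z, y, x) counts",
                  "punctate_validation_error")
  }
  if (any(c(p$n_synaptic, p$n_extrasynaptic, p$n_intracellular,
            p$n_marker_only) < 0L)) {
    stop_punctate("puncta counts must be >= 0", "punctate_validation_error")
  }
  if (any(p$psf_sigma_um <= 0)) {
    stop_punctate("psf sigmas must be positive", "punctate_validation_error")
  }
  fov_um <- min(p$image_shape[2:3]) * p$pixel_size_um
  if (p$soma_diameter_um + 4 > fov_um) {
    stop_punctate(sprintf(
      "soma (%.3g um) does not fit in the %.3g um field with 2 um clearance",
      p$soma_diameter_um, fov_um), "punctate_validation_error")
  }
  invisible(p)
}

# Greedy angular placement: shuffle a fine grid of candidate angles and keep
# those at least `min_angle` from every accepted one (wrapped). If the greedy
# pass cannot seat everything, the separation is relaxed stepwise (crowded
# rings are legitimate at high planted counts). Deterministic under the
# caller's RNG state.
place_angles <- function(n, min_angle, forbidden = numeric(),
                         forbidden_halfwidth = 0) {
  if (n == 0L) return(numeric())
  for (relax in 0.8^(0:6)) {
    sep <- min_angle * relax
    grid <- sample(seq(0, 2 * pi, length.out = 720L + 1L)[-1L])
    keep <- numeric(0)
    for (a in grid) {
      if (length(keep) == n) break
      ok <- all(pmin(abs(a - keep), 2 * pi - abs(a - keep)) >= sep)
      if (ok && length(forbidden)) {
        dfor <- pmin(abs(a - forbidden), 2 * pi - abs(a - forbidden))
        ok <- all(dfor >= forbidden_halfwidth + sep / 2)
      }
      if (ok) keep <- c(keep, a)
    }
    if (length(keep) == n) return(keep)
  }
  stop_punctate("cannot place puncta on the ring at the requested separation",
                "punctate_validation_error")
}

# Render one truncated-Gaussian punctum into a plane; returns the footprint
# mask (pixel centres within radius_px of the centre).
render_punctum <- function(plane, cy, cx, radius_px, amplitude) {
  ny <- nrow(plane); nx <- ncol(plane)
  y0 <- max(1L, floor(cy + 1 - radius_px)); y1 <- min(ny, ceiling(cy + 1 + radius_px))
  x0 <- max(1L, floor(cx + 1 - radius_px)); x1 <- min(nx, ceiling(cx + 1 + radius_px))
  ys <- y0:y1; xs <- x0:x1
  dy <- ys - 1 - cy; dx <- xs - 1 - cx
  d2 <- outer(dy^2, dx^2, `+`)
  sigma <- radius_px / 2
  patch <- ifelse(d2 <= radius_px^2, amplitude * exp(-d2 / (2 * sigma^2)), 0)
  plane[ys, xs] <- plane[ys, xs] + patch
  foot <- matrix(FALSE, ny, nx)
  foot[ys, xs] <- d2 <= radius_px^2
  list(plane = plane, footprint = foot)
}

#' Generate a ground-truthed synthetic scene
#'
#' Renders the two-channel scene described by a [scene_params()] object and
#' returns both the stack and its ground truth: planted punctum centres, the
#' true membrane contour in the equatorial (peak) plane, per-class counts, and
#' exact pre-blur footprint masks per class. The marker ring is drawn on every
#' plane the spherical soma intersects, with its radius following the sphere,
#' so the equatorial plane carries the widest ring.
#'
#' @param params a [scene_params()] object.
#' @return A list with elements `stack` (a [confocal_stack()]) and `truth`
#'   (class `scene_truth`: `punctum_table`, `contour_true`, `counts_true`,
#'   `peak_plane_true`, `footprints`, `marker_mask`).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  withr::with_seed(params$seed, generate_scene_impl(params))
}

generate_scene_impl <- function(p) {
  nz <- p$image_shape[1]; ny <- p$image_shape[2]; nx <- p$image_shape[3]
  px <- p$pixel_size_um
  R_um <- p$soma_diameter_um / 2
  R_px <- R_um / px
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  z_eq <- (nz - 1L) %/% 2L                       # 0-based equatorial plane
  rad_px <- p$punctum_radius_um / px
  ring_half_px <- p$ring_thickness_um / 2 / px

  receptor <- array(0, dim = c(nz, ny, nx))
  marker <- array(0, dim = c(nz, ny, nx))
  foot_syn <- array(FALSE, dim = c(nz, ny, nx))
  foot_ext <- array(FALSE, dim = c(nz, ny, nx))
  foot_int <- array(FALSE, dim = c(nz, ny, nx))

  # --- angular layout on the equatorial ring -------------------------------
  min_ang <- p$min_separation_um / R_um
  gap_half <- (p$punctum_radius_um + p$gap_margin_um) / R_um
  ang_ext <- place_angles(p$n_extrasynaptic, max(min_ang, 2 * gap_half))
  ang_occ <- place_angles(p$n_synaptic + p$n_marker_only, min_ang,
                          forbidden = ang_ext, forbidden_halfwidth = gap_half)
  ang_syn <- ang_occ[seq_len(p$n_synaptic)]
  ang_mrk <- ang_occ[setdiff(seq_along(ang_occ), seq_len(p$n_synaptic))]

  # --- marker ring on every plane the sphere intersects --------------------
  yy <- matrix(0:(ny - 1), ny, nx) - cy
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE) - cx
  dcent <- sqrt(yy^2 + xx^2)
  theta <- atan2(yy, xx) %% (2 * pi)
  in_gap <- matrix(FALSE, ny, nx)
  for (a in ang_ext) {
    da <- pmin(abs(theta - a), 2 * pi - abs(theta - a))
    in_gap <- in_gap | (da <= gap_half)
  }
  for (z in seq_len(nz) - 1L) {
    dz_um <- (z - z_eq) * p$z_step_um
    if (abs(dz_um) >= R_um) next
    rz_px <- sqrt(R_um^2 - dz_um^2) / px
    ring <- abs(dcent - rz_px) <= ring_half_px & !in_gap
    plane <- marker[z + 1L, , ]; dim(plane) <- c(ny, nx)
    plane[ring] <- plane[ring] + p$ring_amplitude
    marker[z + 1L, , ] <- plane
  }

  punctum_rows <- list()
  add_row <- function(class, z, y, x) {
    punctum_rows[[length(punctum_rows) + 1L]] <<-
      tibble::tibble(class = class, z = z, y = y, x = x, radius_px = rad_px)
  }

  # --- on-ring puncta (equatorial plane) -----------------------------------
  put_on_ring <- function(angle) c(cy + R_px * sin(angle), cx + R_px * cos(angle))
  for (a in ang_syn) {
    yx <- put_on_ring(a)
    rp <- receptor[z_eq + 1L, , ]; dim(rp) <- c(ny, nx)
    res <- render_punctum(rp, yx[1], yx[2], rad_px, p$punctum_amplitude)
    receptor[z_eq + 1L, , ] <- res$plane
    foot_syn[z_eq + 1L, , ] <- foot_syn[z_eq + 1L, , ] | res$footprint
    mp <- marker[z_eq + 1L, , ]; dim(mp) <- c(ny, nx)
    marker[z_eq + 1L, , ] <- render_punctum(mp, yx[1], yx[2], rad_px,
                                            p$punctum_amplitude)$plane
    add_row("synaptic", z_eq, yx[1], yx[2])
  }
  for (a in ang_ext) {
    yx <- put_on_ring(a)
    rp <- receptor[z_eq + 1L, , ]; dim(rp) <- c(ny, nx)
    res <- render_punctum(rp, yx[1], yx[2], rad_px, p$punctum_amplitude)
    receptor[z_eq + 1L, , ] <- res$plane
    foot_ext[z_eq + 1L, , ] <- foot_ext[z_eq + 1L, , ] | res$footprint
    add_row("extrasynaptic", z_eq, yx[1], yx[2])
  }
  for (a in ang_mrk) {
    yx <- put_on_ring(a)
    mp <- marker[z_eq + 1L, , ]; dim(mp) <- c(ny, nx)
    marker[z_eq + 1L, , ] <- render_punctum(mp, yx[1], yx[2], rad_px,
                                            p$punctum_amplitude)$plane
  }

  # --- intracellular puncta: interior, clear of the membrane band ----------
  placed <- do.call(rbind, lapply(punctum_rows, function(r) c(r$y, r$x)))
  margin_um <- p$punctum_radius_um + 1.5   # stay clear of a 2 um band's inner half
  n_left <- p$n_intracellular
  attempts <- 0L
  while (n_left > 0L && attempts < 20000L) {
    attempts <- attempts + 1L
    z <- sample.int(nz, 1L) - 1L
    dz_um <- (z - z_eq) * p$z_step_um
    if (abs(dz_um) >= R_um - margin_um) next
    rmax_um <- sqrt(R_um^2 - dz_um^2) - margin_um
    if (rmax_um <= p$punctum_radius_um) next
    r_um <- sqrt(stats::runif(1)) * rmax_um
    a <- stats::runif(1, 0, 2 * pi)
    y <- cy + (r_um / px) * sin(a); x <- cx + (r_um / px) * cos(a)
    if (!is.null(placed) && nrow(placed) > 0) {
      d <- sqrt((placed[, 1] - y)^2 + (placed[, 2] - x)^2) * px
      if (any(d < p$min_separation_um)) next
    }
    rp <- receptor[z + 1L, , ]; dim(rp) <- c(ny, nx)
    res <- render_punctum(rp, y, x, rad_px, p$punctum_amplitude)
    receptor[z + 1L, , ] <- res$plane
    foot_int[z + 1L, , ] <- foot_int[z + 1L, , ] | res$footprint
    add_row("intracellular", z, y, x)
    placed <- rbind(placed, c(y, x))
    n_left <- n_left - 1L
  }
  if (n_left > 0L) {
    stop_punctate("cannot place intracellular puncta at the requested separation",
                  "punctate_validation_error")
  }

  marker_mask <- marker > 0

  # --- optics and noise ----------------------------------------------------
  if (p$apply_psf) {
    s_xy <- p$psf_sigma_um[1] / px
    s_z <- p$psf_sigma_um[2] / p$z_step_um
    receptor <- gaussian_blur_3d(receptor, s_xy, s_z)
    marker <- gaussian_blur_3d(marker, s_xy, s_z)
  }
  receptor <- receptor + p$background_level
  marker <- marker + p$background_level
  if (p$noise_model %in% c("poisson", "poisson+gaussian")) {
    receptor[] <- stats::rpois(length(receptor), lambda = receptor)
    marker[] <- stats::rpois(length(marker), lambda = marker)
  }
  if (p$noise_model %in% c("gaussian", "poisson+gaussian")) {
    receptor <- receptor + stats::rnorm(length(receptor), sd = p$gaussian_sd)
    marker <- marker + stats::rnorm(length(marker), sd = p$gaussian_sd)
  }
  receptor <- pmax(round(receptor), 0)
  marker <- pmax(round(marker), 0)

  voxels <- array(0L, dim = c(2L, nz, ny, nx))
  voxels[1, , , ] <- as.integer(receptor)
  voxels[2, , , ] <- as.integer(marker)
  stack <- confocal_stack(voxels, c("receptor", "marker"),
                          pixel_size_um = px, z_step_um = p$z_step_um)

  contour_angles <- seq(0, 2 * pi, length.out = 129L)[-129L]
  contour_true <- contour_manual(
    cbind(y = cy + R_px * sin(contour_angles),
          x = cx + R_px * cos(contour_angles)))
  contour_true$source <- "auto_traced"  # reset below; ground truth is synthetic
  contour_true$source <- "manual"

  punctum_table <- if (length(punctum_rows)) {
    dplyr::bind_rows(punctum_rows)
  } else {
    tibble::tibble(class = character(), z = integer(), y = numeric(),
                   x = numeric(), radius_px = numeric())
  }
  counts_true <- c(synaptic = p$n_synaptic,
                   extrasynaptic = p$n_extrasynaptic,
                   intracellular = p$n_intracellular)
  truth <- structure(
    list(punctum_table = punctum_table,
         contour_true = contour_true,
         counts_true = counts_true,
         peak_plane_true = z_eq,
         footprints = list(synaptic = foot_syn, extrasynaptic = foot_ext,
                           intracellular = foot_int),
         marker_mask = marker_mask),
    class = "scene_truth")
  list(stack = stack, truth = truth)
}
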