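# Brute-force oracles: naive loop implementations kept deliberately
# independent of the package's vectorized code paths.

# Per-plane pixel counts by explicit triple loop over (z, y, x).
brute_neuropil <- function(stack, thr_receptor, thr_marker) {
  rec <- stack_channel(stack, "receptor")
  mrk <- stack_channel(stack, "marker")
  d <- dim(rec)
  out <- data.frame(z = integer(), receptor_px = integer(),
                    marker_px = integer(), coloc_px = integer())
  for (z in seq_len(d[1])) {
    r_ct <- m_ct <- c_ct <- 0L
    for (y in seq_len(d[2])) {
      for (x in seq_len(d[3])) {
        r_on <- rec[z, y, x] > thr_receptor
        m_on <- mrk[z, y, x] > thr_marker
        if (r_on) r_ct <- r_ct + 1L
        if (m_on) m_ct <- m_ct + 1L
        if (r_on && m_on) c_ct <- c_ct + 1L
      }
    }
    out <- rbind(out, data.frame(z = z - 1L, receptor_px = r_ct,
                                 marker_px = m_ct, coloc_px = c_ct))
  }
  out
}

# Pixel-by-pixel loop binarization.
brute_binarize <- function(plane, threshold) {
  out <- matrix(FALSE, nrow(plane), ncol(plane))
  for (y in seq_len(nrow(plane))) {
    for (x in seq_len(ncol(plane))) {
      out[y, x] <- plane[y, x] > threshold
    }
  }
  out
}

# Double-loop mask AND.
brute_colocalize <- function(a, b) {
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (y in seq_len(nrow(a))) {
    for (x in seq_len(ncol(a))) {
      out[y, x] <- a[y, x] && b[y, x]
    }
  }
  out
}

# Random small two-channel stack for oracle-equivalence checks.
random_stack <- function(nz = 5L, ny = 32L, nx = 32L, max_val = 100L) {
  v <- array(sample.int(max_val + 1L, 2L * nz * ny * nx, replace = TRUE) - 1L,
             dim = c(2L, nz, ny, nx))
  confocal_stack(v, c("receptor", "marker"),
                 pixel_size_um = 0.2, z_step_um = 0.5)
}

# Scene parameters scaled so the soma fits a small field quickly.
small_scene_params <- function(...) {
  scene_params(image_shape = c(7L, 64L, 64L), pixel_size_um = 0.8,
               punctum_radius_um = 0.9, n_synaptic = 6L,
               n_extrasynaptic = 4L, n_intracellular = 8L, n_marker_only = 3L,
               ...)
}

# Thresholds for noiseless zero-background scenes: any signal is signal.
exact_thresholds <- function(min_component_px = 1L) {
  threshold_spec(0, 0, min_component_px = min_component_px)
}

clean_scene_params <- function(...) {
  scene_params(apply_psf = FALSE, noise_model = "none",
               background_level = 0, ...)
}
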