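#' Write a confocal stack to a multi-page TIFF
#'
#' Pages are written channel-fastest: page `z * n_channels + c` holds channel
#' `c` of plane `z` (both 0-based), the interleave used by ImageJ hyperstacks.
#' Intensities are stored as 16-bit integers, so values must be integral and
#' within 0..65535; the encoding is lossless for such data. Calibration and
#' channel labels go to a flat key=value sidecar file `<path>.meta`.
#'
#' @param stack a [confocal_stack()].
#' @param path output file path; the parent directory must exist.
#' @param metadata optional one-row metadata tibble (see [scene_metadata()])
#'   whose fields are appended to the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, metadata = NULL) {
  stopifnot(inherits(stack, "confocal_stack"))
  if (!dir.exists(dirname(path))) {
    stop_punctate(sprintf("parent directory does not exist: %s", dirname(path)),
                  "punctate_io_error")
  }
  v <- stack$voxels
  if (any(v != round(v)) || max(v) > 65535) {
    stop_punctate("write_stack stores 16-bit integers; voxels must be integral and <= 65535",
                  "punctate_validation_error")
  }
  d <- dim(v)  # (c, z, y, x)
  pages <- vector("list", d[1] * d[2])
  for (z in seq_len(d[2])) {
    for (ch in seq_len(d[1])) {
      m <- v[ch, z, , ]
      dim(m) <- d[3:4]
      pages[[(z - 1L) * d[1] + ch]] <- m / 65535
    }
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                 compression = "none", reduce = FALSE),
                 error = function(e) {
                   stop_punctate(sprintf("cannot write TIFF: %s", conditionMessage(e)),
                                 "punctate_io_error")
                 })
  meta <- list(
    n_channels = d[1], n_z = d[2],
    channel_names = paste(stack$channel_names, collapse = ","),
    pixel_size_um = stack$pixel_size_um,
    z_step_um = stack$z_step_um
  )
  if (!is.null(metadata)) {
    meta <- c(meta, as.list(metadata[1, , drop = FALSE]))
  }
  writeLines(sprintf("%s=%s", names(meta),
                     vapply(meta, function(x) format(x, digits = 15), "")),
             paste0(path, ".meta"))
  invisible(path)
}

read_sidecar <- function(path) {
  sidecar <- paste0(path, ".meta")
  if (!file.exists(sidecar)) return(NULL)
  lines <- readLines(sidecar)
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
                  vapply(kv, `[[`, "", 1L))
}

#' Read a multi-page TIFF as a confocal stack
#'
#' The inverse of [write_stack()]: `read_stack(write_stack(s, p), ...)` returns
#' a stack voxel-identical to `s`. For files written by this package the
#' sidecar supplies channel layout and calibration; for foreign TIFFs pass
#' `channel_map` (label to 0-based channel index within a channel-fastest page
#' interleave) and the calibration explicitly.
#'
#' @param path TIFF file path.
#' @param channel_map named integer vector mapping channel labels to 0-based
#'   channel indices, e.g. `c(receptor = 0, marker = 1)`. Must contain
#'   `"receptor"` and `"marker"` for the analysis functions to work; read_stack
#'   itself only requires it to be consistent with the page count.
#' @param pixel_size_um,z_step_um calibration overrides; required when no
#'   sidecar is present.
#' @return A [confocal_stack()].
#' @export
read_stack <- function(path, channel_map = NULL,
                       pixel_size_um = NULL, z_step_um = NULL) {
  if (!file.exists(path)) {
    stop_punctate(sprintf("no such file: %s", path), "punctate_io_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- read_sidecar(path)

  if (is.null(channel_map)) {
    if (is.null(meta)) {
      stop_punctate("no channel_map supplied and no metadata sidecar found",
                    "punctate_configuration_error")
    }
    ch_names <- strsplit(meta$channel_names, ",", fixed = TRUE)[[1]]
    channel_map <- stats::setNames(seq_along(ch_names) - 1L, ch_names)
  }
  if (!all(c("receptor", "marker") %in% names(channel_map))) {
    stop_punctate("channel_map must label both 'receptor' and 'marker' channels",
                  "punctate_configuration_error")
  }
  nc <- max(channel_map) + 1L
  if (length(pages) %% nc != 0L) {
    stop_punctate(sprintf("page count %d not divisible by %d channels",
                          length(pages), nc), "punctate_configuration_error")
  }
  nz <- length(pages) %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])

  px <- pixel_size_um %||% as.numeric(meta$pixel_size_um %||% NA)
  zs <- z_step_um %||% as.numeric(meta$z_step_um %||% NA)
  if (is.na(px) || is.na(zs)) {
    stop_punctate("calibration missing: supply pixel_size_um and z_step_um",
                  "punctate_configuration_error")
  }
  if (px <= 0 || zs <= 0) {
    stop_punctate("calibration must be positive", "punctate_validation_error")
  }

  # Order channels as listed in channel_map; axes (channel, z, y, x).
  v <- array(0L, dim = c(length(channel_map), nz, ny, nx))
  for (i in seq_along(channel_map)) {
    for (z in seq_len(nz)) {
      v[i, z, , ] <- pages[[(z - 1L) * nc + channel_map[[i]] + 1L]]
    }
  }
  confocal_stack(v, names(channel_map), pixel_size_um = px, z_step_um = zs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
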