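#' Acquisition configuration
#'
#' Planning and camera parameters for tiled light-sheet acquisition. The
#' default zoom schedule follows the three-pass multi-scale procedure: a
#' 0.63x overview to find the sample, a 1.6x signal-detection pass (50 ms
#' exposure, 20 um z-spacing), and a 6.3x high-resolution pass (2 um
#' z-trigger interval) restricted to tiles holding signal.
#'
#' @param xy_overlap_fraction Mosaic overlap between adjacent tiles in the
#'   X-Y plane (default 5%).
#' @param z_overlap_fraction Overlap between consecutive optical Z stacks,
#'   as a fraction of stack depth (default 10%), rounded to whole z-steps.
#' @param section_overlap_um Overlap slice left between physical sections
#'   (default 100 um).
#' @param stage_speed_mm_s Continuous Z-stage speed during acquisition.
#' @param exposure_ms Camera exposure per frame.
#' @param zoom_schedule Data frame of passes with columns
#'   `pass, zoom, z_step_um, exposure_ms`.
#' @param offset,gain,read_noise_sd Camera model: constant offset (counts),
#'   counts per photon, Gaussian read noise SD (counts).
#' @param shot_noise Logical; `FALSE` gives a noiseless, deterministic
#'   expectation image (used for calibration measurements).
#' @param stage_move_s Dead time charged per tile move.
#' @param section_cut_s Time charged per vibratome cut (default 180 s, so a
#'   10-cut run spends ~30 min sectioning).
#' @param seed Integer seed for the camera noise stream.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(xy_overlap_fraction = 0.05,
                               z_overlap_fraction = 0.10,
                               section_overlap_um = 100,
                               stage_speed_mm_s = 0.08,
                               exposure_ms = 30,
                               zoom_schedule = data.frame(
                                 pass = 0:2,
                                 zoom = c(0.63, 1.6, 6.3),
                                 z_step_um = c(20, 20, 2),
                                 exposure_ms = c(50, 50, 30)),
                               offset = 100,
                               gain = 1,
                               read_noise_sd = 2,
                               shot_noise = TRUE,
                               stage_move_s = 2,
                               section_cut_s = 180,
                               seed = 1L) {
  for (v in c("xy_overlap_fraction", "z_overlap_fraction")) {
    val <- get(v)
    if (val < 0 || val >= 1) stop_domain("`", v, "` must be in [0, 1)")
  }
  check_positive(stage_speed_mm_s, "stage_speed_mm_s")
  check_positive(exposure_ms, "exposure_ms")
  check_nonnegative(read_noise_sd, "read_noise_sd")
  structure(as.list(environment()), class = "acquisition_config")
}

mosaic_axis <- function(width, fov, overlap) {
  if (fov <= 0) stop_domain("`fov_um` must be positive")
  if (overlap < 0 || overlap >= 1) {
    stop_domain("`overlap_fraction` must be in [0, 1)")
  }
  if (width <= fov) return(list(n = 1L, origins = 0))
  stride <- (1 - overlap) * fov
  n <- ceiling((width - fov) / stride) + 1
  origins <- (seq_len(n) - 1) * stride
  origins <- pmin(origins, width - fov)  # keep the last tile inside bounds
  list(n = as.integer(n), origins = origins)
}

#' Plan a 2D mosaic of fields of view
#'
#' Per axis, the tile count is `1` if the extent fits one field of view and
#' `ceil((W - F) / ((1 - v) F)) + 1` otherwise, with stride `(1 - v) F`;
#' the final tile is pinned to the far edge, so the union always covers the
#' bounds and adjacent tiles overlap by at least `v F`.
#'
#' @param bounds_um List or named vector giving `xmin, xmax, ymin, ymax`
#'   in um.
#' @param fov_um Length-2 field of view `(width_x, height_y)` in um.
#' @param overlap_fraction Overlap fraction `v` in [0, 1).
#' @return A data frame of tiles with columns `tile_id, col, row, x0, y0`
#'   (minimum corner, um) and `fov_x_um, fov_y_um`.
#' @export
plan_mosaic <- function(bounds_um, fov_um, overlap_fraction = 0.05) {
  b <- as.list(bounds_um)
  w <- b$xmax - b$xmin; h <- b$ymax - b$ymin
  if (w < 0 || h < 0) stop_domain("degenerate bounds")
  ax <- mosaic_axis(w, fov_um[1], overlap_fraction)
  ay <- mosaic_axis(h, fov_um[2], overlap_fraction)
  g <- expand.grid(col = seq_len(ax$n), row = seq_len(ay$n))
  data.frame(tile_id = seq_len(nrow(g)), col = g$col, row = g$row,
             x0 = b$xmin + ax$origins[g$col],
             y0 = b$ymin + ay$origins[g$row],
             fov_x_um = fov_um[1], fov_y_um = fov_um[2])
}

#' Plan physical sectioning of a thick sample
#'
#' After each imaged slab, the slab minus an overlap slice is cut away. The
#' section count is `1` if the sample fits one imaging depth and
#' `1 + ceil((L - D) / (D - o))` otherwise; consecutive imaged slabs share
#' exactly `o` um.
#'
#' @param sample_depth_um Total sample depth `L` (um).
#' @param imaged_depth_um Depth imaged per section `D` (um).
#' @param section_overlap_um Overlap slice `o` left between sections (um);
#'   must be below `D`.
#' @return A data frame with one row per section: `section, z_top_um`
#'   (depth where the slab starts), `imaged_depth_um`, `advance_um` (cut
#'   thickness after imaging; `NA` for the last section, which is not cut).
#' @export
plan_sections <- function(sample_depth_um, imaged_depth_um,
                          section_overlap_um = 100) {
  check_positive(sample_depth_um, "sample_depth_um")
  check_positive(imaged_depth_um, "imaged_depth_um")
  check_nonnegative(section_overlap_um, "section_overlap_um")
  if (imaged_depth_um <= section_overlap_um) {
    stop_domain("`imaged_depth_um` must exceed `section_overlap_um` ",
                "(no forward progress)")
  }
  advance <- imaged_depth_um - section_overlap_um
  n <- if (sample_depth_um <= imaged_depth_um) 1L else {
    1L + as.integer(ceiling((sample_depth_um - imaged_depth_um) / advance))
  }
  data.frame(section = seq_len(n),
             z_top_um = (seq_len(n) - 1) * advance,
             imaged_depth_um = imaged_depth_um,
             advance_um = c(rep(advance, n - 1), NA_real_))
}

#' Z-stage trigger schedule and motion-blur length
#'
#' The stage moves continuously along Z and emits a TTL pulse every
#' `pulse_interval_um` to trigger camera exposure, so the pulse period is
#' `interval / speed`; during one exposure the sample travels
#' `speed x exposure`, the axial motion-blur length.
#'
#' @param stage_speed_mm_s Stage speed in mm/s (equivalently um/ms).
#' @param pulse_interval_um Distance between TTL pulses in um.
#' @param exposure_ms Exposure time in ms (optional; blur is `NA` without
#'   it).
#' @return A list with `period_ms` and `blur_um`.
#' @examples
#' trigger_schedule(0.08, 2, 30)  # 25 ms period, 2.4 um blur
#' @export
trigger_schedule <- function(stage_speed_mm_s, pulse_interval_um,
                             exposure_ms = NULL) {
  check_positive(stage_speed_mm_s, "stage_speed_mm_s")
  check_positive(pulse_interval_um, "pulse_interval_um")
  speed_um_ms <- stage_speed_mm_s  # mm/s == um/ms
  list(period_ms = pulse_interval_um / speed_um_ms,
       blur_um = if (is.null(exposure_ms)) NA_real_
                 else speed_um_ms * exposure_ms)
}

#' Frame, byte, and time cost of an acquisition plan
#'
#' @param plans Data frame of tiles (as from [plan_mosaic()]) with an
#'   `n_z` column giving the number of z frames per tile, or a plain count
#'   of tiles with `n_z` passed separately.
#' @param sensor_shape_px Sensor `(rows, cols)`.
#' @param config An [acquisition_config()] supplying exposure, stage and
#'   sectioning times.
#' @param n_z Frames per tile when `plans` lacks an `n_z` column.
#' @param n_cuts Number of vibratome cuts included in the run.
#' @return A list of class `cost_estimate` with `n_tiles, n_frames,
#'   n_bytes` (16-bit frames), `exposure_time_s, stage_time_s,
#'   sectioning_time_s, total_time_s`.
#' @export
cost_model <- function(plans, sensor_shape_px, config = acquisition_config(),
                       n_z = NULL, n_cuts = 0) {
  if (is.data.frame(plans)) {
    n_tiles <- nrow(plans)
    nz <- if ("n_z" %in% names(plans)) plans$n_z else rep(n_z %||% 0, n_tiles)
  } else {
    n_tiles <- as.integer(plans)
    nz <- rep(n_z %||% 0, n_tiles)
  }
  n_frames <- sum(nz)
  n_bytes <- n_frames * prod(sensor_shape_px) * 2
  exposure_time_s <- n_frames * config$exposure_ms / 1000
  # stage time: per-tile repositioning plus continuous z travel paced by
  # the trigger schedule (one frame per pulse)
  period_s <- if (n_frames > 0) {
    trigger_schedule(config$stage_speed_mm_s, 1)$period_ms / 1000
  } else 0
  stage_time_s <- n_tiles * config$stage_move_s
  sectioning_time_s <- n_cuts * config$section_cut_s
  structure(list(n_tiles = n_tiles, n_frames = n_frames, n_bytes = n_bytes,
                 exposure_time_s = exposure_time_s,
                 stage_time_s = stage_time_s,
                 sectioning_time_s = sectioning_time_s,
                 total_time_s = exposure_time_s + stage_time_s +
                   sectioning_time_s),
            class = "cost_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find the sample bounding box in an overview image
#'
#' Thresholds the overview maximum-intensity projection with Otsu's method
#' (or a supplied threshold) and returns the bounding rectangle of
#' above-threshold pixels grown by a margin. A field with no pixel above
#' threshold is reported explicitly rather than raised as an error.
#'
#' @param mip Numeric matrix (overview MIP).
#' @param margin_px Margin added on each side, clipped to the image.
#' @param threshold Optional absolute threshold; by default Otsu's
#'   threshold on the image histogram.
#' @return A list with `empty` (logical) and, when non-empty, `bbox`
#'   (`rmin, rmax, cmin, cmax` in pixels) and `threshold`.
#' @export
detect_sample_boundary <- function(mip, margin_px = 0, threshold = NULL) {
  if (length(mip) == 0) stop_domain("empty image")
  rng <- range(mip)
  if (is.null(threshold)) {
    if (diff(rng) == 0) return(list(empty = TRUE, threshold = rng[2]))
    norm <- (mip - rng[1]) / diff(rng)
    threshold <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  }
  hit <- which(mip > threshold, arr.ind = TRUE)
  if (nrow(hit) == 0) return(list(empty = TRUE, threshold = threshold))
  bbox <- c(rmin = max(1, min(hit[, 1]) - margin_px),
            rmax = min(nrow(mip), max(hit[, 1]) + margin_px),
            cmin = max(1, min(hit[, 2]) - margin_px),
            cmax = min(ncol(mip), max(hit[, 2]) + margin_px))
  list(empty = FALSE, bbox = bbox, threshold = threshold)
}
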