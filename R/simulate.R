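#' Simulate acquisition of one tile stack
#'
#' Forward model of tiled light-sheet imaging of a phantom. For every
#' requested z plane the phantom is blurred axially by the sheet profile --
#' in `stationary` mode the sheet waist sits on the line through the tile
#' center and its thickness grows with the lateral distance of each image
#' row from that line; in `tiled` mode the swept waist illuminates every
#' row at waist thickness -- convolved with a box kernel of the axial
#' motion-blur length. Planes are then blurred laterally by a Gaussian PSF
#' at the diffraction-limited FWHM, sampled at the effective pixel size,
#' scaled by the light-sheet brightness law and exposure, and read out with
#' Poisson shot noise, Gaussian read noise and a constant offset, clamped
#' to the 16-bit range.
#'
#' @param phantom A `phantom_volume`.
#' @param tile One-row data frame or list with `x0, y0` (minimum tile
#'   corner in um) and optionally `tile_id`.
#' @param optics A [detection_path()]; its zoom and sensor define the field
#'   of view.
#' @param sheet A [sheet_model()].
#' @param mode `"tiled"` (axially swept waist) or `"stationary"`.
#' @param z_range_um Length-2 z range (um) of the stack in phantom
#'   coordinates.
#' @param z_step_um Z spacing between frames (um).
#' @param config An [acquisition_config()] supplying exposure, stage speed
#'   and camera model.
#' @param pass Optional pass index stored in the metadata.
#' @param seed Seed of the camera-noise stream; defaults to the config
#'   seed combined with the tile id.
#' @return A `tile_stack`: integer counts array `[row, col, z]` plus
#'   complete metadata.
#' @export
simulate_stack <- function(phantom, tile, optics, sheet,
                           mode = c("tiled", "stationary"),
                           z_range_um, z_step_um,
                           config = acquisition_config(),
                           pass = NA_integer_, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(phantom, "phantom_volume"),
            inherits(optics, "detection_path"),
            inherits(sheet, "sheet_model"))
  tile <- as.list(tile)
  vox <- phantom$voxel_size_um                  # (y, x, z)
  d <- dim(phantom$intensity)
  ext <- c(d[2] * vox[2], d[1] * vox[1], d[3] * vox[3])  # (x, y, z) um

  mag <- total_magnification(optics$zoom, optics$objective$magnification)
  px <- effective_pixel_size(optics$camera_pixel_pitch_um, mag)
  npx <- optics$sensor_shape_px                 # (rows, cols)
  fov <- c(npx[2] * px, npx[1] * px)            # (x, y) um

  if (tile$x0 < 0 || tile$y0 < 0 ||
      tile$x0 + fov[1] > ext[1] + 1e-9 || tile$y0 + fov[2] > ext[2] + 1e-9) {
    stop_domain("tile plan lies outside the phantom bounds")
  }
  zs <- seq(z_range_um[1], z_range_um[2], by = z_step_um)
  if (min(zs) < 0 || max(zs) > ext[3] + 1e-9) {
    stop_domain("z range lies outside the phantom bounds")
  }

  na <- optics$objective$numerical_aperture
  sigma_lat_um <- fwhm_to_sigma(
    rayleigh_resolution(optics$emission_wavelength_um, na))
  blur_um <- config$stage_speed_mm_s * config$exposure_ms

  # phantom sub-grid covering the tile plus a blur margin
  margin_um <- 3 * sigma_lat_um + max(vox[1:2])
  ci <- function(u, v) floor(u / v) + 1L   # voxel index containing coord u
  c0 <- max(1L, ci(tile$x0 - margin_um, vox[2]))
  c1 <- min(d[2], ci(tile$x0 + fov[1] + margin_um, vox[2]))
  r0 <- max(1L, ci(tile$y0 - margin_um, vox[1]))
  r1 <- min(d[1], ci(tile$y0 + fov[2] + margin_um, vox[1]))
  slab <- phantom$intensity[r0:r1, c0:c1, , drop = FALSE]
  ny <- nrow(slab); nx <- ncol(slab); nzp <- dim(slab)[3]

  # axial weights: sheet Gaussian (sigma = w/2) convolved with the motion
  # box, integrated on the phantom z grid and renormalized per plane
  zc <- (seq_len(nzp) - 0.5) * vox[3]
  axial_w <- function(sigma) {
    dz <- outer(zc, zs, "-")
    w <- if (blur_um > 0) {
      stats::pnorm((dz + blur_um / 2) / sigma) -
        stats::pnorm((dz - blur_um / 2) / sigma)
    } else {
      stats::dnorm(dz / sigma)
    }
    sweep(w, 2, colSums(w), "/")
  }

  flat <- matrix(slab, ny * nx, nzp)
  if (mode == "tiled") {
    w0 <- sheet$waist_radius_w0_um / 2
    ax <- flat %*% axial_w(w0)                   # (ny*nx) x nz
  } else {
    waist_y <- tile$y0 + fov[2] / 2
    yc <- (r0:r1 - 0.5) * vox[1]
    sig_rows <- sheet_half_thickness(sheet, yc - waist_y) / 2
    ax <- matrix(0, ny * nx, length(zs))
    # rows sharing (rounded) sheet thickness are blurred in one multiply
    groups <- split(seq_len(ny), round(sig_rows, 3))
    for (g in groups) {
      w <- axial_w(sig_rows[g[1]])
      rows_flat <- as.vector(outer(g, (seq_len(nx) - 1) * ny, "+"))
      ax[rows_flat, ] <- flat[rows_flat, , drop = FALSE] %*% w
    }
  }

  # lateral PSF blur and sampling at pixel centers
  rows_px <- (tile$y0 + (seq_len(npx[1]) - 0.5) * px) / vox[1] + 0.5 -
    (r0 - 1)
  cols_px <- (tile$x0 + (seq_len(npx[2]) - 0.5) * px) / vox[2] + 0.5 -
    (c0 - 1)
  sig_px_row <- sigma_lat_um / vox[1]
  sig_px_col <- sigma_lat_um / vox[2]
  expected <- array(0, c(npx[1], npx[2], length(zs)))
  bright <- relative_brightness_lsfm(na, mag)
  for (k in seq_along(zs)) {
    plane <- matrix(ax[, k], ny, nx)
    if (sig_px_row > 0.05) plane <- gauss_blur_2d(plane, sig_px_row,
                                                  sig_px_col)
    expected[, , k] <- bilinear_sample(plane, rows_px, cols_px) *
      bright * config$exposure_ms
  }

  tile_id <- tile$tile_id %||% 1L
  if (is.null(seed)) seed <- substream_seed(config$seed,
                                            paste0("camera:", tile_id))
  counts <- withr::with_seed(seed, {
    photons <- if (config$shot_noise) {
      array(stats::rpois(length(expected), pmax(expected, 0)),
            dim(expected))
    } else expected
    out <- config$gain * photons + config$offset
    if (config$read_noise_sd > 0) {
      out <- out + stats::rnorm(length(out), 0, config$read_noise_sd)
    }
    array(as.integer(pmin(pmax(round(out), 0), 65535)), dim(out))
  })
  structure(list(
    counts = counts,
    meta = list(tile_id = tile_id, pass = pass, mode = mode,
                x0 = tile$x0, y0 = tile$y0, z_um = zs,
                pixel_size_um = px, z_step_um = z_step_um,
                zoom = optics$zoom, exposure_ms = config$exposure_ms,
                offset = config$offset, seed = seed)),
    class = "tile_stack")
}

#' @export
print.tile_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<tile_stack> %d x %d px, %d planes; %s mode, zoom %.2fx, %.3g um/px\n",
    d[1], d[2], d[3], x$meta$mode, x$meta$zoom, x$meta$pixel_size_um))
  invisible(x)
}

#' Measure dye-pool brightness over an optics grid
#'
#' Simulates imaging of a uniform dye pool for each `(NA, Mag)` setting and
#' reports the mean background-subtracted frame intensity. On a noiseless
#' simulation the regression of `log(intensity)` on `log(NA/Mag)` has
#' slope 2, the light-sheet brightness law.
#'
#' @param settings Data frame with columns `na` and `mag`.
#' @param sheet A [sheet_model()].
#' @param level Dye-pool intensity level.
#' @param exposure_ms Exposure used for every setting.
#' @param n_px Simulated sensor side length (small is enough for a uniform
#'   pool).
#' @param noiseless Disable shot/read noise (default `TRUE`).
#' @param seed Seed for the noisy variant.
#' @return The `settings` data frame with an added `mean_intensity` column.
#' @export
measure_dye_pool_brightness <- function(settings, sheet = sheet_model(),
                                        level = 100, exposure_ms = 50,
                                        n_px = 24, noiseless = TRUE,
                                        seed = 1L) {
  stopifnot(all(c("na", "mag") %in% names(settings)))
  cfg <- acquisition_config(shot_noise = !noiseless,
                            read_noise_sd = if (noiseless) 0 else 2,
                            exposure_ms = exposure_ms,
                            stage_speed_mm_s = 1e-6,  # negligible blur
                            seed = seed)
  out <- numeric(nrow(settings))
  for (i in seq_len(nrow(settings))) {
    na <- settings$na[i]; mag <- settings$mag[i]
    obj <- objective_spec("grid", na, mag, immersion_index = 1.56)
    opt <- detection_path(obj, zoom = 1, sensor_shape_px = c(n_px, n_px))
    px <- effective_pixel_size(opt$camera_pixel_pitch_um, mag)
    fov <- n_px * px
    pool <- generate_dye_pool(level,
                              extent_um = c(fov + 8, fov + 8, 20),
                              voxel_size_um = 2)
    st <- simulate_stack(pool, list(x0 = 4, y0 = 4, tile_id = i), opt, sheet,
                         mode = "tiled", z_range_um = c(8, 12),
                         z_step_um = 4, config = cfg)
    out[i] <- mean(st$counts) - cfg$offset
  }
  settings$mean_intensity <- out
  settings
}
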