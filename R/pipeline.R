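#' Demo-scale multi-scale pipeline configuration
#'
#' Bundles the module configurations for [run_pipeline()]. The default
#' phantom is a desk-scale 1 x 1 x 0.04 mm block -- large enough for a
#' 4 x 4 low-magnification mosaic while keeping the full pipeline run in
#' seconds-to-minutes on one CPU.
#'
#' @param phantom A [phantom_config()].
#' @param acquisition An [acquisition_config()].
#' @param triage A [triage_config()].
#' @param sheets Per-pass sheet models: the waist is opened up for the
#'   low-magnification passes (matching the larger field of view and
#'   coarse z-spacing, as the instrument's automatic aperture would) and
#'   kept thin for the high-resolution pass.
#' @param sensor_px Simulated sensor side length in px (the real 2048 px
#'   sensor is down-scaled for simulation speed; pixel size is
#'   unaffected).
#' @param mode Illumination mode passed to [simulate_stack()].
#' @param acquire_pass2 Simulate the voxel data of pass-2 tiles (`TRUE`)
#'   or plan and count them only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            acquisition = acquisition_config(),
                            triage = triage_config(),
                            sheets = list(
                              overview = sheet_model(12),
                              detect = sheet_model(12),
                              hires = sheet_model(1.7)),
                            sensor_px = 128L,
                            mode = "tiled",
                            acquire_pass2 = TRUE) {
  structure(list(phantom = phantom, acquisition = acquisition,
                 triage = triage, sheets = sheets,
                 sensor_px = as.integer(sensor_px), mode = mode,
                 acquire_pass2 = acquire_pass2),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_domain(sprintf("pipeline stage '%s' failed: %s", name,
                        conditionMessage(e)))
  })
}

# Ground-truth occupancy per tile. `margin_um` shrinks the attributed
# footprint: the triage statistic excludes a one-radius border band where
# the rolling-ball background is undefined, so signal there is not the
# tile's responsibility (and is picked up by the overlapping neighbour
# where one exists).
tile_truth <- function(phantom, tiles, fov_um, margin_um = 0) {
  vox <- phantom$voxel_size_um
  any_hit <- function(mask, x0, y0) {
    if (is.null(mask)) return(FALSE)
    # voxels whose center lies inside the attributed footprint
    r <- which((seq_len(dim(mask)[1]) - 0.5) * vox[1] >= y0 + margin_um &
                 (seq_len(dim(mask)[1]) - 0.5) * vox[1] <=
                   y0 + fov_um[2] - margin_um)
    c <- which((seq_len(dim(mask)[2]) - 0.5) * vox[2] >= x0 + margin_um &
                 (seq_len(dim(mask)[2]) - 0.5) * vox[2] <=
                   x0 + fov_um[1] - margin_um)
    length(r) > 0 && length(c) > 0 && any(mask[r, c, ])
  }
  data.frame(
    tile_id = tiles$tile_id,
    has_signal = vapply(seq_len(nrow(tiles)), function(i) {
      any_hit(phantom$truth$signal_mask, tiles$x0[i], tiles$y0[i])
    }, logical(1)),
    has_bright = vapply(seq_len(nrow(tiles)), function(i) {
      any_hit(phantom$truth$bright_mask, tiles$x0[i], tiles$y0[i])
    }, logical(1)),
    has_dim = vapply(seq_len(nrow(tiles)), function(i) {
      any_hit(phantom$truth$dim_mask, tiles$x0[i], tiles$y0[i])
    }, logical(1)))
}

#' Run the multi-scale acquisition pipeline on a synthetic phantom
#'
#' Executes the full procedure end to end: phantom generation; a lowest
#' magnification overview pass to find the sample boundary; a
#' signal-detection pass over the boundary mosaic; tile triage of each
#' pass-1 stack; a high-magnification pass planned (and optionally
#' acquired) over the flagged tiles only; the sectioning schedule; and
#' detection metrics against the phantom's ground truth. The run is a
#' deterministic function of `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @param seed Master integer seed, expanded per stage via
#'   [substream_seed()].
#' @param dir Optional output directory; when given, tile stacks,
#'   decisions CSV, metrics JSON and the run manifest are written there.
#' @return A list of class `run_manifest`: `seed, config_hash`, the
#'   phantom truth table, per-pass tile tables, triage `decisions`,
#'   `rescan_ids`, `metrics`, `frame_counts` (pass-2 planned vs full
#'   coverage), `sections`, and `cost`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  pc <- config$phantom
  pc$seed <- substream_seed(seed, "phantom")
  ac <- config$acquisition
  ac$seed <- substream_seed(seed, "camera")
  ext <- pc$extent_um

  phantom <- stage("phantom", {
    trees <- generate_neurons(pc)
    rasterize(trees, pc)
  })

  sched <- ac$zoom_schedule
  path_for <- function(zoom) {
    macro_detection_path(zoom = zoom,
                         sensor_shape_px = c(config$sensor_px,
                                             config$sensor_px))
  }

  # pass 0: overview to find the sample boundary
  overview <- stage("overview", {
    zoom0 <- sched$zoom[1]
    px0 <- effective_pixel_size(6.5, total_magnification(zoom0, 2))
    n0 <- floor(min(ext[1:2]) / px0)
    opt0 <- macro_detection_path(zoom = zoom0,
                                 sensor_shape_px = c(n0, n0))
    cfg0 <- ac; cfg0$exposure_ms <- sched$exposure_ms[1]
    st <- simulate_stack(phantom, list(x0 = 0, y0 = 0, tile_id = 0L),
                         opt0, config$sheets$overview, mode = config$mode,
                         z_range_um = c(sched$z_step_um[1] / 2,
                                        ext[3] - sched$z_step_um[1] / 2),
                         z_step_um = sched$z_step_um[1],
                         config = cfg0, pass = 0L)
    bb <- detect_sample_boundary(mip_z(st), margin_px = 2)
    bounds <- if (bb$empty) {
      list(xmin = 0, xmax = ext[1], ymin = 0, ymax = ext[2])
    } else {
      list(xmin = max(0, (bb$bbox[["cmin"]] - 1) * px0),
           xmax = min(ext[1], bb$bbox[["cmax"]] * px0),
           ymin = max(0, (bb$bbox[["rmin"]] - 1) * px0),
           ymax = min(ext[2], bb$bbox[["rmax"]] * px0))
    }
    list(stack = st, bounds = bounds, empty = bb$empty)
  })

  # pass 1: signal-detection mosaic
  pass1 <- stage("pass1", {
    zoom1 <- sched$zoom[2]
    opt1 <- path_for(zoom1)
    px1 <- effective_pixel_size(6.5, total_magnification(zoom1, 2))
    fov1 <- config$sensor_px * px1
    b <- overview$bounds
    # keep the mosaic inside the phantom (tiles are FOV-sized)
    b$xmax <- min(b$xmax, ext[1]); b$ymax <- min(b$ymax, ext[2])
    b$xmin <- min(b$xmin, ext[1] - fov1); b$ymin <- min(b$ymin, ext[2] - fov1)
    tiles <- plan_mosaic(b, c(fov1, fov1), ac$xy_overlap_fraction)
    z_step <- sched$z_step_um[2]
    zr <- c(z_step / 2, ext[3] - z_step / 2)
    n_z <- length(seq(zr[1], zr[2], by = z_step))
    cfg1 <- ac; cfg1$exposure_ms <- sched$exposure_ms[2]
    stacks <- lapply(seq_len(nrow(tiles)), function(i) {
      simulate_stack(phantom, tiles[i, ], opt1, config$sheets$detect,
                     mode = config$mode, z_range_um = zr,
                     z_step_um = z_step, config = cfg1, pass = 1L)
    })
    list(tiles = cbind(tiles, n_z = n_z, zoom = zoom1), stacks = stacks,
         fov = c(fov1, fov1))
  })

  decisions <- stage("triage", {
    do.call(rbind, lapply(seq_along(pass1$stacks), function(i) {
      triage_tile(pass1$stacks[[i]], config$triage,
                  tile_id = pass1$tiles$tile_id[i])
    }))
  })
  rescan_ids <- select_rescan_tiles(decisions, config$triage$policy)

  # pass 2: high magnification over flagged tiles only
  pass2 <- stage("pass2", {
    zoom2 <- sched$zoom[3]
    opt2 <- path_for(zoom2)
    px2 <- effective_pixel_size(6.5, total_magnification(zoom2, 2))
    fov2 <- config$sensor_px * px2
    z_step <- sched$z_step_um[3]
    zr <- c(z_step / 2, ext[3] - z_step / 2)
    n_z <- length(seq(zr[1], zr[2], by = z_step))
    cfg2 <- ac; cfg2$exposure_ms <- sched$exposure_ms[3]
    plan_for <- function(t1) {
      b <- list(xmin = t1$x0, xmax = min(ext[1], t1$x0 + pass1$fov[1]),
                ymin = t1$y0, ymax = min(ext[2], t1$y0 + pass1$fov[2]))
      b$xmin <- min(b$xmin, ext[1] - fov2)
      b$ymin <- min(b$ymin, ext[2] - fov2)
      plan_mosaic(b, c(fov2, fov2), ac$xy_overlap_fraction)
    }
    sub_per_tile <- nrow(plan_for(pass1$tiles[1, ]))
    plans <- lapply(rescan_ids, function(id) {
      p <- plan_for(pass1$tiles[pass1$tiles$tile_id == id, ])
      p$parent_tile <- id
      p
    })
    plans <- if (length(plans)) do.call(rbind, plans) else
      data.frame(tile_id = integer(0), x0 = numeric(0), y0 = numeric(0),
                 parent_tile = integer(0))
    if (nrow(plans)) plans$tile_id <- seq_len(nrow(plans))
    stacks <- if (config$acquire_pass2 && nrow(plans)) {
      lapply(seq_len(nrow(plans)), function(i) {
        simulate_stack(phantom, plans[i, ], opt2, config$sheets$hires,
                       mode = config$mode, z_range_um = zr,
                       z_step_um = z_step, config = cfg2, pass = 2L)
      })
    } else list()
    frames_planned <- nrow(plans) * n_z
    frames_full <- nrow(pass1$tiles) * sub_per_tile * n_z
    list(plans = if (nrow(plans)) cbind(plans, n_z = n_z, zoom = zoom2)
         else plans,
         stacks = stacks, n_z = n_z,
         frames_planned = frames_planned, frames_full = frames_full)
  })

  sections <- stage("sections", {
    plan_sections(ext[3], imaged_depth_um = max(ext[3],
                                                ac$section_overlap_um + 1),
                  section_overlap_um = min(ac$section_overlap_um,
                                           ext[3] / 2))
  })

  metrics <- stage("metrics", {
    radius_px <- decisions$rolling_ball_radius_px[1]
    px1 <- effective_pixel_size(6.5, total_magnification(sched$zoom[2], 2))
    truth <- tile_truth(phantom, pass1$tiles, pass1$fov,
                        margin_um = radius_px * px1)
    snr_by_tile <- stats::aggregate(decisions$snr,
                                    list(tile_id = decisions$tile_id), max)
    truth$snr <- snr_by_tile$x[match(truth$tile_id, snr_by_tile$tile_id)]
    m <- evaluate_detection(rescan_ids, truth)
    list(truth = truth, metrics = m)
  })

  cost <- cost_model(rbind(pass1$tiles[c("tile_id", "n_z")],
                           if (nrow(pass2$plans))
                             pass2$plans[c("tile_id", "n_z")]),
                     sensor_shape_px = c(config$sensor_px,
                                         config$sensor_px),
                     config = ac,
                     n_cuts = sum(!is.na(sections$advance_um)))

  manifest <- structure(list(
    seed = seed,
    config_hash = config_hash(config),
    bounds = overview$bounds,
    pass1_tiles = pass1$tiles,
    pass2_plans = pass2$plans,
    decisions = decisions,
    rescan_ids = rescan_ids,
    truth = metrics$truth,
    metrics = metrics$metrics,
    frame_counts = list(pass2_planned = pass2$frames_planned,
                        pass2_full_coverage = pass2$frames_full),
    sections = sections,
    cost = cost),
    class = "run_manifest")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(pass1$stacks)) {
      write_stack(pass1$stacks[[i]],
                  file.path(dir, sprintf("pass1_tile%03d.tif", i)))
    }
    utils::write.csv(decisions, file.path(dir, "decisions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, config_hash = manifest$config_hash,
           fp_rate = metrics$metrics$fp_rate,
           fn_rate = metrics$metrics$fn_rate,
           n_tiles = nrow(pass1$tiles),
           rescan_ids = rescan_ids,
           frame_counts = manifest$frame_counts),
      file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf(
    "<run_manifest> seed %s; %d pass-1 tiles, %d flagged; fp %.3f fn %.3f\n",
    format(x$seed), nrow(x$pass1_tiles), length(x$rescan_ids),
    x$metrics$fp_rate, x$metrics$fn_rate))
  invisible(x)
}
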