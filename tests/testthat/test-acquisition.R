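test_that("mosaic planning reproduces the closed-form tile counts", {
  b <- function(w, h = w) list(xmin = 0, xmax = w, ymin = 0, ymax = h)
  expect_equal(nrow(plan_mosaic(b(4000), c(4000, 4000), 0.05)), 1)
  m <- plan_mosaic(b(11600), c(4000, 4000), 0.05)
  expect_equal(max(m$col), 3)                      # ceil(7.6/3.8) + 1
  expect_equal(nrow(m), 9)
  expect_equal(max(plan_mosaic(b(8000), c(4000, 4000), 0.05)$col), 3)
  expect_error(plan_mosaic(b(100), c(0, 10), 0.05), "positive")
})

test_that("mosaic tiles cover the bounds with at least the stated overlap", {
  set.seed(71)
  for (i in 1:25) {
    w <- stats::runif(1, 50, 5000); f <- stats::runif(1, 40, w + 100)
    v <- stats::runif(1, 0, 0.4)
    m <- plan_mosaic(list(xmin = 0, xmax = w, ymin = 0, ymax = 40),
                     c(f, 40), v)
    xs <- sort(unique(m$x0))
    expect_lte(xs[1], 0)
    expect_gte(xs[length(xs)] + f, w - 1e-9)
    if (length(xs) > 1) {
      gaps <- diff(xs)
      expect_true(all(gaps <= (1 - v) * f + 1e-9))  # overlap >= v*f
    }
    # count matches the formula
    n_expect <- if (w <= f) 1 else ceiling((w - f) / ((1 - v) * f)) + 1
    expect_equal(length(xs), n_expect)
  }
})

test_that("section planning: counts, exact overlap, coverage", {
  expect_equal(nrow(plan_sections(1000, 1000, 100)), 1)
  expect_equal(nrow(plan_sections(10000, 1000, 100)), 11)
  expect_equal(nrow(plan_sections(5800, 2000, 100)), 3)
  expect_error(plan_sections(1000, 100, 100), "progress")

  # exhaustive small-case enumeration against a step-by-step simulation
  for (L in seq(100, 3000, by = 170)) {
    for (D in c(250, 400, 1000)) {
      o <- 50
      s <- plan_sections(L, D, o)
      # simulate: advance until the imaged slabs cover L
      n_sim <- 1; top <- D
      while (top < L) { top <- top + (D - o); n_sim <- n_sim + 1 }
      expect_equal(nrow(s), n_sim)
      # consecutive imaged slabs share exactly o
      if (nrow(s) > 1) {
        expect_true(all(abs(diff(s$z_top_um) - (D - o)) < 1e-9))
      }
      expect_gte(s$z_top_um[nrow(s)] + D, L)
    }
  }
})

test_that("trigger schedule: pulse period and motion blur", {
  expect_equal(trigger_schedule(0.08, 2)$period_ms, 25)
  expect_equal(trigger_schedule(0.1, 2)$period_ms, 20)
  expect_equal(trigger_schedule(0.1, 2, exposure_ms = 30)$blur_um, 3)
  expect_error(trigger_schedule(0, 2), "positive")
})

test_that("cost model: byte arithmetic, zero plans, additivity, proportionality", {
  cfg <- acquisition_config()
  c1 <- cost_model(1, c(2048, 2048), cfg, n_z = 100)
  expect_equal(c1$n_bytes, 838860800)
  c0 <- cost_model(0, c(2048, 2048), cfg, n_z = 100)
  expect_equal(c0$n_frames, 0)
  expect_equal(c0$n_bytes, 0)
  expect_equal(c0$total_time_s, 0)
  # additive over disjoint plan subsets
  plans <- data.frame(tile_id = 1:9, n_z = rep(20, 9))
  whole <- cost_model(plans, c(128, 128), cfg)
  parts <- cost_model(plans[1:4, ], c(128, 128), cfg)
  rest <- cost_model(plans[5:9, ], c(128, 128), cfg)
  expect_equal(whole$n_frames, parts$n_frames + rest$n_frames)
  expect_equal(whole$n_bytes, parts$n_bytes + rest$n_bytes)
  # restricting a pass to 1/3 of tiles scales frames by exactly 1/3
  third <- cost_model(plans[1:3, ], c(128, 128), cfg)
  expect_equal(third$n_frames, whole$n_frames / 3)
})

test_that("camera noise model gives the configured offset and read noise", {
  pool <- generate_dye_pool(0, extent_um = c(700, 700, 20), voxel_size_um = 2)
  opt <- macro_detection_path(zoom = 1.6, sensor_shape_px = c(340, 340))
  cfg <- acquisition_config(offset = 100, read_noise_sd = 2, seed = 4)
  st <- simulate_stack(pool, list(x0 = 2, y0 = 2), opt, sheet_model(),
                       mode = "tiled", z_range_um = c(8, 12), z_step_um = 4,
                       config = cfg)
  px <- as.numeric(st$counts)
  expect_gt(length(px), 1e5)
  expect_equal(mean(px), 100, tolerance = 0.001)      # +-0.1 counts
  expect_equal(stats::sd(px), 2, tolerance = 0.1)     # +-10 %
})

test_that("expected signal is linear in exposure and phantom intensity", {
  opt <- macro_detection_path(zoom = 1.6, sensor_shape_px = c(32, 32))
  mean_counts <- function(level, exposure) {
    pool <- generate_dye_pool(level, extent_um = c(100, 100, 20),
                              voxel_size_um = 2)
    cfg <- acquisition_config(offset = 0, read_noise_sd = 0,
                              shot_noise = FALSE, exposure_ms = exposure,
                              stage_speed_mm_s = 1e-6)
    st <- simulate_stack(pool, list(x0 = 10, y0 = 10), opt, sheet_model(),
                         mode = "tiled", z_range_um = c(10, 10),
                         z_step_um = 2, config = cfg)
    mean(st$counts)
  }
  base <- mean_counts(200, 30)
  expect_equal(mean_counts(400, 30) / base, 2, tolerance = 0.01)
  expect_equal(mean_counts(200, 60) / base, 2, tolerance = 0.01)
})

test_that("tiled sheet is uniform across the FOV; stationary blurs at the edge", {
  ext <- c(120, 200, 40)
  pos <- expand.grid(x = c(40, 60, 80), y = c(20, 100, 180), z = 20)
  ph <- generate_beads(0, ext, voxel_size_um = 1, positions = pos,
                       amplitude = 5e4)
  opt <- macro_detection_path(zoom = 6.3, sensor_shape_px = c(384, 192))
  cfg <- acquisition_config(shot_noise = FALSE, read_noise_sd = 0,
                            stage_speed_mm_s = 1e-6)
  axial_fwhm <- function(mode) {
    st <- simulate_stack(ph, list(x0 = 10, y0 = 1), opt, sheet_model(2),
                         mode = mode, z_range_um = c(5, 35), z_step_um = 1,
                         config = cfg)
    est <- characterize_psf(st, voxel_size_um = c(rep(st$meta$pixel_size_um,
                                                      2), 1),
                            crop_halfwidth_px = c(5, 5, 12),
                            threshold_k = 20, min_separation_px = 10)
    pb <- est$per_bead
    # waist line runs through the FOV center row
    center <- abs(pb$row - 192) < 64
    list(center = pb$fwhm_z_um[center], edge = pb$fwhm_z_um[!center],
         all = pb$fwhm_z_um)
  }
  tiled <- axial_fwhm("tiled")
  stat <- axial_fwhm("stationary")
  # both modes agree at the waist line
  expect_equal(median(tiled$center), median(stat$center), tolerance = 0.05)
  # tiled: spatially uniform; stationary: edge rows heavily blurred
  expect_lt(stats::sd(tiled$all) / mean(tiled$all), 0.05)
  expect_gt(median(stat$edge) / median(stat$center), 1.5)
})

test_that("dye-pool brightness follows the NA^2/Mag^2 law", {
  grid <- expand.grid(na = c(0.2, 0.4, 0.8), mag = c(2, 8))
  res <- measure_dye_pool_brightness(grid, level = 2000)
  fit <- stats::lm(log(mean_intensity) ~ log(na / mag), data = res)
  expect_equal(unname(stats::coef(fit)[2]), 2, tolerance = 0.025)
  # settings with equal NA/Mag ratio are equally bright
  pair <- measure_dye_pool_brightness(data.frame(na = c(0.2, 0.4),
                                                 mag = c(2, 4)),
                                      level = 2000)
  expect_equal(pair$mean_intensity[1], pair$mean_intensity[2],
               tolerance = 0.02)
  # doubling the dye level doubles the signal
  lo <- measure_dye_pool_brightness(data.frame(na = 0.4, mag = 4),
                                    level = 1000)
  hi <- measure_dye_pool_brightness(data.frame(na = 0.4, mag = 4),
                                    level = 2000)
  expect_equal(hi$mean_intensity / lo$mean_intensity, 2, tolerance = 0.01)
})

test_that("sample-boundary detection: empty field, disc box, margin growth", {
  flat <- matrix(5, 60, 60)
  expect_true(detect_sample_boundary(flat)$empty)

  img <- matrix(10, 80, 80)
  rc <- expand.grid(r = 1:80, c = 1:80)
  disc <- (rc$r - 40)^2 + (rc$c - 50)^2 <= 15^2
  img[cbind(rc$r[disc], rc$c[disc])] <- 200
  bb <- detect_sample_boundary(img, margin_px = 0)
  expect_false(bb$empty)
  expect_true(all(abs(bb$bbox - c(25, 55, 35, 65)) <= 1))
  bb2 <- detect_sample_boundary(img, margin_px = 4)
  expect_equal(unname(bb2$bbox - bb$bbox), c(-4, 4, -4, 4))
  # margin clipped at the image edge
  bb3 <- detect_sample_boundary(img, margin_px = 60)
  expect_equal(unname(bb3$bbox), c(1, 80, 1, 80))
})
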