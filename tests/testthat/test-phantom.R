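test_that("neuron generation is seeded, valid, and in bounds", {
  cfg <- small_phantom_config()
  cfg0 <- cfg; cfg0$n_neurons <- 0
  expect_identical(generate_neurons(cfg0), list())

  cfg5 <- cfg; cfg5$n_neurons <- 5
  trees <- generate_neurons(cfg5)
  expect_length(trees, 5)
  for (tr in trees) {
    expect_silent(validate_tree(tr))
    expect_equal(sum(tr$parent == -1), 1)
    expect_true(all(tr$x >= 0 & tr$x <= cfg$extent_um[1]))
    expect_true(all(tr$y >= 0 & tr$y <= cfg$extent_um[2]))
    expect_true(all(tr$z >= 0 & tr$z <= cfg$extent_um[3]))
  }
  expect_identical(trees, generate_neurons(cfg5))  # bit-identical rerun
})

test_that("cable length correlates linearly with branch count over a population", {
  cfg <- phantom_config(extent_um = c(600, 600, 60), n_neurons = 32,
                        max_nodes = 200, seed = 9)
  trees <- generate_neurons(cfg)
  st <- vapply(trees, function(tr) {
    s <- swc_stats(tr)
    c(s$total_length_um, s$n_branch_points)
  }, numeric(2))
  expect_gt(stats::cor(st[1, ], st[2, ]), 0.8)
})

test_that("swc_stats matches hand-computed morphometry", {
  seg <- data.frame(id = 1:2, type = c(1L, 2L), x = c(0, 3), y = c(0, 4),
                    z = 0, radius = 1, parent = c(-1L, 1L))
  s <- swc_stats(structure(seg, class = c("neuron_tree", "data.frame")))
  expect_equal(s$total_length_um, 5)
  expect_equal(s$n_branch_points, 0L)
  expect_equal(s$n_terminals, 1L)

  ytree <- data.frame(id = 1:4, type = c(1L, 2L, 2L, 2L),
                      x = c(0, 0, 10, -10), y = 0, z = c(0, 10, 10, 10),
                      radius = 1, parent = c(-1L, 1L, 2L, 2L))
  s <- swc_stats(structure(ytree, class = c("neuron_tree", "data.frame")))
  expect_equal(s$total_length_um, 30)
  expect_equal(s$n_branch_points, 1L)
  expect_equal(s$n_terminals, 2L)

  root_only <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                          radius = 1, parent = -1L)
  s <- swc_stats(structure(root_only, class = c("neuron_tree", "data.frame")))
  expect_equal(s$total_length_um, 0)
  expect_equal(s$n_terminals, 1L)  # bare root counts as a terminal
})

test_that("tree validation rejects multi-root, duplicate and cyclic tables", {
  base <- data.frame(id = 1:3, type = 2L, x = 0, y = 0, z = 0, radius = 1,
                     parent = c(-1L, 1L, 2L))
  two_roots <- base; two_roots$parent[2] <- -1L
  expect_error(validate_tree(two_roots), "exactly one root")
  dup <- base; dup$id[2] <- 1L
  expect_error(validate_tree(dup), "duplicate")
  cyc <- base; cyc$parent <- c(3L, 1L, 2L)
  expect_error(validate_tree(cyc), "root|cycle")
})

test_that("SWC files round-trip generated trees", {
  trees <- generate_neurons(small_phantom_config())
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(trees[[1]], path)
  back <- read_swc(path)
  expect_equal(as.data.frame(back), as.data.frame(trees[[1]]),
               tolerance = 1e-9, ignore_attr = TRUE)
  bad <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# header", "1 1 0 0"), bad)
  expect_error(read_swc(bad), "malformed")
})

test_that("rasterization: background floor, cylinder mask volume, class ratio", {
  cfg <- small_phantom_config(background_level = 7)
  empty <- rasterize(list(), cfg)
  expect_true(all(empty$intensity == 7))

  # straight axon: truth-mask voxel count vs the analytic cylinder volume
  cfg1 <- phantom_config(extent_um = c(100, 40, 20), voxel_size_um = 1,
                         background_level = 0, background_texture_sd = 0,
                         seed = 1)
  tr <- straight_axon_tree(c(10, 20, 10), c(90, 20, 10), radius = 3)
  ph <- rasterize(list(tr), cfg1)
  expected_vox <- pi * 3^2 * 80   # cylinder volume / unit voxel volume
  expect_lt(abs(sum(ph$truth$signal_mask) - expected_vox) / expected_vox,
            0.2)
  # every truth voxel is strictly above background before noise
  expect_true(all(ph$intensity[ph$truth$signal_mask] > 0))

  # bright and dim axons rasterize at the configured amplitude ratio
  trb <- straight_axon_tree(c(10, 10, 10), c(50, 10, 10), snr_class = "bright")
  trd <- straight_axon_tree(c(10, 30, 10), c(50, 30, 10), snr_class = "dim")
  ph2 <- rasterize(list(trb, trd), cfg1)
  peak_b <- max(ph2$intensity[10, , ])
  peak_d <- max(ph2$intensity[30, , ])
  expect_equal(peak_b / peak_d, cfg1$bright_level / cfg1$dim_level,
               tolerance = 1e-6)
})

test_that("rasterization is additive with a single background term", {
  cfg <- phantom_config(extent_um = c(60, 60, 20), voxel_size_um = 2,
                        background_level = 5, background_texture_sd = 0,
                        seed = 1)
  a <- straight_axon_tree(c(10, 15, 10), c(50, 15, 10))
  b <- straight_axon_tree(c(10, 45, 10), c(50, 45, 10))
  both <- rasterize(list(a, b), cfg)
  sep <- rasterize(list(a), cfg)$intensity + rasterize(list(b), cfg)$intensity
  expect_equal(both$intensity, sep - 5, tolerance = 1e-9)
})

test_that("out-of-bounds nodes are reported by id", {
  cfg <- small_phantom_config()
  tr <- straight_axon_tree(c(10, 10, 10), c(500, 10, 10))
  expect_error(rasterize(list(tr), cfg), "node 2")
})

test_that("bead fields: empty, reproducible, Poisson-consistent counts", {
  ext <- c(500, 500, 500)
  none <- generate_beads(0, ext, voxel_size_um = 2, seed = 1,
                         background_level = 3)
  expect_true(all(none$intensity == 3))
  expect_equal(nrow(none$truth$beads), 0)

  b1 <- generate_beads(300, ext, voxel_size_um = 2, seed = 5)
  b2 <- generate_beads(300, ext, voxel_size_um = 2, seed = 5)
  expect_identical(b1$truth$beads, b2$truth$beads)
  expect_error(generate_beads(300, ext, voxel_size_um = 2,
                              bead_diameter_um = 5), "sub-resolution")

  # mean count over 20 seeds inside the Poisson 99% band
  lambda <- 300 * prod(ext) / 1e9
  counts <- vapply(1:20, function(s) {
    nrow(generate_beads(300, ext, voxel_size_um = 2, seed = s)$truth$beads)
  }, numeric(1))
  band <- stats::qpois(c(0.005, 0.995), 20 * lambda) / 20
  expect_gte(mean(counts), band[1])
  expect_lte(mean(counts), band[2])
})

test_that("dye pools are exactly uniform", {
  expect_true(all(generate_dye_pool(0)$intensity == 0))
  expect_true(all(generate_dye_pool(100)$intensity == 100))
  expect_error(generate_dye_pool(-1), "non-negative")
})

test_that("spike-track generator follows the logistic law", {
  expect_error(generate_spike_track(slope_um = 0), "positive")
  # far below the transition the narrow probability is negligible
  far <- generate_spike_track(d0_um = 22, slope_um = 10, n = 2000, seed = 2,
                              distance_range = c(-100, -78))  # d0 - 10*slope
  expect_lt(mean(far$is_narrow), 0.01)
  # near the half-probability point the narrow fraction is ~0.5
  tr <- generate_spike_track(d0_um = 22, slope_um = 10, n = 2000, seed = 3,
                             distance_range = c(-100, 100))
  win <- tr[abs(tr$distance_um - 22) <= 5, ]
  ci <- stats::qbinom(c(0.005, 0.995), nrow(win), 0.5) / nrow(win)
  expect_gte(mean(win$is_narrow), ci[1])
  expect_lte(mean(win$is_narrow), ci[2])
})
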