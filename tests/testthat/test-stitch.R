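make_texture <- function(nr, nc, seed = 1) {
  set.seed(seed)
  coarse <- matrix(stats::rnorm(ceiling(nr / 4) * ceiling(nc / 4)),
                   ceiling(nr / 4))
  m <- coarse[rep(seq_len(nrow(coarse)), each = 4)[1:nr],
              rep(seq_len(ncol(coarse)), each = 4)[1:nc]]
  m + matrix(stats::rnorm(nr * nc, sd = 0.05), nr, nc)
}

test_that("phase correlation recovers rigid shifts between crops", {
  a <- make_texture(64, 64, 3)
  expect_equal(estimate_offset(a, a)$shift, c(0, 0))
  expect_gt(estimate_offset(a, a)$score, 0.999)

  big <- make_texture(100, 100, 4)
  crop_a <- big[21:84, 21:84]
  crop_b <- big[(21 - 7):(84 - 7), (21 + 3):(84 + 3)]
  off <- estimate_offset(crop_a, crop_b)
  expect_equal(off$shift, c(7, -3))                  # exact, noiseless
  # antisymmetry
  rev <- estimate_offset(crop_b, crop_a)
  expect_equal(rev$shift, -off$shift)

  # 10% noise: within 1 px
  s <- stats::sd(crop_b)
  set.seed(9)
  noisy <- crop_b + matrix(stats::rnorm(length(crop_b), sd = 0.1 * s),
                           nrow(crop_b))
  offn <- estimate_offset(crop_a, noisy)
  expect_true(all(abs(offn$shift - c(7, -3)) <= 1))

  expect_warning(o0 <- estimate_offset(matrix(5, 32, 32),
                                       matrix(5, 32, 32)), "constant")
  expect_equal(o0$score, 0)
  expect_error(estimate_offset(matrix(0, 8, 8), matrix(0, 8, 8)), "16 px")
})

test_that("pairwise offsets propagate over a spanning tree; cycles are checked", {
  pairs <- data.frame(from = c(1, 2, 1), to = c(2, 3, 3),
                      drow = c(5, 5, 10), dcol = c(0, 2, 2))
  pos <- solve_offsets(pairs, reference = 1)
  expect_equal(pos$row_px[pos$tile_id == 3], 10)
  expect_equal(pos$col_px[pos$tile_id == 3], 2)
  bad <- pairs; bad$drow[3] <- 20
  expect_error(solve_offsets(bad, reference = 1), "cycle")
})

test_that("fusion reconstructs a source volume cut into overlapping tiles", {
  src <- make_texture(60, 80, 7)
  expect_equal(fuse_tiles(list(src), matrix(c(0, 0), 1)), src)

  t1 <- src[, 1:50]; t2 <- src[, 41:80]
  fused <- fuse_tiles(list(t1, t2), matrix(c(0, 0, 0, 40), 2, byrow = TRUE))
  # both tiles agree with the source, so blending reproduces it exactly,
  # inside and outside the blend ramps
  expect_equal(fused, src, tolerance = 1e-12)

  # 3D: two overlapping slabs
  vol <- array(stats::rnorm(20 * 20 * 10), c(20, 20, 10))
  v1 <- vol[1:14, , ]; v2 <- vol[9:20, , ]
  fused3 <- fuse_tiles(list(v1, v2),
                       matrix(c(0, 0, 0, 8, 0, 0), 2, byrow = TRUE))
  expect_equal(fused3, vol, tolerance = 1e-12)
})

test_that("blending weights sum to one: differing tiles average, not add", {
  t1 <- matrix(0, 20, 30)
  t2 <- matrix(10, 20, 30)
  fused <- fuse_tiles(list(t1, t2), matrix(c(0, 0, 0, 10), 2, byrow = TRUE))
  # overlap columns hold a convex combination of 0 and 10
  ov <- fused[, 11:30]
  expect_true(all(ov >= 0 & ov <= 10))
  expect_equal(fused[, 1:10], matrix(0, 20, 10))    # verbatim outside
  expect_equal(fused[, 31:40], matrix(10, 20, 10))
})

test_that("block-mean downsampling: identity, constants, hand-computed blocks", {
  v <- array(stats::rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_equal(downsample(v, 1, 1), v)
  expect_true(all(downsample(array(3, c(6, 6, 6)), 1, 3) == 3))
  expect_error(downsample(v, 2, 1), "target")

  a <- array(as.numeric(1:64), c(4, 4, 4))
  d <- downsample(a, 1, 2)
  expect_equal(dim(d), c(2, 2, 2))
  # hand-computed mean of the first 2x2x2 block
  expect_equal(d[1, 1, 1], mean(a[1:2, 1:2, 1:2]))
  expect_equal(d[2, 2, 2], mean(a[3:4, 3:4, 3:4]))
  # global mean preserved for integer ratios
  expect_equal(mean(d), mean(a))

  # down - up(nearest) - down is idempotent
  up <- upsample_nearest(d, 2)
  expect_equal(downsample(up, 1, 2), d)
})

test_that("boundary distance: identity, parallel planes, translated circle", {
  g <- as.matrix(expand.grid(x = 0:9 * 10, y = 0:9 * 10, z = 0))
  expect_equal(boundary_distance(g, g), 0)
  g2 <- g; g2[, 3] <- 12
  expect_equal(boundary_distance(g, g2), 12)
  expect_equal(boundary_distance(g2, g), 12)       # symmetric
  expect_error(boundary_distance(g[0, ], g), "empty")

  # circle vs the same circle translated by t << r: mean NN distance is
  # the angular average of |t cos(theta)| = 2 t / pi
  th <- seq(0, 2 * pi, length.out = 4001)[-1]
  r <- 500; t <- 3
  circ <- cbind(r * cos(th), r * sin(th), 0)
  moved <- cbind(r * cos(th) + t, r * sin(th), 0)
  # numeric-integration oracle for the expected average
  oracle <- mean(abs(t * cos(th)))
  expect_equal(oracle, 2 * t / pi, tolerance = 1e-3)
  expect_equal(boundary_distance(circ, moved), 2 * t / pi, tolerance = 0.05)
})
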