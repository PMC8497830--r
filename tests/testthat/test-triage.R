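test_that("z-MIP is the pixelwise maximum", {
  one <- array(matrix(1:12, 3, 4), c(3, 4, 1))
  expect_equal(mip_z(one), matrix(1:12, 3, 4))
  two <- array(c(3, 7), c(1, 1, 2))
  expect_equal(mip_z(two), matrix(7, 1, 1))
  set.seed(1)
  st <- array(stats::rnorm(4 * 5 * 6), c(4, 5, 6))
  m <- mip_z(st)
  for (k in 1:6) expect_true(all(m >= st[, , k]))
  expect_error(mip_z(array(0, c(0, 0, 0))), "empty")
})

test_that("rolling-ball background behaves like a grayscale opening", {
  const <- matrix(42, 20, 20)
  expect_equal(rolling_ball_background(const, 5), const)

  # a single hot pixel on a flat field is removed entirely
  img <- matrix(10, 30, 30)
  img[15, 15] <- 110
  bg <- rolling_ball_background(img, 5)
  expect_equal(bg, matrix(10, 30, 30))
  expect_equal((img - bg)[15, 15], 100)

  # a plateau wider than the disc survives in the background
  img2 <- matrix(0, 40, 40)
  img2[10:35, 10:35] <- 50
  bg2 <- rolling_ball_background(img2, 5)
  expect_equal(bg2[20, 20], 50)
  expect_true(all(bg2 <= img2))
  expect_error(rolling_ball_background(matrix(0, 5, 5), 10), "larger")
})

test_that("rolling-ball equals the brute-force opening oracle on random images", {
  set.seed(33)
  for (i in 1:12) {
    nr <- sample(10:32, 1); nc <- sample(10:32, 1)
    r <- sample(1:5, 1)
    img <- matrix(stats::rnorm(nr * nc), nr, nc)
    expect_equal(rolling_ball_background(img, r), brute_opening(img, r))
  }
})

test_that("subdivision grids: counts, window arithmetic, coverage", {
  expect_equal(nrow(subdivide(c(100, 100), c(1, 1), 0.1)), 1)
  w16 <- subdivide(c(256, 256), c(4, 4), 0.1)
  expect_equal(nrow(w16), 16)

  w <- subdivide(c(400, 400), c(4, 4), 0.1)
  expect_equal(w$r1[1] - w$r0[1] + 1, 109)        # window size
  expect_equal(w$r0[w$grid_col == 1][2] - w$r0[1], 97)  # stride
  # union covers every pixel; adjacent windows overlap >= stated fraction
  covered <- matrix(FALSE, 400, 400)
  for (i in seq_len(nrow(w))) {
    covered[w$r0[i]:w$r1[i], w$c0[i]:w$c1[i]] <- TRUE
  }
  expect_true(all(covered))
  rows <- unique(w[, c("grid_row", "r0", "r1")])
  rows <- rows[order(rows$grid_row), ]
  ov <- rows$r1[-nrow(rows)] - rows$r0[-1] + 1
  expect_true(all(ov >= floor(0.1 * 109)))
  expect_error(subdivide(c(100, 100), c(4, 4), 1), "overlap")
})

test_that("three-way classification applies the stated threshold arithmetic", {
  cfg <- triage_config(high_k = 2, low_k = 0.5)
  s <- function(stat) list(bg_mean = 100, bg_sd = 10,
                           signal_statistic = stat)
  expect_equal(classify_subregion(s(125), cfg), "signal")      # > 120
  expect_equal(classify_subregion(s(103), cfg), "no_signal")   # < 105
  expect_equal(classify_subregion(s(110), cfg), "uncertain")
  expect_error(classify_subregion(list(bg_mean = 0, bg_sd = -1,
                                       signal_statistic = 0), cfg),
               "bg_sd")
  # monotone: raising the statistic never demotes the class
  rank <- c(no_signal = 1, uncertain = 2, signal = 3)
  cls <- rank[vapply(seq(95, 130, by = 1),
                     function(v) classify_subregion(s(v), cfg),
                     character(1))]
  expect_true(all(diff(cls) >= 0))
})

test_that("SNR is the background-referenced statistic in SD units", {
  expect_equal(snr_of(445, 100, 10), 34.5)
  expect_equal(snr_of(145, 100, 10), 4.5)
  expect_equal(snr_of(100, 100, 10), 0)
  expect_error(snr_of(1, 0, 0), "bg_sd")
})

test_that("rescan selection policies nest and raising high_k never adds tiles", {
  d <- data.frame(tile_id = rep(1:4, each = 2),
                  class = c("no_signal", "no_signal",
                            "signal", "no_signal",
                            "uncertain", "no_signal",
                            "signal", "uncertain"))
  expect_equal(select_rescan_tiles(d, "any_signal"), c(2, 4))
  expect_equal(select_rescan_tiles(d, "signal_or_uncertain"), c(2, 3, 4))
  expect_true(all(select_rescan_tiles(d, "any_signal") %in%
                    select_rescan_tiles(d, "signal_or_uncertain")))
  none <- data.frame(tile_id = 1:3, class = "no_signal")
  expect_length(select_rescan_tiles(none, "signal_or_uncertain"), 0)

  # re-classify the same stats under increasing high_k
  stats_grid <- data.frame(tile_id = 1:50, bg_mean = 100, bg_sd = 10,
                           signal_statistic = seq(100, 180, length.out = 50))
  flagged <- function(k) {
    cfg <- triage_config(high_k = k)
    cls <- vapply(seq_len(nrow(stats_grid)), function(i) {
      classify_subregion(as.list(stats_grid[i, ]), cfg)
    }, character(1))
    select_rescan_tiles(data.frame(tile_id = stats_grid$tile_id,
                                   class = cls), "any_signal")
  }
  f2 <- flagged(2); f4 <- flagged(4); f6 <- flagged(6)
  expect_true(all(f4 %in% f2))
  expect_true(all(f6 %in% f4))
})

test_that("detection metrics follow their printed definitions", {
  truth <- data.frame(tile_id = 1:10,
                      has_signal = c(rep(TRUE, 7), rep(FALSE, 3)))
  perfect <- evaluate_detection(1:7, truth)
  expect_equal(perfect$fp_rate, 0)
  expect_equal(perfect$fn_rate, 0)

  m <- evaluate_detection(c(1:7, 8), truth)     # 8 rescanned, 1 empty
  expect_equal(m$fp_rate, 0.125)

  big <- data.frame(tile_id = 1:2000,
                    has_signal = c(rep(TRUE, 5), rep(FALSE, 1995)))
  m5 <- evaluate_detection(integer(0), big)     # all 5 true tiles missed
  expect_equal(m5$fn_rate, 0.0025)              # 5 out of 2000
  expect_true(is.na(m5$fp_rate))                # nothing rescanned

  # permutation invariance in tile order
  perm <- sample(nrow(truth))
  m1 <- evaluate_detection(c(2, 5, 9), truth)
  m2 <- evaluate_detection(c(2, 5, 9), truth[perm, ])
  expect_equal(m1$fp_rate, m2$fp_rate)
  expect_equal(m1$fn_rate, m2$fn_rate)
  expect_error(evaluate_detection(99, truth), "cover")
})

test_that("triage_tile produces consistent per-subregion decisions", {
  set.seed(5)
  mip <- matrix(100 + stats::rnorm(128 * 128, sd = 3), 128, 128)
  mip[40:42, 60:80] <- 400    # a bright bar in one subregion
  d <- triage_tile(mip, triage_config(), tile_id = 7L)
  expect_equal(nrow(d), 16)
  expect_true(all(d$tile_id == 7))
  bar <- d$r0 <= 42 & d$r1 >= 40 & d$c0 <= 80 & d$c1 >= 60
  expect_true(all(d$class[bar] == "signal"))
  expect_equal(max(d$snr), max(d$snr[bar]))
  # provenance recorded
  expect_true(all(c("high_k", "low_k", "rolling_ball_radius_px") %in%
                    names(d)))
})
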