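#' Triage configuration
#'
#' Parameters of the tile-triage signal-detection procedure: each tile's
#' Z-MIP is split into an overlapping grid of subregions, a rolling-ball
#' background is subtracted, and each subregion is classified three ways
#' against thresholds expressed in background standard deviations.
#'
#' @param grid Length-2 subregion grid (default 4 x 4).
#' @param subregion_overlap_fraction Overlap between adjacent subregions as
#'   a fraction of window size (default 10%).
#' @param rolling_ball_radius_px Radius of the rolling-ball (grayscale
#'   opening) structuring disc; `NULL` defaults to a quarter of the
#'   subregion width.
#' @param high_k Signal threshold in background SDs (default 2: intensity
#'   above background mean + 2 SD is classified as signal).
#' @param low_k No-signal threshold in background SDs (default 0.5);
#'   subregions between the two thresholds are `uncertain`.
#' @param statistic Subregion intensity statistic: a high percentile of the
#'   background-subtracted image (`"percentile"`, default, robust to hot
#'   pixels) or the plain `"max"`.
#' @param statistic_p Percentile used when `statistic = "percentile"`.
#' @param policy Rescan policy: `"signal_or_uncertain"` (default;
#'   conservative, stands in for manual inspection of uncertain
#'   subregions) or `"any_signal"`.
#' @return An object of class `triage_config`.
#' @export
triage_config <- function(grid = c(4L, 4L),
                          subregion_overlap_fraction = 0.1,
                          rolling_ball_radius_px = NULL,
                          high_k = 2,
                          low_k = 0.5,
                          statistic = c("percentile", "max"),
                          statistic_p = 0.999,
                          policy = c("signal_or_uncertain", "any_signal")) {
  statistic <- match.arg(statistic)
  policy <- match.arg(policy)
  if (any(grid < 1)) stop_domain("`grid` must be >= 1 x 1")
  if (low_k < 0 || high_k <= low_k) {
    stop_domain("thresholds must satisfy high_k > low_k >= 0")
  }
  if (!is.null(rolling_ball_radius_px) && rolling_ball_radius_px < 1) {
    stop_domain("`rolling_ball_radius_px` must be >= 1")
  }
  structure(list(grid = as.integer(grid),
                 subregion_overlap_fraction = subregion_overlap_fraction,
                 rolling_ball_radius_px = rolling_ball_radius_px,
                 high_k = high_k, low_k = low_k,
                 statistic = statistic, statistic_p = statistic_p,
                 policy = policy),
            class = "triage_config")
}

#' Maximum intensity projection along z
#'
#' @param stack A `tile_stack` or a 3D array `[row, col, z]`.
#' @return Numeric matrix of pixelwise maxima.
#' @export
mip_z <- function(stack) {
  a <- if (inherits(stack, "tile_stack")) stack$counts else stack
  if (length(a) == 0) stop_domain("empty stack")
  if (length(dim(a)) != 3) stop_domain("stack must be a 3D array")
  out <- matrix(a[, , 1], dim(a)[1], dim(a)[2])
  for (k in seq_len(dim(a)[3])[-1]) {
    out <- pmax(out, matrix(a[, , k], dim(a)[1], dim(a)[2]))
  }
  out
}

# row/col offsets of a disc structuring element of the given radius
disc_offsets <- function(radius) {
  r <- seq(-radius, radius)
  g <- expand.grid(dr = r, dc = r)
  g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, ]
}

# grayscale erosion/dilation by shifted pmin/pmax; pixels outside the
# image do not participate (equivalent to +Inf/-Inf padding)
gray_morph <- function(img, offsets, op = c("erode", "dilate")) {
  op <- match.arg(op)
  pad <- if (op == "erode") Inf else -Inf
  fun <- if (op == "erode") pmin else pmax
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(pad, nr, nc)
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets$dr[i]; dc <- offsets$dc[i]
    sr <- seq_len(nr) + dr; sc <- seq_len(nc) + dc
    okr <- sr >= 1 & sr <= nr; okc <- sc >= 1 & sc <= nc
    if (!any(okr) || !any(okc)) next
    shifted <- matrix(pad, nr, nc)
    shifted[okr, okc] <- img[sr[okr], sc[okc]]
    out <- fun(out, shifted)
  }
  out
}

#' Rolling-ball background of an image
#'
#' The background is the grayscale morphological opening of the image with
#' a disc structuring element of the given radius: structures narrower
#' than the disc are removed while broad plateaus and slowly varying
#' background are preserved. The opening is pixelwise less than or equal
#' to the image, so the residual `image - background` is non-negative.
#'
#' @param image Numeric matrix.
#' @param radius_px Disc radius in pixels (>= 1, below the image size).
#' @return Background matrix of the same shape.
#' @export
rolling_ball_background <- function(image, radius_px) {
  if (radius_px < 1) stop_domain("`radius_px` must be >= 1")
  if (2 * radius_px + 1 > min(dim(image))) {
    stop_domain("`radius_px` larger than the image")
  }
  off <- disc_offsets(radius_px)
  gray_morph(gray_morph(image, off, "erode"), off, "dilate")
}

#' Split an image into an overlapping grid of subregion windows
#'
#' Window size per axis is `ceil(H / (g - (g - 1) v))` for grid count `g`
#' and overlap fraction `v`; windows are placed on a regular stride with
#' the final window pinned to the image edge, so the union covers every
#' pixel and adjacent windows overlap by at least the stated fraction.
#'
#' @param dim_px Length-2 image size `(rows, cols)`, or a matrix whose
#'   dimensions are used.
#' @param grid Length-2 grid `(rows, cols)`.
#' @param overlap_fraction Overlap fraction in [0, 1).
#' @return Data frame of windows: `subregion, grid_row, grid_col,
#'   r0, r1, c0, c1` (inclusive pixel ranges).
#' @export
subdivide <- function(dim_px, grid = c(4L, 4L), overlap_fraction = 0.1) {
  if (is.matrix(dim_px)) dim_px <- dim(dim_px)
  if (overlap_fraction >= 1 || overlap_fraction < 0) {
    stop_domain("`overlap_fraction` must be in [0, 1)")
  }
  if (any(grid < 1)) stop_domain("`grid` must be >= 1 x 1")
  axis_windows <- function(n, g, v) {
    w <- min(n, ceiling(n / (g - (g - 1) * v)))
    if (g == 1) return(data.frame(lo = 1L, hi = n))
    stride <- floor((n - w) / (g - 1))
    lo <- 1L + (seq_len(g) - 1L) * stride
    lo[g] <- n - w + 1L
    data.frame(lo = as.integer(lo), hi = as.integer(lo + w - 1L))
  }
  ar <- axis_windows(dim_px[1], grid[1], overlap_fraction)
  ac <- axis_windows(dim_px[2], grid[2], overlap_fraction)
  g <- expand.grid(grid_row = seq_len(grid[1]), grid_col = seq_len(grid[2]))
  data.frame(subregion = seq_len(nrow(g)),
             grid_row = g$grid_row, grid_col = g$grid_col,
             r0 = ar$lo[g$grid_row], r1 = ar$hi[g$grid_row],
             c0 = ac$lo[g$grid_col], c1 = ac$hi[g$grid_col])
}

#' Background statistics and signal statistic of one subregion
#'
#' Background mean and SD are estimated robustly (median and scaled MAD)
#' on the raw MIP window, so they capture the slowly varying
#' autofluorescence texture and are insensitive to sparse signal pixels.
#' The signal statistic is a high percentile (or maximum) of the
#' rolling-ball residual, referenced back to the background level so the
#' classification thresholds read on the raw intensity scale.
#'
#' @param raw_window Raw MIP subregion (numeric matrix).
#' @param residual_window Background-subtracted subregion of the same
#'   shape.
#' @param config A [triage_config()].
#' @param bg_mean,bg_sd Optional externally estimated background
#'   statistics (e.g. tile-level values, which are steadier than
#'   per-window ones when the background texture varies on the window
#'   scale); estimated from `raw_window` when missing.
#' @return A list with `bg_mean, bg_sd, signal_statistic, snr`.
#' @export
subregion_stats <- function(raw_window, residual_window, config,
                            bg_mean = NULL, bg_sd = NULL) {
  bg_mean <- bg_mean %||% stats::median(raw_window)
  # mad() carries the 1.4826 normal-consistency scaling
  bg_sd <- bg_sd %||% stats::mad(raw_window)
  peak <- if (config$statistic == "max") max(residual_window) else {
    stats::quantile(residual_window, config$statistic_p, names = FALSE)
  }
  stat <- bg_mean + peak
  list(bg_mean = bg_mean, bg_sd = bg_sd, signal_statistic = stat,
       snr = if (bg_sd > 0) (stat - bg_mean) / bg_sd else NA_real_)
}

#' Three-way subregion classification
#'
#' `signal` if the statistic exceeds `bg_mean + high_k bg_sd`, `no_signal`
#' if it falls below `bg_mean + low_k bg_sd`, `uncertain` otherwise.
#'
#' @param stats A list with `bg_mean, bg_sd, signal_statistic` (as from
#'   [subregion_stats()]).
#' @param config A [triage_config()].
#' @return One of `"signal"`, `"no_signal"`, `"uncertain"`.
#' @export
classify_subregion <- function(stats, config = triage_config()) {
  if (!is.finite(stats$bg_sd) || stats$bg_sd < 0) {
    stop_domain("`bg_sd` must be a non-negative finite number")
  }
  hi <- stats$bg_mean + config$high_k * stats$bg_sd
  lo <- stats$bg_mean + config$low_k * stats$bg_sd
  if (stats$signal_statistic > hi) "signal"
  else if (stats$signal_statistic < lo) "no_signal"
  else "uncertain"
}

#' Signal-to-noise ratio of a subregion statistic
#'
#' @param signal_statistic Subregion statistic (raw intensity scale).
#' @param bg_mean,bg_sd Background mean and SD; `bg_sd` must be positive.
#' @return `(signal_statistic - bg_mean) / bg_sd`.
#' @examples
#' snr_of(445, 100, 10)  # 34.5
#' @export
snr_of <- function(signal_statistic, bg_mean, bg_sd) {
  if (!is.finite(bg_sd) || bg_sd <= 0) stop_domain("`bg_sd` must be > 0")
  (signal_statistic - bg_mean) / bg_sd
}

#' Triage one tile
#'
#' Computes the Z-MIP, subtracts the rolling-ball background, splits the
#' MIP into overlapping subregions, and classifies each.
#'
#' @param stack A `tile_stack`, 3D array, or an already-projected MIP
#'   matrix.
#' @param config A [triage_config()].
#' @param tile_id Identifier attached to the output rows.
#' @return Data frame with one row per subregion: window coordinates,
#'   `bg_mean, bg_sd, signal_statistic, snr, class`, plus the thresholds
#'   used (provenance).
#' @export
triage_tile <- function(stack, config = triage_config(), tile_id = 1L) {
  mip <- if (is.matrix(stack)) stack else mip_z(stack)
  mip <- matrix(as.numeric(mip), nrow(mip), ncol(mip))
  wins <- subdivide(dim(mip), config$grid,
                    config$subregion_overlap_fraction)
  radius <- config$rolling_ball_radius_px %||%
    max(1L, floor((wins$c1[1] - wins$c0[1] + 1) / 4))
  bg <- rolling_ball_background(mip, radius)
  resid <- mip - bg
  # the opening cannot see past the image border, so the background is
  # unreliable within one structuring-element radius of the edge; that
  # band is excluded from the statistic (the mosaic overlap means border
  # structures reappear in the neighbouring tile's interior)
  valid <- matrix(FALSE, nrow(mip), ncol(mip))
  valid[(radius + 1):(nrow(mip) - radius),
        (radius + 1):(ncol(mip) - radius)] <- TRUE
  # background level and SD estimated once per tile: the whole MIP spans
  # several texture correlation lengths, so median/MAD are stable there
  tile_bg_mean <- stats::median(mip)
  tile_bg_sd <- stats::mad(mip)
  res <- lapply(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    rw <- resid[w$r0:w$r1, w$c0:w$c1]
    vw <- valid[w$r0:w$r1, w$c0:w$c1]
    if (any(vw)) rw <- rw[vw]
    s <- subregion_stats(mip[w$r0:w$r1, w$c0:w$c1], rw, config,
                         bg_mean = tile_bg_mean, bg_sd = tile_bg_sd)
    data.frame(tile_id = tile_id, subregion = w$subregion,
               r0 = w$r0, r1 = w$r1, c0 = w$c0, c1 = w$c1,
               bg_mean = s$bg_mean, bg_sd = s$bg_sd,
               signal_statistic = s$signal_statistic, snr = s$snr,
               class = classify_subregion(s, config),
               high_k = config$high_k, low_k = config$low_k,
               rolling_ball_radius_px = radius)
  })
  do.call(rbind, res)
}

#' Select tiles for high-magnification rescan
#'
#' A tile is flagged iff any of its subregions meets the policy:
#' `any_signal` requires a `signal` class, `signal_or_uncertain` also
#' accepts `uncertain` (standing in for manual review, favoring low false
#' negatives). The `signal_or_uncertain` list always contains the
#' `any_signal` list.
#'
#' @param decisions Data frame of subregion rows with `tile_id` and
#'   `class` (as from [triage_tile()], possibly row-bound over tiles).
#' @param policy Overrides the policy recorded in `config`.
#' @return Sorted vector of flagged tile ids.
#' @export
select_rescan_tiles <- function(decisions,
                                policy = c("signal_or_uncertain",
                                           "any_signal")) {
  policy <- match.arg(policy)
  keep <- if (policy == "any_signal") decisions$class == "signal" else {
    decisions$class %in% c("signal", "uncertain")
  }
  sort(unique(decisions$tile_id[keep]))
}

#' Evaluate triage against ground truth
#'
#' The false positive rate is the fraction of rescanned tiles without true
#' signal (denominator: rescanned tiles); the false negative rate is the
#' fraction of all tiles that hold true signal but were not rescanned
#' (denominator: all tiles). The two denominators intentionally differ:
#' each matches how the corresponding rate is conventionally quoted.
#'
#' @param rescan_ids Tile ids flagged for rescan.
#' @param truth Data frame with `tile_id`, logical `has_signal`, and
#'   optional `snr` and `snr_class` columns.
#' @return A list of class `detection_metrics`: `fp_rate` (`NA` when no
#'   tile was rescanned), `fn_rate`, counts, and the SNR values of
#'   detected and missed true-signal tiles.
#' @export
evaluate_detection <- function(rescan_ids, truth) {
  stopifnot(all(c("tile_id", "has_signal") %in% names(truth)))
  if (anyDuplicated(truth$tile_id)) stop_domain("duplicate truth tiles")
  unknown <- setdiff(rescan_ids, truth$tile_id)
  if (length(unknown)) {
    stop_domain("truth does not cover tiles: ",
                paste(unknown, collapse = ", "))
  }
  rescanned <- truth$tile_id %in% rescan_ids
  fp <- rescanned & !truth$has_signal
  fn <- !rescanned & truth$has_signal
  snr <- if ("snr" %in% names(truth)) truth$snr else rep(NA_real_,
                                                         nrow(truth))
  structure(list(
    fp_rate = if (sum(rescanned) == 0) NA_real_
              else sum(fp) / sum(rescanned),
    fn_rate = sum(fn) / nrow(truth),
    n_tiles_total = nrow(truth),
    n_tiles_rescanned = sum(rescanned),
    n_false_negative = sum(fn),
    snr_detected = snr[rescanned & truth$has_signal],
    snr_missed = snr[fn],
    missed_tile_ids = truth$tile_id[fn]),
    class = "detection_metrics")
}
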