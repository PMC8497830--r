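#' Detect isolated beads in a stack
#'
#' Candidate voxels are local maxima (26-neighbourhood) above
#' `bg_mean + threshold_k * bg_sd`, with background estimated robustly
#' (median / scaled MAD) over the whole stack. Any pair of candidates
#' closer than `min_separation_px` is rejected entirely -- both beads are
#' dropped, since overlapping profiles would bias the fit. Surviving
#' centers are refined by an intensity-weighted centroid in a small
#' window.
#'
#' @param stack A `tile_stack` or 3D numeric array `[row, col, z]`.
#' @param min_separation_px Minimum pairwise separation in voxels.
#' @param threshold_k Detection threshold in background SDs.
#' @param centroid_halfwidth Half-size of the centroid refinement window.
#' @return Data frame of centers `row, col, z` (fractional voxel indices);
#'   possibly empty.
#' @export
detect_beads <- function(stack, min_separation_px = 8, threshold_k = 8,
                         centroid_halfwidth = 3) {
  a <- if (inherits(stack, "tile_stack")) stack$counts else stack
  if (length(a) == 0) stop_domain("empty stack")
  a <- array(as.numeric(a), dim(a))
  bg_mean <- stats::median(a)
  bg_sd <- stats::mad(a)
  if (bg_sd == 0) bg_sd <- stats::sd(a)
  thr <- bg_mean + threshold_k * max(bg_sd, .Machine$double.eps)
  cand <- which(a > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(data.frame(row = numeric(0), col = numeric(0), z = numeric(0)))
  }
  d <- dim(a)
  is_peak <- vapply(seq_len(nrow(cand)), function(i) {
    p <- cand[i, ]
    w <- a[max(1, p[1] - 1):min(d[1], p[1] + 1),
           max(1, p[2] - 1):min(d[2], p[2] + 1),
           max(1, p[3] - 1):min(d[3], p[3] + 1)]
    a[p[1], p[2], p[3]] >= max(w)
  }, logical(1))
  peaks <- cand[is_peak, , drop = FALSE]
  # collapse plateau peaks closer than 2 voxels into one
  if (nrow(peaks) > 1) {
    keep <- rep(TRUE, nrow(peaks))
    for (i in seq_len(nrow(peaks) - 1)) {
      if (!keep[i]) next
      for (j in (i + 1):nrow(peaks)) {
        if (keep[j] && sqrt(sum((peaks[i, ] - peaks[j, ])^2)) < 2) {
          keep[j] <- FALSE
        }
      }
    }
    peaks <- peaks[keep, , drop = FALSE]
  }
  # reject both members of any pair closer than min_separation
  if (nrow(peaks) > 1) {
    dd <- as.matrix(stats::dist(peaks))
    diag(dd) <- Inf
    peaks <- peaks[apply(dd, 1, min) >= min_separation_px, , drop = FALSE]
  }
  if (nrow(peaks) == 0) {
    return(data.frame(row = numeric(0), col = numeric(0), z = numeric(0)))
  }
  h <- centroid_halfwidth
  centers <- t(apply(peaks, 1, function(p) {
    ri <- max(1, p[1] - h):min(d[1], p[1] + h)
    ci <- max(1, p[2] - h):min(d[2], p[2] + h)
    zi <- max(1, p[3] - h):min(d[3], p[3] + h)
    w <- pmax(a[ri, ci, zi, drop = FALSE] - bg_mean, 0)
    s <- sum(w)
    if (s == 0) return(as.numeric(p))
    c(sum(slice.index(w, 1) * w) / s + ri[1] - 1,
      sum(slice.index(w, 2) * w) / s + ci[1] - 1,
      sum(slice.index(w, 3) * w) / s + zi[1] - 1)
  }))
  data.frame(row = centers[, 1], col = centers[, 2], z = centers[, 3])
}

#' Fit a Gaussian to a 1D intensity profile and report the FWHM
#'
#' Least-squares fit of `A exp(-(x - c)^2 / (2 sigma^2)) + b` (the
#' baseline absorbs the camera offset); `FWHM = 2 sqrt(2 ln 2) sigma`.
#' Starting values come from the discrete peak and half-maximum crossing
#' width.
#'
#' @param profile Numeric vector of at least 5 samples with a single mode.
#' @param spacing Sample spacing (um per sample, or px).
#' @return A list with `fwhm` (in `spacing` units), `r2`, `sigma`,
#'   `center`, `amplitude`, `baseline`. A flat or non-convergent profile
#'   is an error reporting the residual state.
#' @export
fit_fwhm <- function(profile, spacing = 1) {
  y <- as.numeric(profile)
  if (length(y) < 5) stop_domain("need at least 5 samples")
  x <- (seq_along(y) - 1) * spacing
  b0 <- min(y); a0 <- max(y) - b0
  if (a0 <= 0 || stats::sd(y) == 0) stop_domain("flat profile; nothing to fit")
  c0 <- x[which.max(y)]
  above <- which(y - b0 >= a0 / 2)
  s0 <- max((x[max(above)] - x[min(above)] + spacing) / FWHM_PER_SIGMA,
            spacing / 4)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - cc)^2 / (2 * sig^2)) + b,
      start = list(A = a0, cc = c0, sig = s0, b = b0),
      lower = c(0, min(x) - diff(range(x)), spacing / 100, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop_domain("Gaussian fit did not converge: ", conditionMessage(fit),
                " (profile range ", signif(min(y), 4), "..",
                signif(max(y), 4), ")")
  }
  p <- stats::coef(fit)
  resid <- y - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(fwhm = sigma_to_fwhm(unname(p["sig"])), r2 = r2,
       sigma = unname(p["sig"]), center = unname(p["cc"]),
       amplitude = unname(p["A"]), baseline = unname(p["b"]))
}

#' Characterize the PSF from a bead stack
#'
#' Detects beads, crops a window around each, projects the
#' background-subtracted crop onto each axis (mean projection, which
#' preserves the Gaussian width along the projected axis), fits the
#' Gaussian FWHM per axis, and aggregates across beads by the median.
#'
#' @param stack A `tile_stack` or 3D array `[row, col, z]`.
#' @param voxel_size_um Length-3 voxel size `(row, col, z)` in um.
#' @param crop_halfwidth_px Half-size of the per-bead crop, per axis
#'   (recycled).
#' @param min_separation_px,threshold_k Passed to [detect_beads()].
#' @return A list of class `psf_estimate`: `fwhm_x_um, fwhm_y_um,
#'   fwhm_z_um` (median over beads), `fit_r2` per axis, `n_beads`, and a
#'   per-bead data frame. Zero detected beads is an error.
#' @export
characterize_psf <- function(stack, voxel_size_um,
                             crop_halfwidth_px = c(6, 6, 6),
                             min_separation_px = 8, threshold_k = 8) {
  a <- if (inherits(stack, "tile_stack")) stack$counts else stack
  a <- array(as.numeric(a), dim(a))
  beads <- detect_beads(a, min_separation_px, threshold_k)
  if (nrow(beads) == 0) stop_domain("no beads detected")
  d <- dim(a)
  h <- rep(crop_halfwidth_px, length.out = 3)
  per_bead <- lapply(seq_len(nrow(beads)), function(i) {
    p <- round(as.numeric(beads[i, ]))
    ri <- max(1, p[1] - h[1]):min(d[1], p[1] + h[1])
    ci <- max(1, p[2] - h[2]):min(d[2], p[2] + h[2])
    zi <- max(1, p[3] - h[3]):min(d[3], p[3] + h[3])
    crop <- a[ri, ci, zi, drop = FALSE]
    prof <- list(y = apply(crop, 1, mean), x = apply(crop, 2, mean),
                 z = apply(crop, 3, mean))
    fit1 <- function(v, sp) tryCatch(fit_fwhm(v, sp),
                                     error = function(e) NULL)
    fy <- fit1(prof$y, voxel_size_um[1])
    fx <- fit1(prof$x, voxel_size_um[2])
    fz <- fit1(prof$z, voxel_size_um[3])
    if (is.null(fy) || is.null(fx) || is.null(fz)) return(NULL)
    data.frame(row = beads$row[i], col = beads$col[i], z = beads$z[i],
               fwhm_y_um = fy$fwhm, fwhm_x_um = fx$fwhm,
               fwhm_z_um = fz$fwhm,
               r2_y = fy$r2, r2_x = fx$r2, r2_z = fz$r2)
  })
  per_bead <- do.call(rbind, per_bead)
  if (is.null(per_bead) || nrow(per_bead) == 0) {
    stop_domain("no bead profile could be fitted")
  }
  structure(list(
    fwhm_x_um = stats::median(per_bead$fwhm_x_um),
    fwhm_y_um = stats::median(per_bead$fwhm_y_um),
    fwhm_z_um = stats::median(per_bead$fwhm_z_um),
    fit_r2 = c(x = stats::median(per_bead$r2_x),
               y = stats::median(per_bead$r2_y),
               z = stats::median(per_bead$r2_z)),
    n_beads = nrow(per_bead),
    per_bead = per_bead),
    class = "psf_estimate")
}

#' @export
print.psf_estimate <- function(x, ...) {
  cat(sprintf(
    "<psf_estimate> FWHM %.3g x %.3g x %.3g um (x, y, z); %d beads\n",
    x$fwhm_x_um, x$fwhm_y_um, x$fwhm_z_um, x$n_beads))
  invisible(x)
}

#' Render synthetic bead images with a known generative PSF
#'
#' Places Gaussian spots of the stated FWHM triple at given positions on a
#' pixel grid -- the ground-truth image for PSF parameter-recovery tests
#' and the bead-grid phantom used to compare illumination modes.
#'
#' @param positions Data frame or matrix with columns `x, y, z` in um.
#' @param fwhm_um Length-3 generative FWHM `(x, y, z)` in um.
#' @param pixel_size_um Length-3 sampling `(row/y, col/x, z)` in um.
#' @param shape_px Length-3 output array shape `(rows, cols, planes)`.
#' @param amplitude Peak amplitude per bead.
#' @param baseline Constant baseline added everywhere.
#' @param noise_sd Gaussian noise SD (0 = noiseless).
#' @param seed Seed used when `noise_sd > 0`.
#' @return 3D array `[row, col, z]`.
#' @export
render_beads <- function(positions, fwhm_um, pixel_size_um, shape_px,
                         amplitude = 1000, baseline = 100, noise_sd = 0,
                         seed = 1L) {
  pos <- as.data.frame(positions)
  sig <- fwhm_to_sigma(rep(fwhm_um, length.out = 3))
  vox <- rep(pixel_size_um, length.out = 3)
  out <- array(baseline, shape_px)
  yc <- (seq_len(shape_px[1]) - 0.5) * vox[1]
  xc <- (seq_len(shape_px[2]) - 0.5) * vox[2]
  zc <- (seq_len(shape_px[3]) - 0.5) * vox[3]
  for (i in seq_len(nrow(pos))) {
    gy <- exp(-(yc - pos$y[i])^2 / (2 * sig[2]^2))
    gx <- exp(-(xc - pos$x[i])^2 / (2 * sig[1]^2))
    gz <- exp(-(zc - pos$z[i])^2 / (2 * sig[3]^2))
    out <- out + amplitude * outer(outer(gy, gx), gz)
  }
  if (noise_sd > 0) {
    out <- withr::with_seed(seed, {
      out + array(stats::rnorm(length(out), 0, noise_sd), dim(out))
    })
  }
  out
}
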