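# Internal helpers shared across modules.

# Gaussian FWHM = 2 sqrt(2 ln 2) sigma
FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

fwhm_to_sigma <- function(fwhm) fwhm / FWHM_PER_SIGMA
sigma_to_fwhm <- function(sigma) sigma * FWHM_PER_SIGMA

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(sprintf("`%s` must be a positive finite number", name))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_domain(sprintf("`%s` must be a non-negative finite number", name))
  }
  invisible(x)
}

#' Derive a reproducible sub-seed for a named module stream
#'
#' A single pipeline seed is expanded into independent per-module seeds so
#' that, e.g., phantom generation and camera noise do not share a random
#' stream and module-level results do not depend on pipeline stage order.
#'
#' @param seed Integer master seed.
#' @param stream Character name of the consuming module/stage.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(paste0(stream, ":", format(seed)))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_substream <- function(seed, stream, expr) {
  withr::with_seed(substream_seed(seed, stream), expr)
}

# Separable Gaussian blur of a matrix, sigma in pixels per axis.
# Kernel is truncated at 4 sigma and renormalized; borders use
# renormalized partial kernels (no energy loss at edges).
gauss_blur_2d <- function(img, sigma_row, sigma_col = sigma_row) {
  blur_axis <- function(m, sigma, along_rows) {
    if (sigma <= 0) return(m)
    r <- max(1L, ceiling(4 * sigma))
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    n <- if (along_rows) nrow(m) else ncol(m)
    if (2 * r + 1 > 2 * n) {
      r <- n - 1L
      k <- stats::dnorm(seq(-r, r), sd = sigma)
    }
    out <- matrix(0, nrow(m), ncol(m))
    wsum <- if (along_rows) matrix(0, nrow(m), ncol(m)) else out
    for (d in seq(-r, r)) {
      w <- k[d + r + 1]
      if (along_rows) {
        src <- seq_len(nrow(m)) + d
        ok <- src >= 1 & src <= nrow(m)
        out[ok, ] <- out[ok, ] + w * m[src[ok], ]
        wsum[ok, ] <- wsum[ok, ] + w
      } else {
        src <- seq_len(ncol(m)) + d
        ok <- src >= 1 & src <= ncol(m)
        out[, ok] <- out[, ok] + w * m[, src[ok]]
        wsum[, ok] <- wsum[, ok] + w
      }
    }
    out / wsum
  }
  img <- blur_axis(img, sigma_row, TRUE)
  blur_axis(img, sigma_col, FALSE)
}

# Bilinear interpolation of matrix `m` at fractional (row, col) coordinates.
# Coordinates outside the grid are clamped to the border.
bilinear_sample <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); r1 <- r0 + 1
  c0 <- pmin(floor(cols), nc - 1L); c1 <- c0 + 1
  if (nr == 1L) { r0 <- r1 <- rep(1, length(rows)) }
  if (nc == 1L) { c0 <- c1 <- rep(1, length(cols)) }
  fr <- rows - r0; fc <- cols - c0
  grid_fr <- matrix(fr, length(rows), length(cols))
  grid_fc <- matrix(fc, length(rows), length(cols), byrow = TRUE)
  idx <- function(r, c) m[cbind(rep(r, times = length(c)),
                                rep(c, each = length(r)))]
  v00 <- matrix(idx(r0, c0), length(rows), length(cols))
  v10 <- matrix(idx(r1, c0), length(rows), length(cols))
  v01 <- matrix(idx(r0, c1), length(rows), length(cols))
  v11 <- matrix(idx(r1, c1), length(rows), length(cols))
  v00 * (1 - grid_fr) * (1 - grid_fc) + v10 * grid_fr * (1 - grid_fc) +
    v01 * (1 - grid_fr) * grid_fc + v11 * grid_fr * grid_fc
}
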