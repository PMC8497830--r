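#' Estimate the rigid shift between two overlapping crops
#'
#' Phase correlation of the two overlap crops: the cross-power spectrum is
#' normalized and inverse-transformed, and the correlation peak gives the
#' integer shift of `b` relative to `a` (optionally refined to sub-pixel
#' precision by parabolic interpolation around the peak). The score is the
#' Pearson correlation of the shifted overlap.
#'
#' @param a,b Numeric matrices of identical shape (the nominal overlap
#'   crops of the two tiles), at least 16 px per axis.
#' @param subpixel Refine the peak by parabolic interpolation (off by
#'   default; tile shifts are integer-scale).
#' @return A list of class `tile_offset` with `shift` (`(drow, dcol)` such
#'   that `b` shifted by `shift` aligns with `a`) and `score` in [-1, 1].
#'   Degenerate (constant) crops yield a zero shift with score 0 and a
#'   warning.
#' @export
estimate_offset <- function(a, b, subpixel = FALSE) {
  if (!all(dim(a) == dim(b))) stop_domain("crops must have equal shape")
  if (any(dim(a) < 16)) stop_domain("overlap region must be >= 16 px per axis")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant overlap region; returning null offset")
    return(structure(list(shift = c(0, 0), score = 0),
                     class = "tile_offset"))
  }
  fa <- stats::fft(a - mean(a))
  fb <- stats::fft(b - mean(b))
  cross <- fa * Conj(fb)
  denom <- Mod(cross)
  denom[denom < .Machine$double.eps] <- .Machine$double.eps
  corr <- Re(stats::fft(cross / denom, inverse = TRUE))
  peak <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  raw <- c(wrap(peak[1], nrow(a)), wrap(peak[2], ncol(a)))
  if (subpixel) {
    refine <- function(along_row) {
      at <- function(d) {
        r <- ((peak[1] - 1 + if (along_row) d else 0) %% nrow(a)) + 1
        c <- ((peak[2] - 1 + if (along_row) 0 else d) %% ncol(a)) + 1
        corr[r, c]
      }
      y0 <- at(-1); y1 <- at(0); y2 <- at(1)
      den <- y0 - 2 * y1 + y2
      if (den >= 0) 0 else 0.5 * (y0 - y2) / den
    }
    raw <- raw + c(refine(TRUE), refine(FALSE))
  }
  # the peak gives the displacement of a relative to b; report the
  # displacement of b relative to a (b = translate(a, shift))
  shift <- -raw
  # score: correlation of the aligned overlap, pairing a[i, j] with
  # b[i + s1, j + s2] (integer part of the shift)
  s <- round(shift)
  rs_a <- max(1, 1 - s[1]):min(nrow(a), nrow(a) - s[1])
  cs_a <- max(1, 1 - s[2]):min(ncol(a), ncol(a) - s[2])
  rs_b <- rs_a + s[1]; cs_b <- cs_a + s[2]
  score <- if (length(rs_a) > 2 && length(cs_a) > 2) {
    suppressWarnings(stats::cor(as.vector(a[rs_a, cs_a]),
                                as.vector(b[rs_b, cs_b])))
  } else 0
  if (!is.finite(score)) score <- 0
  structure(list(shift = unname(shift), score = score),
            class = "tile_offset")
}

#' Propagate pairwise offsets to global tile positions
#'
#' Pairwise shifts are composed over a spanning tree (breadth-first from
#' the reference tile). Redundant pairwise measurements are checked for
#' cycle consistency; a cycle whose closure error exceeds `tol` is an
#' error.
#'
#' @param pairs Data frame with columns `from, to, drow, dcol`: tile `to`
#'   is displaced by `(drow, dcol)` relative to tile `from`.
#' @param reference Tile id fixed at the origin (defaults to the first
#'   `from`).
#' @param tol Cycle-closure tolerance in pixels.
#' @return Data frame `tile_id, row_px, col_px` of global positions.
#' @export
solve_offsets <- function(pairs, reference = NULL, tol = 1) {
  ids <- unique(c(pairs$from, pairs$to))
  reference <- reference %||% ids[1]
  pos <- list()
  pos[[as.character(reference)]] <- c(0, 0)
  queue <- reference
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    p <- pos[[as.character(cur)]]
    hits <- which(pairs$from == cur | pairs$to == cur)
    for (i in hits) {
      fwd <- pairs$from[i] == cur
      other <- if (fwd) pairs$to[i] else pairs$from[i]
      d <- c(pairs$drow[i], pairs$dcol[i]) * if (fwd) 1 else -1
      cand <- p + d
      key <- as.character(other)
      if (is.null(pos[[key]])) {
        pos[[key]] <- cand
        queue <- c(queue, other)
      } else if (max(abs(pos[[key]] - cand)) > tol) {
        stop_domain(sprintf(
          "inconsistent offset cycle at tiles %s-%s: closure error %.2f px",
          cur, other, max(abs(pos[[key]] - cand))))
      }
    }
  }
  solved <- names(pos)
  data.frame(tile_id = if (is.numeric(ids)) as.numeric(solved) else solved,
             row_px = vapply(pos, `[`, numeric(1), 1),
             col_px = vapply(pos, `[`, numeric(1), 2),
             row.names = NULL)
}

#' Fuse tiles into a single volume with linear blending
#'
#' Tiles (2D matrices or 3D arrays) are placed at their integer offsets;
#' where tiles overlap, voxels are combined with weights proportional to
#' each tile's distance from its own border (a separable linear ramp),
#' normalized to sum to 1. Voxels covered by a single tile are copied
#' verbatim.
#'
#' @param tiles List of arrays with identical number of dimensions.
#' @param offsets Matrix (n x ndim) of integer offsets of each tile's
#'   first voxel, or the data frame from [solve_offsets()] (2D).
#' @return The fused array.
#' @export
fuse_tiles <- function(tiles, offsets) {
  if (is.data.frame(offsets)) {
    offsets <- as.matrix(offsets[, c("row_px", "col_px")])
  }
  offsets <- round(offsets)
  offsets <- sweep(offsets, 2, apply(offsets, 2, min))  # shift to origin
  nd <- length(dim(tiles[[1]]) %||% c(length(tiles[[1]])))
  dims <- vapply(tiles, function(t) dim(t) %||% length(t), numeric(nd))
  out_dim <- vapply(seq_len(nd), function(a) {
    max(offsets[, a] + dims[a, ])
  }, numeric(1))
  acc <- array(0, out_dim)
  wacc <- array(0, out_dim)
  ramp <- function(n) pmin(seq_len(n), rev(seq_len(n)))
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    d <- dim(t) %||% length(t)
    w <- Reduce(function(acc, a) {
      sweep(acc, a, ramp(d[a]), "*")
    }, seq_len(nd), array(1, d))
    idx <- lapply(seq_len(nd), function(a) offsets[i, a] + seq_len(d[a]))
    acc_idx <- do.call(`[`, c(list(acc), idx))
    w_idx <- do.call(`[`, c(list(wacc), idx))
    acc <- do.call(`[<-`, c(list(acc), idx, list(acc_idx + w * t)))
    wacc <- do.call(`[<-`, c(list(wacc), idx, list(w_idx + w)))
  }
  out <- acc
  nz <- wacc > 0
  out[nz] <- acc[nz] / wacc[nz]
  out
}

#' Block-mean downsampling to a coarser voxel grid
#'
#' Groups source voxels into blocks by mapping each source index to a
#' target bin (`floor((i - 1) * source / target)`), and averages within
#' blocks; edge blocks average over the voxels available. For integer
#' block ratios this is exact block-mean pooling and preserves the global
#' mean.
#'
#' @param vol 2D or 3D numeric array.
#' @param source_voxel,target_voxel Voxel sizes per axis (target >= source
#'   per axis), recycled to the array dimensionality.
#' @return The pooled array.
#' @export
downsample <- function(vol, source_voxel, target_voxel) {
  nd <- length(dim(vol))
  source_voxel <- rep(source_voxel, length.out = nd)
  target_voxel <- rep(target_voxel, length.out = nd)
  if (any(target_voxel < source_voxel)) {
    stop_domain("target voxel must be >= source voxel on every axis")
  }
  out <- vol
  for (a in seq_len(nd)) {
    n <- dim(out)[a]
    bins <- floor((seq_len(n) - 1) * source_voxel[a] / target_voxel[a]) + 1
    nb <- max(bins)
    if (nb == n) next  # identity on this axis
    pool <- matrix(0, nb, n)
    pool[cbind(bins, seq_len(n))] <- 1
    pool <- pool / rowSums(pool)
    # bring axis `a` to the front, contract, and restore order
    perm <- c(a, setdiff(seq_len(nd), a))
    front <- aperm(out, perm)
    fd <- dim(front)
    pooled <- pool %*% matrix(front, fd[1], prod(fd[-1]))
    dim(pooled) <- c(nb, fd[-1])
    out <- aperm(pooled, order(perm))
  }
  out
}

#' Nearest-neighbour upsampling (inverse companion of [downsample()])
#'
#' @param vol 2D or 3D numeric array.
#' @param factor Integer repetition factor per axis.
#' @return The upsampled array.
#' @export
upsample_nearest <- function(vol, factor) {
  nd <- length(dim(vol))
  factor <- rep(factor, length.out = nd)
  idx <- lapply(seq_len(nd), function(a) rep(seq_len(dim(vol)[a]),
                                             each = factor[a]))
  do.call(`[`, c(list(vol), idx))
}

#' Symmetrized mean nearest-neighbour distance between boundary point sets
#'
#' `0.5 (mean over a of NN in b + mean over b of NN in a)`, the symmetric
#' average surface distance used to compare an imaged anatomical boundary
#' with its reference counterpart.
#'
#' @param a,b Numeric matrices (n x d) of boundary sample points (um).
#' @return Mean distance in the coordinate units.
#' @export
boundary_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop_domain("empty boundary set")
  nn_mean <- function(p, q) {
    qs <- rowSums(q^2)
    mean(vapply(seq_len(nrow(p)), function(i) {
      sqrt(max(0, min(qs - 2 * as.vector(q %*% p[i, ]) + sum(p[i, ]^2))))
    }, numeric(1)))
  }
  0.5 * (nn_mean(a, b) + nn_mean(b, a))
}
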