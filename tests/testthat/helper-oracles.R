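# Independent oracles used across tests. These deliberately use naive
# per-pixel algorithms, not the package's vectorized implementations.

# Brute-force grayscale opening with a disc: for every pixel, erosion is
# the min over in-image disc neighbours, then dilation the max of the
# eroded image over the same neighbourhood.
brute_opening <- function(img, radius) {
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2 + 1e-9, ]
  nr <- nrow(img); nc <- ncol(img)
  pass <- function(m, fun) {
    out <- matrix(0, nr, nc)
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        rr <- r + off$dr; cc <- c + off$dc
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        out[r, c] <- fun(m[cbind(rr[ok], cc[ok])])
      }
    }
    out
  }
  pass(pass(img, min), max)
}

# A hand-built straight two-node axon as an SWC tree
straight_axon_tree <- function(p0, p1, radius = 3, snr_class = "bright") {
  tr <- data.frame(id = 1:2, type = c(1L, 2L),
                   x = c(p0[1], p1[1]), y = c(p0[2], p1[2]),
                   z = c(p0[3], p1[3]),
                   radius = radius, parent = c(-1L, 1L))
  class(tr) <- c("neuron_tree", "data.frame")
  attr(tr, "snr_class") <- snr_class
  tr
}

# Minimal phantom config for fast tests
small_phantom_config <- function(...) {
  phantom_config(extent_um = c(120, 120, 24), voxel_size_um = 2,
                 n_neurons = 2, max_nodes = 40, seed = 42,
                 background_texture_sd = 0, ...)
}
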