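#' Configuration of the synthetic brain phantom
#'
#' Parameters of the seeded phantom generator. The phantom emulates a
#' desk-scale block of cleared tissue holding a handful of sparsely labeled
#' neurons with branching axons: a small fraction of neurons is weakly
#' labeled ("dim" class), the rest are bright, mirroring the non-uniform
#' brightness of viral labeling.
#'
#' Intensity levels are expected photon counts per voxel per default
#' exposure at unit relative brightness; the acquisition simulator scales
#' them by the optical brightness law and exposure. `bright_level` and
#' `dim_level` were calibrated once by running the default acquisition and
#' triage settings so that measured subregion SNR lands near 34.5 (bright)
#' and 4.5 (dim); they are ordinary parameters and can be changed freely.
#'
#' @param extent_um Numeric length-3 `(x, y, z)` extent of the volume in um.
#' @param voxel_size_um Isotropic voxel size in um.
#' @param n_neurons Number of neurons to generate.
#' @param branch_prob Per-step probability that a growing neurite bifurcates.
#' @param step_um Step length of the neurite random walk in um.
#' @param tortuosity Direction persistence in [0, 1); 0 is a straight line,
#'   larger values wiggle more.
#' @param soma_radius_um Soma radius in um.
#' @param axon_radius_um Axon radius in um (sets the Gaussian cross-section
#'   sigma at rasterization and the truth-mask distance).
#' @param max_nodes Safety cap on nodes per tree.
#' @param bright_level,dim_level Peak axon intensity of the two SNR classes.
#' @param dim_fraction Fraction of neurons assigned to the dim class.
#' @param background_level Uniform background intensity added everywhere.
#' @param background_texture_sd SD of the smooth background texture field
#'   (slowly varying autofluorescence); 0 disables it.
#' @param texture_scale_um Correlation length of the background texture.
#' @param vessel_density Number of autofluorescent vessel tubes per mm^3
#'   (0 disables vessels; off by default).
#' @param vessel_level,vessel_radius_um Vessel intensity and radius.
#' @param seed Mandatory integer seed; all generation is a pure function of
#'   (config, seed).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(extent_um = c(1000, 1000, 40),
                           voxel_size_um = 2,
                           n_neurons = 6,
                           branch_prob = 0.04,
                           step_um = 8,
                           tortuosity = 0.25,
                           soma_radius_um = 8,
                           axon_radius_um = 2,
                           max_nodes = 150,
                           bright_level = 28000,
                           dim_level = 3650,
                           dim_fraction = 1/3,
                           background_level = 20,
                           background_texture_sd = 900,
                           texture_scale_um = 120,
                           vessel_density = 0,
                           vessel_level = 200,
                           vessel_radius_um = 6,
                           seed = 1L) {
  if (length(extent_um) != 3 || any(extent_um <= 0)) {
    stop_domain("`extent_um` must be three positive lengths")
  }
  check_positive(voxel_size_um, "voxel_size_um")
  check_nonnegative(n_neurons, "n_neurons")
  check_nonnegative(branch_prob, "branch_prob")
  check_positive(step_um, "step_um")
  check_nonnegative(tortuosity, "tortuosity")
  check_nonnegative(background_level, "background_level")
  check_nonnegative(background_texture_sd, "background_texture_sd")
  check_nonnegative(vessel_density, "vessel_density")
  if (is.null(seed)) stop_domain("`seed` is mandatory")
  structure(as.list(environment()), class = "phantom_config")
}

new_neuron_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "type", "x", "y", "z", "radius", "parent") %in%
                  names(nodes)))
  structure(nodes, class = c("neuron_tree", "data.frame"))
}

#' Validate a neuron tree (SWC node table)
#'
#' Checks the structural invariants of an SWC morphology: unique ids,
#' exactly one root (`parent == -1`), every parent id present, and a single
#' connected component with no cycles.
#'
#' @param tree A data frame with SWC columns
#'   `id, type, x, y, z, radius, parent`.
#' @return The tree, invisibly; errors describe the violated invariant.
#' @export
validate_tree <- function(tree) {
  if (anyDuplicated(tree$id)) stop_domain("duplicate node ids")
  roots <- tree$id[tree$parent == -1]
  if (length(roots) != 1) {
    stop_domain(sprintf("tree must have exactly one root, found %d",
                        length(roots)))
  }
  known <- tree$parent %in% c(-1, tree$id)
  if (!all(known)) {
    stop_domain("parent ids missing from node table: ",
                paste(tree$parent[!known], collapse = ", "))
  }
  # walk to root from every node; a cycle or disconnection shows up as a
  # walk longer than the node count
  parent_of <- stats::setNames(tree$parent, tree$id)
  for (id in tree$id) {
    cur <- id; steps <- 0
    while (cur != -1) {
      cur <- parent_of[[as.character(cur)]]
      steps <- steps + 1
      if (steps > nrow(tree)) stop_domain("cycle detected at node ", id)
    }
  }
  invisible(tree)
}

#' Generate sparsely labeled neurons with branching axons
#'
#' Grows each neuron as a discrete-step random walk from a soma placed
#' uniformly in the volume. At every step the growth cone advances
#' `step_um` along a direction that is the previous direction perturbed by
#' isotropic noise of magnitude `tortuosity`, and bifurcates with
#' probability `branch_prob`. Walks reflect off the volume boundary so all
#' nodes stay in bounds.
#'
#' @param config A [phantom_config()].
#' @return A list of `neuron_tree` objects, each with an `snr_class`
#'   attribute of `"bright"` or `"dim"`.
#' @export
generate_neurons <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$n_neurons == 0) return(list())
  with_substream(config$seed, "neurons", {
    lapply(seq_len(config$n_neurons), function(i) {
      tr <- grow_tree(config)
      attr(tr, "snr_class") <-
        if (stats::runif(1) < config$dim_fraction) "dim" else "bright"
      tr
    })
  })
}

# random unit vector
runit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

grow_tree <- function(config) {
  ext <- config$extent_um
  # soma away from the faces so the blob fits
  m <- pmin(config$soma_radius_um * 2, ext / 4)
  soma <- m + stats::runif(3) * (ext - 2 * m)
  nodes <- list(list(id = 1L, type = 1L, x = soma[1], y = soma[2],
                     z = soma[3], radius = config$soma_radius_um,
                     parent = -1L))
  # active growth cones: position, direction, parent node id
  cones <- list(list(pos = soma, dir = runit3(), parent = 1L))
  next_id <- 2L
  while (length(cones) > 0 && next_id <= config$max_nodes) {
    cone <- cones[[1]]; cones <- cones[-1]
    n_steps <- 5L + stats::rgeom(1, 0.05)
    for (s in seq_len(n_steps)) {
      if (next_id > config$max_nodes) break
      d <- cone$dir + config$tortuosity * stats::rnorm(3)
      d <- d / sqrt(sum(d^2))
      pos <- cone$pos + config$step_um * d
      # reflect at the faces
      for (a in 1:3) {
        if (pos[a] < 0) { pos[a] <- -pos[a]; d[a] <- -d[a] }
        if (pos[a] > ext[a]) { pos[a] <- 2 * ext[a] - pos[a]; d[a] <- -d[a] }
      }
      nodes[[next_id]] <- list(id = next_id, type = 2L, x = pos[1],
                               y = pos[2], z = pos[3],
                               radius = config$axon_radius_um,
                               parent = cone$parent)
      cone <- list(pos = pos, dir = d, parent = next_id)
      next_id <- next_id + 1L
      if (stats::runif(1) < config$branch_prob) {
        bd <- cone$dir + 0.8 * stats::rnorm(3)
        cones <- c(cones, list(list(pos = pos, dir = bd / sqrt(sum(bd^2)),
                                    parent = cone$parent)))
      }
    }
  }
  df <- do.call(rbind, lapply(nodes, as.data.frame))
  validate_tree(new_neuron_tree(df))
}

#' Summary statistics of a neuron tree
#'
#' @param tree A `neuron_tree` (validated SWC node table).
#' @return A list with `total_length_um` (sum of parent-child Euclidean
#'   distances), `n_branch_points` (nodes with >= 2 children) and
#'   `n_terminals` (nodes with no children; a bare root counts as one
#'   terminal).
#' @export
swc_stats <- function(tree) {
  validate_tree(tree)
  idx <- match(tree$parent, tree$id)
  has_parent <- !is.na(idx)
  seg <- cbind(tree$x - tree$x[idx], tree$y - tree$y[idx],
               tree$z - tree$z[idx])[has_parent, , drop = FALSE]
  total <- if (nrow(seg)) sum(sqrt(rowSums(seg^2))) else 0
  n_children <- table(factor(tree$parent[has_parent], levels = tree$id))
  list(total_length_um = total,
       n_branch_points = sum(n_children >= 2),
       n_terminals = sum(n_children == 0))
}

#' Read and write SWC morphology files
#'
#' Standard 7-column SWC text format (`id type x y z radius parent`,
#' `#`-prefixed comments).
#'
#' @param tree A `neuron_tree`.
#' @param path File path.
#' @return `read_swc` returns a validated `neuron_tree`; `write_swc`
#'   returns `path` invisibly.
#' @export
write_swc <- function(tree, path) {
  validate_tree(tree)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# SWC morphology written by mlsfm", con)
  writeLines("# id type x y z radius parent", con)
  apply(tree, 1, function(r) {
    writeLines(paste(format(r[["id"]], trim = TRUE),
                     format(r[["type"]], trim = TRUE),
                     format(r[["x"]], trim = TRUE, digits = 10),
                     format(r[["y"]], trim = TRUE, digits = 10),
                     format(r[["z"]], trim = TRUE, digits = 10),
                     format(r[["radius"]], trim = TRUE, digits = 10),
                     format(r[["parent"]], trim = TRUE)), con)
  })
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop_domain("SWC file ", path, " holds no nodes")
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad)) {
    stop_domain(sprintf("malformed SWC line %d in %s", bad[1], path))
  }
  m <- do.call(rbind, lapply(fields, as.numeric))
  df <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                   x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                   parent = as.integer(m[, 7]))
  validate_tree(new_neuron_tree(df))
}

new_phantom_volume <- function(intensity, voxel_size_um, truth = list(),
                               meta = list()) {
  stopifnot(length(dim(intensity)) == 3)
  if (any(intensity < 0)) stop_domain("phantom intensity must be >= 0")
  structure(list(intensity = intensity,
                 voxel_size_um = voxel_size_um,
                 truth = truth, meta = meta),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<phantom_volume> %d x %d x %d voxels at %s um (y, x, z)\n",
    d[1], d[2], d[3], paste(signif(x$voxel_size_um, 3), collapse = " x ")))
  cat(sprintf("  intensity range [%.3g, %.3g]; truth layers: %s\n",
              min(x$intensity), max(x$intensity),
              if (length(x$truth)) paste(names(x$truth), collapse = ", ")
              else "none"))
  invisible(x)
}

# Sample points along the polyline segments of a tree: one row per splat
# point with Gaussian sigma and normalized amplitude such that the peak
# intensity along a drawn line equals `level`.
polyline_points <- function(p0, p1, sigma_um, level, vox, node_id) {
  seg <- p1 - p0
  len <- sqrt(sum(seg^2))
  spacing <- min(vox) / 2
  ts <- if (len == 0) 0 else seq(0, 1, by = min(1, spacing / len))
  amp <- if (len == 0) level else level * spacing / (sqrt(2 * pi) * sigma_um)
  data.frame(x = p0[1] + ts * seg[1], y = p0[2] + ts * seg[2],
             z = p0[3] + ts * seg[3], sigma = sigma_um, amp = amp,
             node_id = node_id)
}

# Splat Gaussian blobs for a batch of points into `vol`; `mask` marks
# voxels within one sigma of any point. One call per structure keeps the
# copy-on-write cost of the volume to a single copy.
splat_points <- function(vol, mask, pts, vox) {
  d <- dim(vol)
  for (i in seq_len(nrow(pts))) {
    sigma <- pts$sigma[i]
    kr <- ceiling(3 * sigma / vox)
    ci <- c(pts$x[i], pts$y[i], pts$z[i]) / vox + 0.5
    lo <- floor(ci - kr); hi <- ceiling(ci + kr)
    lo <- pmax(lo, 1); hi2 <- pmin(hi, d[c(2, 1, 3)])
    if (any(lo > hi2)) {
      stop_domain("node ", pts$node_id[i],
                  " rasterizes outside the volume")
    }
    xi <- lo[1]:hi2[1]; yi <- lo[2]:hi2[2]; zi <- lo[3]:hi2[3]
    dx2 <- ((xi - ci[1]) * vox[1])^2
    dy2 <- ((yi - ci[2]) * vox[2])^2
    dz2 <- ((zi - ci[3]) * vox[3])^2
    r2 <- outer(outer(dy2, dx2, "+"), dz2, "+")
    vol[yi, xi, zi] <- vol[yi, xi, zi] + pts$amp[i] * exp(-r2 / (2 * sigma^2))
    if (!is.null(mask)) {
      mask[yi, xi, zi] <- mask[yi, xi, zi] | (r2 <= sigma^2 * (1 + 1e-9))
    }
  }
  list(vol = vol, mask = mask)
}

#' Rasterize neuron trees into a phantom volume
#'
#' Draws every tree as a 3D polyline with a Gaussian radial intensity
#' cross-section (`sigma` = node radius), an enlarged Gaussian blob at the
#' soma, optional vessel tubes, and a background field (uniform level plus
#' an optional smooth texture replicated along z). Composition is additive
#' with a single background term. The truth mask marks voxels within one
#' radius of any neuron segment; per-tile occupancy can be derived from it.
#'
#' @param trees List of `neuron_tree` objects (e.g. from
#'   [generate_neurons()]); their `snr_class` attribute selects the bright
#'   or dim intensity level.
#' @param config A [phantom_config()].
#' @return A `phantom_volume` whose `truth` holds `signal_mask` (logical
#'   array) and `neuron_class` (per-tree class), and whose array is indexed
#'   `[y, x, z]`.
#' @export
rasterize <- function(trees, config) {
  stopifnot(inherits(config, "phantom_config"))
  ext <- config$extent_um
  vox <- rep(config$voxel_size_um, 3)
  d <- c(ceiling(ext[2] / vox[2]), ceiling(ext[1] / vox[1]),
         ceiling(ext[3] / vox[3]))  # [y, x, z]
  vol <- array(0, d)
  masks <- list(bright = array(FALSE, d), dim = array(FALSE, d))
  classes <- character(length(trees))
  for (k in seq_along(trees)) {
    tree <- validate_tree(trees[[k]])
    cls <- attr(tree, "snr_class")
    if (is.null(cls)) cls <- "bright"
    classes[k] <- cls
    level <- if (cls == "dim") config$dim_level else config$bright_level
    oob <- tree$x < 0 | tree$x > ext[1] | tree$y < 0 | tree$y > ext[2] |
      tree$z < 0 | tree$z > ext[3]
    if (any(oob)) {
      stop_domain("node ", tree$id[which(oob)[1]], " is outside the volume")
    }
    idx <- match(tree$parent, tree$id)
    pts <- do.call(rbind, lapply(seq_len(nrow(tree)), function(i) {
      if (is.na(idx[i])) {  # soma blob
        polyline_points(c(tree$x[i], tree$y[i], tree$z[i]),
                        c(tree$x[i], tree$y[i], tree$z[i]),
                        tree$radius[i], 2 * level, vox, tree$id[i])
      } else {
        j <- idx[i]
        polyline_points(c(tree$x[j], tree$y[j], tree$z[j]),
                        c(tree$x[i], tree$y[i], tree$z[i]),
                        tree$radius[i], level, vox, tree$id[i])
      }
    }))
    res <- splat_points(vol, masks[[cls]], pts, vox)
    vol <- res$vol; masks[[cls]] <- res$mask
  }
  vol <- vol + vessel_field(config, d, vox)
  bg <- background_field(config, d)
  new_phantom_volume(vol + bg, vox,
                     truth = list(signal_mask = masks$bright | masks$dim,
                                  bright_mask = masks$bright,
                                  dim_mask = masks$dim,
                                  neuron_class = classes),
                     meta = list(config = config, kind = "neurons"))
}

vessel_field <- function(config, d, vox) {
  out <- array(0, d)
  if (config$vessel_density <= 0) return(out)
  ext <- config$extent_um
  n <- stats::rpois(1, config$vessel_density * prod(ext) / 1e9)
  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    p0 <- stats::runif(3) * ext
    p1 <- pmin(pmax(p0 + runit3() * max(ext), 0), ext)
    polyline_points(p0, p1, config$vessel_radius_um,
                    config$vessel_level, vox, NA)
  }))
  if (is.null(pts)) return(out)
  splat_points(out, NULL, pts, vox)$vol
}

# smooth 2D texture (replicated along z): white noise on a coarse grid,
# bilinearly upsampled, rescaled to the requested SD
background_field <- function(config, d) {
  bg <- array(config$background_level, d)
  if (config$background_texture_sd <= 0) return(bg)
  with_substream(config$seed, "texture", {
    cell_px <- max(2, round(config$texture_scale_um / config$voxel_size_um))
    nr <- max(2, ceiling(d[1] / cell_px) + 1)
    nc <- max(2, ceiling(d[2] / cell_px) + 1)
    coarse <- matrix(stats::rnorm(nr * nc), nr, nc)
    tex <- bilinear_sample(coarse,
                           seq(1, nr, length.out = d[1]),
                           seq(1, nc, length.out = d[2]))
    # round off the piecewise-linear ridges so the field is smooth at the
    # rolling-ball scale
    tex <- gauss_blur_2d(tex, cell_px / 3)
    tex <- tex - mean(tex)
    s <- stats::sd(as.vector(tex))
    if (s > 0) tex <- tex * (config$background_texture_sd / s)
    tex <- tex - min(tex)  # keep intensity non-negative
    bg + array(rep(tex, d[3]), d)
  })
}

#' Generate a field of sub-resolution fluorescent beads
#'
#' Point emitters (nominally 0.2 um beads, below the voxel size) are placed
#' uniformly at random; each deposits its amplitude into the 8 neighboring
#' voxels by trilinear weights so sub-voxel positions are preserved. True
#' positions are recorded in `truth$beads`.
#'
#' @param density_per_mm3 Expected bead count per mm^3 (Poisson).
#' @param extent_um Length-3 volume extent in um.
#' @param voxel_size_um Isotropic voxel size in um.
#' @param seed Integer seed.
#' @param bead_diameter_um Nominal bead diameter; must be below the voxel
#'   size (the bead is a point emitter at this scale).
#' @param amplitude Photon amplitude per bead.
#' @param background_level Uniform background.
#' @param positions Optional data frame of fixed bead positions
#'   (`x, y, z` in um) overriding random placement, e.g. a regular grid
#'   for illumination-mode comparisons.
#' @return A `phantom_volume`.
#' @export
generate_beads <- function(density_per_mm3, extent_um, voxel_size_um = 1,
                           seed = 1L, bead_diameter_um = 0.2,
                           amplitude = 1000, background_level = 0,
                           positions = NULL) {
  check_nonnegative(density_per_mm3, "density_per_mm3")
  if (bead_diameter_um >= voxel_size_um) {
    stop_domain("`bead_diameter_um` must be below the voxel size ",
                "(sub-resolution point emitters)")
  }
  vox <- rep(voxel_size_um, 3)
  d <- c(ceiling(extent_um[2] / vox[2]), ceiling(extent_um[1] / vox[1]),
         ceiling(extent_um[3] / vox[3]))
  with_substream(seed, "beads", {
    if (is.null(positions)) {
      n <- stats::rpois(1, density_per_mm3 * prod(extent_um) / 1e9)
      pos <- matrix(stats::runif(3 * n), ncol = 3) %*% diag(extent_um)
      colnames(pos) <- c("x", "y", "z")
    } else {
      pos <- as.matrix(as.data.frame(positions)[, c("x", "y", "z")])
      n <- nrow(pos)
    }
    vol <- array(background_level, d)
    for (i in seq_len(n)) {
      ci <- c(pos[i, "y"] / vox[2], pos[i, "x"] / vox[1],
              pos[i, "z"] / vox[3]) + 0.5
      i0 <- floor(ci); f <- ci - i0
      for (dy in 0:1) for (dx in 0:1) for (dz in 0:1) {
        j <- i0 + c(dy, dx, dz)
        if (all(j >= 1) && all(j <= d)) {
          w <- prod(ifelse(c(dy, dx, dz) == 1, f, 1 - f))
          vol[j[1], j[2], j[3]] <- vol[j[1], j[2], j[3]] + amplitude * w
        }
      }
    }
    new_phantom_volume(vol, vox,
                       truth = list(beads = as.data.frame(pos)),
                       meta = list(seed = seed, kind = "beads"))
  })
}

#' Generate a uniform dye pool
#'
#' @param level Uniform intensity level (>= 0).
#' @param extent_um Length-3 extent in um.
#' @param voxel_size_um Isotropic voxel size in um.
#' @return A `phantom_volume` whose intensity is exactly `level` everywhere.
#' @export
generate_dye_pool <- function(level, extent_um = c(200, 200, 20),
                              voxel_size_um = 2) {
  check_nonnegative(level, "level")
  vox <- rep(voxel_size_um, 3)
  d <- c(ceiling(extent_um[2] / vox[2]), ceiling(extent_um[1] / vox[1]),
         ceiling(extent_um[3] / vox[3]))
  new_phantom_volume(array(level, d), vox,
                     meta = list(kind = "dye_pool", level = level))
}

#' Generate spike-width labels along an electrode track
#'
#' Units are placed at distances uniform over `distance_range` (signed
#' distance to the anatomical boundary; positive = inside the target
#' structure) and labeled narrow-spiking with logistic probability
#' `1 / (1 + exp(-(d - d0)/slope))`.
#'
#' @param d0_um True half-probability distance in um.
#' @param slope_um True logistic scale in um (> 0).
#' @param n Number of units (>= 1).
#' @param seed Integer seed.
#' @param distance_range Length-2 range of distances sampled.
#' @return A data frame with columns `distance_um` and `is_narrow`.
#' @export
generate_spike_track <- function(d0_um = 22, slope_um = 10, n = 500,
                                 seed = 1L,
                                 distance_range = c(-300, 300)) {
  if (n < 1) stop_domain("`n` must be >= 1")
  check_positive(slope_um, "slope_um")
  with_substream(seed, "spike_track", {
    d <- stats::runif(n, distance_range[1], distance_range[2])
    p <- stats::plogis((d - d0_um) / slope_um)
    data.frame(distance_um = d,
               is_narrow = stats::runif(n) < p)
  })
}
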