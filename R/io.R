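#' Write and read 16-bit tile stacks as multi-page TIFF with JSON sidecar
#'
#' Voxel counts are written as 16-bit multi-page TIFF (one page per z
#' plane) and the stack metadata -- stage origin, pixel size, z planes,
#' zoom, pass, exposure, seed, and a config hash when available -- as a
#' JSON sidecar next to the image. The round trip is lossless for 16-bit
#' counts.
#'
#' @param stack A `tile_stack`.
#' @param path Output TIFF path; the sidecar is `path` with a `.json`
#'   extension added.
#' @return `write_stack` returns `path` invisibly; `read_stack` a
#'   `tile_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "tile_stack"))
  pages <- lapply(seq_len(dim(stack$counts)[3]), function(k) {
    stack$counts[, , k] / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(stack$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      stop_domain("cannot parse TIFF ", path, ": ",
                                  conditionMessage(e))
                    })
  if (!length(pages)) stop_domain("TIFF ", path, " holds no pages")
  counts <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    counts[, , k] <- as.integer(round(pages[[k]] * 65535))
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else list()
  structure(list(counts = counts, meta = meta), class = "tile_stack")
}

#' Write a phantom volume to TIFF + sidecar (+ truth mask)
#'
#' The intensity field is scaled to the 16-bit range (scale factor stored
#' in the sidecar), truth masks are written as separate binary TIFF
#' stacks.
#'
#' @param phantom A `phantom_volume`.
#' @param dir Output directory (created if missing).
#' @param name Base name of the files.
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  stopifnot(inherits(phantom, "phantom_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(phantom$intensity, 1)
  scale <- 65535 / mx
  pages <- lapply(seq_len(dim(phantom$intensity)[3]), function(k) {
    round(phantom$intensity[, , k] * scale) / 65535
  })
  tiff::writeTIFF(pages, file.path(dir, paste0(name, ".tif")),
                  bits.per.sample = 16, compression = "none")
  if (!is.null(phantom$truth$signal_mask)) {
    mask_pages <- lapply(seq_len(dim(phantom$truth$signal_mask)[3]),
                         function(k) {
                           phantom$truth$signal_mask[, , k] * 1
                         })
    tiff::writeTIFF(mask_pages, file.path(dir, paste0(name, "_mask.tif")),
                    bits.per.sample = 8, compression = "none")
  }
  meta <- list(voxel_size_um = phantom$voxel_size_um,
               intensity_scale = scale,
               config = phantom$meta$config,
               config_hash = config_hash(phantom$meta$config),
               kind = phantom$meta$kind)
  jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}

#' Read and write configuration objects as YAML
#'
#' @param config A named list (or one of the package's config objects).
#' @param path YAML file path.
#' @return `read_config` returns a named list; `write_config` the path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Stable fingerprint of a configuration object
#'
#' @param config Any R object (classes are dropped before hashing).
#' @return A character hash.
#' @export
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  rlang::hash(rapply(list(unclass(config)), unclass, how = "replace"))
}
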