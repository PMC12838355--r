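#' Read and write image stacks as multi-page TIFF
#'
#' Stacks are stored channel-major: all z-slices of the first channel, then
#' all z-slices of the second, as 32-bit float pages. Because TIFF float
#' samples conventionally live in \[0, 1\], intensities are divided by a
#' power-of-two scale on write; the scale, channel names and voxel geometry
#' travel in a JSON sidecar (`<stem>.json`) written next to the TIFF.
#'
#' @param stack An [image_stack()].
#' @param path Path of the `.tif` file.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   an [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  mx <- max(v, 1e-12)
  scale <- 2^ceiling(log2(mx))
  pages <- list()
  for (ch in seq_along(stack$channels)) {
    for (z in seq_len(dim(v)[3])) {
      pages[[length(pages) + 1L]] <- v[, , z, ch] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  g <- stack$geometry
  meta <- list(channels = stack$channels, scale = scale,
               ny = g$ny, nx = g$nx, n_slices = g$n_slices,
               dx = g$dx, dy = g$dy, dz = g$dz, layout = "channel-major")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(meta$channels)
  nz <- meta$n_slices
  if (length(pages) != nc * nz) abort("page count does not match sidecar metadata.")
  vox <- array(0, c(meta$ny, meta$nx, nz, nc))
  i <- 1L
  for (ch in seq_len(nc)) {
    for (z in seq_len(nz)) {
      vox[, , z, ch] <- pages[[i]] * meta$scale
      i <- i + 1L
    }
  }
  acq <- acquisition_geometry(field_pixels = c(meta$ny, meta$nx),
                              n_slices = nz, dx = meta$dx, dy = meta$dy,
                              dz = meta$dz)
  image_stack(vox, acq, channels = meta$channels)
}

#' Read and write binary masks as TIFF
#'
#' Voxel or pixel masks are written as 8-bit TIFF pages with foreground 1.
#'
#' @param mask A logical matrix or 3D array.
#' @param path Path of the `.tif` file.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` the
#'   logical matrix/array.
#' @export
write_mask <- function(mask, path) {
  if (length(dim(mask)) == 2L) {
    tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  } else {
    pages <- lapply(seq_len(dim(mask)[3]), function(z) mask[, , z] * 1)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1L) return(pages[[1]] > 0.5)
  arr <- array(FALSE, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]] > 0.5
  arr
}
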