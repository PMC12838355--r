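#' Construct an image stack
#'
#' A multi-channel 3D voxel grid with physical geometry. Voxels are indexed
#' `[y, x, z, channel]` (row, column, slice, channel), 1-based as usual in R,
#' with non-negative intensities in arbitrary units.
#'
#' @param voxels 4D numeric array `(ny, nx, n_slices, n_channels)`, or a 3D
#'   array for a single channel.
#' @param geometry An [acquisition_geometry()] consistent with `dim(voxels)`.
#' @param channels Character vector of channel names.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, geometry, channels = c("dapi", "marker")) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  d <- dim(voxels)
  if (length(d) != 4L) abort("`voxels` must be a 3D or 4D array.")
  if (d[4] != length(channels)) abort("channel names must match dim(voxels)[4].")
  if (d[1] != geometry$ny || d[2] != geometry$nx || d[3] != geometry$n_slices) {
    abort("voxel dimensions are inconsistent with `geometry`.")
  }
  if (min(voxels) < 0) abort("intensities must be >= 0.")
  structure(list(voxels = voxels, geometry = geometry,
                 channels = as.character(channels)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d x %d x %d, channels: %s\n",
              dim(x$voxels)[1], dim(x$voxels)[2], dim(x$voxels)[3],
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

# voxel-centre coordinates along one axis, um
axis_coords <- function(n, step) (seq_len(n) - 0.5) * step

# squared normalized offsets; an Inf semi-axis contributes 0 (extrusion)
norm_sq <- function(coords, center, semi_axis) {
  if (is.finite(semi_axis)) ((coords - center) / semi_axis)^2 else
    numeric(length(coords))
}

# boolean (ny, nx, nz) voxel mask of an ellipsoid; Inf z semi-axis extrudes
ellipsoid_mask <- function(acq, center, radii) {
  ey <- norm_sq(axis_coords(acq$ny, acq$dy), center[2], radii[2])
  ex <- norm_sq(axis_coords(acq$nx, acq$dx), center[1], radii[1])
  ez <- norm_sq(axis_coords(acq$n_slices, acq$dz), center[3], radii[3])
  outer(outer(ey, ex, "+"), ez, "+") <= 1
}

# nuclear envelope semi-axes from the nominal volume (slab: area) fraction
nucleus_envelope <- function(geom) {
  if (!is.null(geom$nucleus_radii)) return(geom$nucleus_radii)
  s <- if (is.finite(geom$cell_radii[3])) geom$nucleus_scale^(1 / 3) else
    sqrt(geom$nucleus_scale)
  geom$cell_radii * s
}

# render the nucleus voxel mask inside an envelope centred at `center`;
# consumes RNG for shape orientation
render_nucleus <- function(geom, acq, center) {
  re <- nucleus_envelope(geom)
  switch(
    geom$nucleus_shape,
    round = ellipsoid_mask(acq, center, re),
    kidney = {
      # ellipsoid minus an offset ellipsoidal bite on a random side
      theta <- runif(1, 0, 2 * pi)
      bite_c <- center + c(cos(theta) * 0.9 * re[1],
                           sin(theta) * 0.9 * re[2], 0)
      env <- ellipsoid_mask(acq, center, re)
      bite <- ellipsoid_mask(acq, bite_c, re * c(0.55, 0.55, if (is.finite(re[3])) 0.7 else 1))
      env & !bite
    },
    multilobed = {
      # k overlapping lobes on a ring inside the envelope
      k <- geom$n_lobes
      rm_ <- min(re[1], re[2])
      rl <- 0.45 * rm_
      rc <- 0.50 * rm_
      theta0 <- runif(1, 0, 2 * pi)
      lz <- if (is.finite(re[3])) min(rl, 0.8 * re[3]) else Inf
      m <- array(FALSE, c(acq$ny, acq$nx, acq$n_slices))
      for (i in seq_len(k)) {
        th <- theta0 + 2 * pi * (i - 1) / k
        lc <- center + c(cos(th) * rc, sin(th) * rc, 0)
        m <- m | ellipsoid_mask(acq, lc, c(rl, rl, lz))
      }
      m
    }
  )
}

# separable gaussian blur with a truncated, edge-renormalized kernel
gaussian_blur3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 0.05 || d[ax] < 2L) next
    n <- d[ax]
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * s^2))
    K[abs(outer(idx, idx, "-")) > ceiling(4 * s)] <- 0
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- K %*% matrix(a, nrow = n)
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

apply_noise <- function(arr, intensity) {
  switch(intensity$noise,
         none = arr,
         gaussian = {
           if (intensity$noise_sigma == 0) arr else
             pmax(arr + rnorm(length(arr), 0, intensity$noise_sigma), 0)
         },
         poisson = {
           sc <- intensity$noise_scale
           array(rpois(length(arr), arr * sc) / sc, dim(arr))
         })
}

#' Generate a synthetic two-channel confocal stack of one cell
#'
#' Renders a single immune-cell phantom into a two-channel 3D stack
#' (channel `"dapi"` = nuclear stain, channel `"marker"` = compartmentalized
#' marker) together with its ground truth. The marker channel has expected
#' intensity `mu_nuc` inside the nucleus, `mu_cyt` in the cytoplasm and
#' `background` outside the cell; the nuclear-stain channel is `mu_dapi`
#' inside the nucleus and `background` elsewhere. Per-voxel noise is applied
#' first, then the Gaussian optical blur; the same parameters and seed give
#' bit-identical output.
#'
#' The cell centre is jittered uniformly (up to `center_jitter` um per axis)
#' and the nucleus is placed uniformly within an interior margin chosen so
#' that blur cannot push nuclear signal outside the cell.
#'
#' @param geometry A [cell_geometry()].
#' @param intensity An [intensity_model()].
#' @param acq An [acquisition_geometry()]. The jittered cell must fit within
#'   the xy field.
#' @param seed Integer seed controlling jitter, shape orientation and noise.
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (class `synthetic_truth`: boolean voxel grids `cell_mask` and
#'   `nucleus_mask`, plus the generating parameters and seed).
#' @examples
#' acq <- acquisition_geometry(field_pixels = c(48, 48), n_slices = 5,
#'                             dx = 0.4, dz = 1.2)
#' g <- generate_cell_stack(cell_geometry(), intensity_model(), acq, seed = 1)
#' g$stack
#' sum(g$truth$nucleus_mask) / sum(g$truth$cell_mask)
#' @export
generate_cell_stack <- function(geometry = cell_geometry(),
                                intensity = intensity_model(),
                                acq = acquisition_geometry(),
                                seed = 1L) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(intensity, "intensity_model"),
            inherits(acq, "acquisition_geometry"))
  fx <- acq$nx * acq$dx; fy <- acq$ny * acq$dy; fz <- acq$n_slices * acq$dz
  if (geometry$cell_radii[1] + geometry$center_jitter > fx / 2 ||
      geometry$cell_radii[2] + geometry$center_jitter > fy / 2) {
    abort("cell (plus jitter) is larger than the xy field.")
  }
  withr::with_seed(as.integer(seed), {
    jit <- runif(2, -geometry$center_jitter, geometry$center_jitter)
    center <- c(fx / 2 + jit[1], fy / 2 + jit[2], fz / 2)
    cell <- ellipsoid_mask(acq, center, geometry$cell_radii)

    re <- nucleus_envelope(geometry)
    pad <- max(2 * intensity$psf_sigma, 0.15)
    max_off <- pmax(0, geometry$cell_radii[1:2] - re[1:2] - pad)
    off <- runif(2, -1, 1) * pmin(max_off, geometry$center_jitter)
    nuc_center <- center + c(off, 0)
    nucleus <- render_nucleus(geometry, acq, nuc_center) & cell

    bg <- intensity$background
    marker <- array(bg, dim(cell))
    marker[cell] <- intensity$mu_cyt
    marker[nucleus] <- intensity$mu_nuc
    dapi <- array(bg, dim(cell))
    dapi[nucleus] <- intensity$mu_dapi

    marker <- apply_noise(marker, intensity)
    dapi <- apply_noise(dapi, intensity)

    if (intensity$psf_sigma > 0) {
      sv <- intensity$psf_sigma / c(acq$dy, acq$dx, acq$dz)
      marker <- gaussian_blur3d(marker, sv)
      dapi <- gaussian_blur3d(dapi, sv)
    }

    vox <- array(0, c(dim(cell), 2L))
    vox[, , , 1] <- dapi
    vox[, , , 2] <- marker
    stack <- image_stack(vox, acq, channels = c("dapi", "marker"))
    truth <- structure(
      list(cell_mask = cell, nucleus_mask = nucleus,
           geometry = geometry, intensity = intensity, acq = acq,
           center = center, nucleus_center = nuc_center,
           seed = as.integer(seed)),
      class = "synthetic_truth")
    list(stack = stack, truth = truth)
  })
}
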