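#' Acquisition geometry of a confocal z-stack
#'
#' Physical sampling of the imaged volume. Defaults correspond to
#' high-resolution single-cell acquisition with an oil-immersion 63x
#' objective: square pixels of 0.07 um, a z-step of 0.19 um and 31 optical
#' sections, i.e. an imaged slab of about 5.9 um -- thinner than a typical
#' granulocyte or monocyte, so a mounted cell spans the whole slab.
#'
#' @param field_pixels Integer pair `(ny, nx)`: image height and width in
#'   pixels.
#' @param n_slices Number of optical sections (z-planes).
#' @param dx,dy Pixel size in um. Pixels must be square (`dx == dy`).
#' @param dz Axial step between optical sections, um.
#' @return An object of class `acquisition_geometry`.
#' @examples
#' acquisition_geometry()
#' acquisition_geometry(field_pixels = c(64, 64), n_slices = 9, dx = 0.28, dz = 0.655)
#' @export
acquisition_geometry <- function(field_pixels = c(256L, 256L), n_slices = 31L,
                                 dx = 0.07, dy = dx, dz = 0.19) {
  field_pixels <- as.integer(field_pixels)
  if (length(field_pixels) != 2L || any(field_pixels < 1L)) {
    abort("`field_pixels` must be two positive integers (ny, nx).")
  }
  if (!isTRUE(dx > 0) || !isTRUE(dz > 0)) abort("`dx` and `dz` must be > 0.")
  if (!isTRUE(all.equal(dx, dy))) abort("pixels must be square: dx == dy.")
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) abort("`n_slices` must be >= 1.")
  structure(
    list(ny = field_pixels[1], nx = field_pixels[2], n_slices = n_slices,
         dx = dx, dy = dy, dz = dz),
    class = "acquisition_geometry"
  )
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("<acquisition_geometry> %d x %d px (dx = %g um), %d slices (dz = %g um)\n",
              x$ny, x$nx, x$dx, x$n_slices, x$dz))
  invisible(x)
}

#' Single-cell phantom geometry
#'
#' Describes the shape of a synthetic immune cell: an ellipsoidal cell body
#' and a nucleus that is round, kidney-shaped (monocyte-like) or multilobed
#' (granulocyte-like).
#'
#' A z semi-axis of `Inf` renders the shape as its xy cross-section extruded
#' through the whole stack ("slab mode"): the mounted, compressed cell spans
#' the imaged z-range, so every in-cell pixel column traverses the same
#' thickness. This is the default; it matches acquisition in which the stack
#' depth (about 5.9 um) is smaller than the cell diameter, and it makes the
#' z-sum projection piecewise constant so segmentation is exactly recoverable.
#' Finite semi-axes give a true ellipsoid with chord-length falloff at the rim.
#'
#' @param cell_radii Numeric triple, um: semi-axes (x, y, z) of the cell
#'   ellipsoid. The z semi-axis may be `Inf` (slab mode).
#' @param nucleus_shape One of `"round"`, `"kidney"`, `"multilobed"`.
#' @param n_lobes Number of nuclear lobes for `"multilobed"`, between 2 and 5.
#' @param nucleus_scale Nominal nuclear fraction of cell volume (area fraction
#'   in slab mode), in (0, 1). Kidney and multilobed shapes are carved from /
#'   packed into the envelope this fraction defines, so their realized volume
#'   is somewhat smaller.
#' @param center_jitter Maximum random displacement of the cell centre from
#'   the field centre, um (uniform per axis).
#' @param nucleus_radii Optional numeric triple, um: explicit nuclear envelope
#'   semi-axes overriding `nucleus_scale` (must fit strictly inside the cell).
#' @return An object of class `cell_geometry`.
#' @examples
#' cell_geometry()                              # round nucleus, slab cell
#' cell_geometry(nucleus_shape = "multilobed")  # granulocyte-like
#' @export
cell_geometry <- function(cell_radii = c(6, 6, Inf),
                          nucleus_shape = c("round", "kidney", "multilobed"),
                          n_lobes = 3L,
                          nucleus_scale = 0.4,
                          center_jitter = 0.5,
                          nucleus_radii = NULL) {
  nucleus_shape <- match.arg(nucleus_shape)
  if (length(cell_radii) != 3L || any(cell_radii <= 0)) {
    abort("`cell_radii` must be three positive semi-axes (um).")
  }
  if (any(!is.finite(cell_radii[1:2]))) {
    abort("cell x/y semi-axes must be finite (only the z semi-axis may be Inf).")
  }
  n_lobes <- as.integer(n_lobes)
  if (nucleus_shape == "multilobed" && (n_lobes < 2L || n_lobes > 5L)) {
    abort("`n_lobes` must be between 2 and 5.")
  }
  if (!isTRUE(nucleus_scale > 0 && nucleus_scale < 1)) {
    abort("`nucleus_scale` must lie strictly in (0, 1).")
  }
  if (!isTRUE(center_jitter >= 0)) abort("`center_jitter` must be >= 0.")
  if (!is.null(nucleus_radii)) {
    if (length(nucleus_radii) != 3L || any(nucleus_radii <= 0)) {
      abort("`nucleus_radii` must be three positive semi-axes (um).")
    }
    if (any(nucleus_radii[1:2] >= cell_radii[1:2])) {
      abort("nucleus must fit strictly inside the cell envelope.")
    }
  }
  structure(
    list(cell_radii = as.numeric(cell_radii), nucleus_shape = nucleus_shape,
         n_lobes = n_lobes, nucleus_scale = nucleus_scale,
         center_jitter = center_jitter,
         nucleus_radii = if (is.null(nucleus_radii)) NULL else as.numeric(nucleus_radii)),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> radii (%s) um, %s nucleus (scale %.2f)\n",
              paste(signif(x$cell_radii, 3), collapse = ", "),
              if (x$nucleus_shape == "multilobed")
                sprintf("%d-lobed", x$n_lobes) else x$nucleus_shape,
              x$nucleus_scale))
  invisible(x)
}

#' Fluorophore intensity model for the phantom
#'
#' Mean signal levels (arbitrary units) for the two rendered channels: a
#' nuclear stain (DAPI-like, bright in the nucleus only) and a marker channel
#' distributed between nucleus and cytoplasm with a configurable
#' nuclear:cytoplasmic ratio, emulating an antibody-stained protein that can
#' relocate between compartments. Photon-like noise is added per voxel and an
#' isotropic Gaussian blur stands in for the optical point-spread function.
#' Noise is applied before blur; negative values are clipped at zero;
#' detector saturation is not simulated.
#'
#' @param mu_nuc Mean marker intensity inside the nucleus.
#' @param mu_cyt Mean marker intensity in the cytoplasm.
#' @param mu_dapi Mean nuclear-stain intensity inside the nucleus.
#' @param background Mean off-cell intensity (both channels). Must be below
#'   both the nuclear stain and the brighter marker compartment.
#' @param noise `"gaussian"` (additive, sd `noise_sigma`), `"poisson"`
#'   (counts at `noise_scale` counts per intensity unit), or `"none"`.
#' @param noise_sigma Gaussian noise standard deviation (ignored otherwise).
#' @param noise_scale Poisson scaling, counts per intensity unit.
#' @param psf_sigma Isotropic Gaussian blur sigma, um. `0` disables blur.
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(mu_nuc = 180, mu_cyt = 90, mu_dapi = 180,
                            background = 4,
                            noise = c("gaussian", "poisson", "none"),
                            noise_sigma = 6, noise_scale = 1,
                            psf_sigma = 0.15) {
  noise <- match.arg(noise)
  for (v in c(mu_nuc = mu_nuc, mu_cyt = mu_cyt, mu_dapi = mu_dapi,
              background = background)) {
    if (!isTRUE(v >= 0)) abort("intensity means must be >= 0.")
  }
  if (!isTRUE(background < min(mu_dapi, max(mu_nuc, mu_cyt)))) {
    abort("`background` must be below min(mu_dapi, max(mu_nuc, mu_cyt)).")
  }
  if (!isTRUE(psf_sigma >= 0)) abort("`psf_sigma` must be >= 0.")
  if (noise == "gaussian" && !isTRUE(noise_sigma >= 0)) {
    abort("`noise_sigma` must be >= 0.")
  }
  if (noise == "poisson" && !isTRUE(noise_scale > 0)) {
    abort("`noise_scale` must be > 0.")
  }
  structure(
    list(mu_nuc = mu_nuc, mu_cyt = mu_cyt, mu_dapi = mu_dapi,
         background = background, noise = noise, noise_sigma = noise_sigma,
         noise_scale = noise_scale, psf_sigma = psf_sigma),
    class = "intensity_model"
  )
}

#' @export
print.intensity_model <- function(x, ...) {
  nz <- switch(x$noise,
               gaussian = sprintf("gaussian(sigma = %g)", x$noise_sigma),
               poisson = sprintf("poisson(scale = %g)", x$noise_scale),
               none = "none")
  cat(sprintf("<intensity_model> marker %g/%g (nuc/cyt), dapi %g, bg %g, noise %s, psf %g um\n",
              x$mu_nuc, x$mu_cyt, x$mu_dapi, x$background, nz, x$psf_sigma))
  invisible(x)
}

default_geometry_for <- function(cell_type) {
  switch(cell_type,
         GR = cell_geometry(nucleus_shape = "multilobed", n_lobes = 3L),
         MO = cell_geometry(nucleus_shape = "kidney"),
         cell_geometry())
}

#' Design of a two-channel imaging cohort
#'
#' Describes a cohort of single-cell stacks: donors nested in groups (for
#' example a junior and a senior age group), one or more sorted cell types
#' (`GR` granulocytes render with multilobed nuclei, `MO` monocytes with
#' kidney-shaped nuclei), one or more markers, and a fixed number of cells
#' imaged per donor and marker (30 by default, so a two-group design with 8
#' donors per group yields 480 cells per cell type and marker).
#'
#' @param groups Character vector of group labels (>= 1).
#' @param n_donors_per_group Donors per group.
#' @param cell_types Character vector of cell-type labels.
#' @param markers Character vector of marker labels.
#' @param cells_per_donor Cells imaged per donor, cell type and marker.
#' @param intensity An [intensity_model()], or a nested named list
#'   `intensity[[group]][[marker]]` for group/marker-specific parameters.
#' @param geometry A [cell_geometry()], or a named list keyed by cell type;
#'   `NULL` uses shape conventions per cell type (see above).
#' @param seed Master seed; every per-stack seed derives from it, so the full
#'   cohort is bit-reproducible.
#' @return An object of class `cohort_design`.
#' @examples
#' d <- cohort_design(n_donors_per_group = 2, cells_per_donor = 3)
#' cohort_labels(d)
#' @export
cohort_design <- function(groups = c("junior", "senior"),
                          n_donors_per_group = 8L,
                          cell_types = "GR",
                          markers = "HMGB1",
                          cells_per_donor = 30L,
                          intensity = intensity_model(),
                          geometry = NULL,
                          seed = 1L) {
  if (length(groups) < 1L || anyDuplicated(groups)) {
    abort("`groups` must be distinct labels.")
  }
  n_donors_per_group <- as.integer(n_donors_per_group)
  cells_per_donor <- as.integer(cells_per_donor)
  if (n_donors_per_group < 1L || cells_per_donor < 1L) {
    abort("counts must be >= 1.")
  }
  if (length(cell_types) < 1L || length(markers) < 1L) {
    abort("need at least one cell type and one marker.")
  }
  intensity <- normalize_intensity_table(intensity, groups, markers)
  geometry <- normalize_geometry_table(geometry, cell_types)
  structure(
    list(groups = as.character(groups),
         n_donors_per_group = n_donors_per_group,
         cell_types = as.character(cell_types),
         markers = as.character(markers),
         cells_per_donor = cells_per_donor,
         intensity = intensity, geometry = geometry,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

# expand a single model (or partial list) to intensity[[group]][[marker]]
normalize_intensity_table <- function(intensity, groups, markers) {
  if (inherits(intensity, "intensity_model")) {
    intensity <- setNames(
      lapply(groups, function(g) setNames(rep(list(intensity), length(markers)), markers)),
      groups)
    return(intensity)
  }
  if (!is.list(intensity) || !all(groups %in% names(intensity))) {
    abort("`intensity` must be an intensity_model or a named list per group.")
  }
  out <- lapply(groups, function(g) {
    el <- intensity[[g]]
    if (inherits(el, "intensity_model")) {
      return(setNames(rep(list(el), length(markers)), markers))
    }
    if (!all(markers %in% names(el))) {
      abort(sprintf("intensity for group '%s' must cover all markers.", g))
    }
    el[markers]
  })
  setNames(out, groups)
}

normalize_geometry_table <- function(geometry, cell_types) {
  if (is.null(geometry)) {
    return(setNames(lapply(cell_types, default_geometry_for), cell_types))
  }
  if (inherits(geometry, "cell_geometry")) {
    return(setNames(rep(list(geometry), length(cell_types)), cell_types))
  }
  if (!is.list(geometry) || !all(cell_types %in% names(geometry))) {
    abort("`geometry` must be a cell_geometry or a named list per cell type.")
  }
  geometry[cell_types]
}

#' @export
print.cohort_design <- function(x, ...) {
  n <- length(x$groups) * x$n_donors_per_group * length(x$cell_types) *
    length(x$markers) * x$cells_per_donor
  cat(sprintf("<cohort_design> %d groups x %d donors x %d types x %d markers x %d cells = %d stacks (seed %d)\n",
              length(x$groups), x$n_donors_per_group, length(x$cell_types),
              length(x$markers), x$cells_per_donor, n, x$seed))
  invisible(x)
}

#' Plant a cytoplasmic translocation effect in one group
#'
#' Rescales the cytoplasmic marker mean for one group and marker, emulating
#' nucleus-to-cytoplasm translocation of the stained protein (the cytoplasm
#' gains signal). All other group/marker intensity models are untouched.
#'
#' @param design A [cohort_design()].
#' @param group Group receiving the effect (default: the last group).
#' @param marker Marker carrying the effect (default: the first marker).
#' @param factor Multiplier applied to the cytoplasmic mean `mu_cyt`.
#' @return The modified `cohort_design`.
#' @export
plant_translocation <- function(design, group = NULL, marker = NULL, factor = 2) {
  stopifnot(inherits(design, "cohort_design"))
  group <- group %||% design$groups[length(design$groups)]
  marker <- marker %||% design$markers[1]
  if (!group %in% design$groups) abort(sprintf("unknown group '%s'.", group))
  if (!marker %in% design$markers) abort(sprintf("unknown marker '%s'.", marker))
  if (!isTRUE(factor > 0)) abort("`factor` must be > 0.")
  im <- design$intensity[[group]][[marker]]
  im$mu_cyt <- im$mu_cyt * factor
  design$intensity[[group]][[marker]] <- intensity_model(
    mu_nuc = im$mu_nuc, mu_cyt = im$mu_cyt, mu_dapi = im$mu_dapi,
    background = im$background, noise = im$noise,
    noise_sigma = im$noise_sigma, noise_scale = im$noise_scale,
    psf_sigma = im$psf_sigma)
  design
}
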