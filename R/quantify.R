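#' Pixel-value histogram of a compartment
#'
#' Counts masked pixels at each intensity `k` in 1..255. Zero-valued pixels
#' are outside the histogram domain (they carry no detectable fluorescence),
#' so the total count equals the number of non-zero masked pixels.
#'
#' @param img8 8-bit image (integer matrix in \[0, 255\]).
#' @param mask Logical mask of the same shape.
#' @return Integer vector of length 255; element `k` is the count at
#'   intensity `k`.
#' @examples
#' img <- matrix(c(0L, 3L, 3L, 7L), 2)
#' h <- intensity_histogram(img, matrix(TRUE, 2, 2))
#' h[c(3, 7)]
#' @export
intensity_histogram <- function(img8, mask) {
  if (!all(dim(img8) == dim(mask))) abort("shape mismatch between image and mask.")
  tabulate(as.integer(img8[mask]), nbins = 255L)
}

#' Tidy per-compartment histogram table
#'
#' Convenience wrapper around [intensity_histogram()] returning a tibble,
#' e.g. for CSV export of per-cell histograms.
#'
#' @inheritParams intensity_histogram
#' @param compartment Optional label column to attach.
#' @return A tibble with columns `k` (1..255), `count` and, if given,
#'   `compartment`.
#' @export
histogram_table <- function(img8, mask, compartment = NULL) {
  out <- tibble(k = 1:255, count = intensity_histogram(img8, mask))
  if (!is.null(compartment)) out$compartment <- compartment
  out
}

#' Per-compartment pixel metrics N, S and MFI
#'
#' `N` is the number of masked pixels with detectable signal (value > 0),
#' `S` the integrated intensity (sum of all masked pixel values; zeros add
#' nothing), and `S / N` the mean pixel intensity -- an image-based analog
#' of flow cytometry's mean fluorescence intensity (MFI). An empty
#' compartment has `N = 0`, `S = 0` and a missing MFI (`NA`, never 0).
#'
#' @inheritParams intensity_histogram
#' @return A list with elements `n`, `s`, `mfi`.
#' @examples
#' compartment_metrics(matrix(c(0L, 3L, 3L, 7L), 2), matrix(TRUE, 2, 2))
#' @export
compartment_metrics <- function(img8, mask) {
  if (!all(dim(img8) == dim(mask))) abort("shape mismatch between image and mask.")
  v <- as.integer(img8[mask])
  n <- sum(v > 0L)
  s <- sum(v)
  list(n = n, s = s, mfi = if (n > 0L) s / n else NA_real_)
}

#' Histogram half-width at half-maximum
#'
#' Measures the breadth of an intensity histogram: locate the modal bin
#' (ties broken toward the smaller intensity), take half its height, and
#' scan outward for the first crossings below that level, interpolating
#' linearly between bins; the HWHM is half the distance between the two
#' crossings. A run of bins exactly at half-maximum is traversed, so the
#' outermost plateau edge is used. A histogram whose mass sits in a single
#' bin is a point mass with zero width. If a side never drops below
#' half-maximum inside the 1..255 domain, that crossing is clamped to the
#' domain edge and the result carries a `truncated` attribute.
#'
#' One-sided variants (`"left"`, `"right"`: distance from the mode to the
#' single crossing) are available alongside the default symmetric
#' half-of-full-width.
#'
#' @param counts Histogram counts over intensities 1..255 (vector of length
#'   255), with at least one positive bin.
#' @param variant `"half_fwhm"` (default), `"left"` or `"right"`.
#' @return Numeric HWHM in intensity units, with logical attribute
#'   `truncated`.
#' @examples
#' tri <- numeric(255)
#' tri[80:120] <- 20 - abs(80:120 - 100)
#' hwhm(tri)  # 10: half-max at half-base of a triangle
#' @export
hwhm <- function(counts, variant = c("half_fwhm", "left", "right")) {
  variant <- match.arg(variant)
  if (length(counts) != 255L) abort("`counts` must have length 255 (k = 1..255).")
  if (any(counts < 0)) abort("histogram counts must be >= 0.")
  if (all(counts == 0)) abort("histogram is empty.")
  counts <- as.numeric(counts)
  if (sum(counts > 0) == 1L) {
    return(structure(0, truncated = FALSE))
  }
  kstar <- which.max(counts)
  h <- counts[kstar] / 2
  trunc_l <- trunc_r <- FALSE

  j <- kstar
  while (j <= 255L && counts[j] >= h) j <- j + 1L
  if (j > 255L) {
    right <- 255
    trunc_r <- TRUE
  } else {
    right <- (j - 1) + (counts[j - 1] - h) / (counts[j - 1] - counts[j])
  }

  j <- kstar
  while (j >= 1L && counts[j] >= h) j <- j - 1L
  if (j < 1L) {
    left <- 1
    trunc_l <- TRUE
  } else {
    left <- (j + 1) - (counts[j + 1] - h) / (counts[j + 1] - counts[j])
  }

  value <- switch(variant,
                  half_fwhm = (right - left) / 2,
                  left = kstar - left,
                  right = right - kstar)
  structure(value, truncated = trunc_l || trunc_r)
}

#' Quantification settings
#'
#' @param nuclear_channel,marker_channel Channel names in the stack.
#' @param cell_mask_channel Channel whose 8-bit projection is Otsu-thresholded
#'   for the cell mask: the marker channel (default, the channel being
#'   quantified), the nuclear stain, or the union of both foregrounds.
#' @param connectivity Pixel connectivity for component labelling (8 or 4).
#' @param hwhm_variant Passed to [hwhm()].
#' @param min_pixels Compartments with fewer than this many non-zero pixels
#'   are flagged low-quality (metrics are still reported).
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(nuclear_channel = "dapi", marker_channel = "marker",
                         cell_mask_channel = c("marker", "dapi", "union"),
                         connectivity = 8, hwhm_variant = "half_fwhm",
                         min_pixels = 10L) {
  structure(list(nuclear_channel = nuclear_channel,
                 marker_channel = marker_channel,
                 cell_mask_channel = match.arg(cell_mask_channel),
                 connectivity = connectivity,
                 hwhm_variant = hwhm_variant,
                 min_pixels = as.integer(min_pixels)),
            class = "quant_config")
}

empty_metrics <- function(prefix) {
  setNames(list(NA_integer_, NA_integer_, NA_real_, NA_real_),
           paste0(prefix, c("_n", "_s", "_mfi", "_hwhm")))
}

quantify_compartment <- function(img8, mask, cfg, prefix) {
  m <- compartment_metrics(img8, mask)
  hist <- intensity_histogram(img8, mask)
  if (any(hist > 0)) {
    hw <- hwhm(hist, cfg$hwhm_variant)
    trunc <- isTRUE(attr(hw, "truncated"))
    hw <- as.numeric(hw)
  } else {
    hw <- NA_real_
    trunc <- FALSE
  }
  out <- setNames(list(m$n, m$s, m$mfi, hw),
                  paste0(prefix, c("_n", "_s", "_mfi", "_hwhm")))
  out[[paste0("qc_low_n_", prefix)]] <- m$n < cfg$min_pixels
  out[[paste0("qc_hwhm_truncated_", prefix)]] <- trunc
  out
}

#' Quantify one cell stack
#'
#' Runs the full per-cell pipeline: z-sum projection of the nuclear-stain
#' and marker channels, 8-bit rescale, Otsu threshold and largest-component
#' cell mask, nuclear mask from the nuclear stain within the cell,
#' nuclear/cytoplasmic partition, and per-compartment histogram metrics
#' (N, S, MFI, HWHM) of the marker channel. Deterministic for a fixed stack
#' and configuration; degenerate segmentation states (constant channel, no
#' foreground object) propagate as `qc_*` flag columns rather than errors.
#'
#' @param stack An [image_stack()] (or a path to one written by
#'   [write_stack()]).
#' @param config A [quant_config()].
#' @param cell_id Identifier recorded in the output row.
#' @param labels Optional named list (donor, group, ...) spliced into the row.
#' @return A one-row tibble with label columns, `nuclear_*` and `cyto_*`
#'   metric columns (`_n`, `_s`, `_mfi`, `_hwhm`) and `qc_*` flags.
#' @examples
#' acq <- acquisition_geometry(field_pixels = c(48, 48), n_slices = 5,
#'                             dx = 0.4, dz = 1.2)
#' g <- generate_cell_stack(acq = acq, seed = 1)
#' quantify_cell(g$stack)
#' @export
quantify_cell <- function(stack, config = quant_config(), cell_id = "cell",
                          labels = NULL) {
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "image_stack"), inherits(config, "quant_config"))
  m8 <- rescale_8bit(sum_project(stack, config$marker_channel))
  d8 <- rescale_8bit(sum_project(stack, config$nuclear_channel))

  fg_of <- function(img8) {
    t <- otsu_threshold(img8)
    list(fg = img8 > t, single = is_single_class(t))
  }
  qc_marker_single <- FALSE
  qc_dapi_single <- FALSE
  fg <- switch(config$cell_mask_channel,
               marker = {
                 r <- fg_of(m8); qc_marker_single <- r$single; r$fg
               },
               dapi = {
                 r <- fg_of(d8); qc_dapi_single <- r$single; r$fg
               },
               union = {
                 rm_ <- fg_of(m8); rd <- fg_of(d8)
                 qc_marker_single <- rm_$single; qc_dapi_single <- rd$single
                 rm_$fg | rd$fg
               })

  base <- c(list(cell_id = cell_id), labels)
  if (!any(fg)) {
    row <- c(base, list(cell_px = 0L),
             empty_metrics("nuclear"), empty_metrics("cyto"),
             list(qc_no_object = TRUE,
                  qc_marker_single_class = qc_marker_single,
                  qc_dapi_single_class = qc_dapi_single,
                  qc_low_n_nuclear = TRUE, qc_hwhm_truncated_nuclear = FALSE,
                  qc_low_n_cyto = TRUE, qc_hwhm_truncated_cyto = FALSE))
    return(as_tibble(row))
  }
  cell <- largest_component(fg, config$connectivity)
  nuc <- nucleus_mask(d8, cell)
  if (is_single_class(nuc)) qc_dapi_single <- TRUE
  comp <- compartments(cell, nuc)

  row <- c(base, list(cell_px = sum(cell)),
           quantify_compartment(m8, comp$nucleus, config, "nuclear"),
           quantify_compartment(m8, comp$cytoplasm, config, "cyto"),
           list(qc_no_object = FALSE,
                qc_marker_single_class = qc_marker_single,
                qc_dapi_single_class = qc_dapi_single))
  as_tibble(row[unique(c("cell_id", names(base), "cell_px",
                         names(empty_metrics("nuclear")),
                         paste0(c("qc_low_n_", "qc_hwhm_truncated_"), "nuclear"),
                         names(empty_metrics("cyto")),
                         paste0(c("qc_low_n_", "qc_hwhm_truncated_"), "cyto"),
                         "qc_no_object", "qc_marker_single_class",
                         "qc_dapi_single_class"))])
}

#' Quantify a whole synthetic cohort
#'
#' Streams through a [cohort_design()]: each stack is generated from its
#' per-cell seed, quantified with [quantify_cell()], and discarded, so
#' memory stays flat in the cohort size.
#'
#' @param design A [cohort_design()].
#' @param acq An [acquisition_geometry()] shared by all stacks.
#' @param config A [quant_config()].
#' @return A tibble with one row per cell: labels, metrics and QC flags.
#' @export
quantify_cohort <- function(design, acq = acquisition_geometry(),
                            config = quant_config()) {
  labs <- cohort_labels(design)
  rows <- vector("list", nrow(labs))
  for (i in seq_len(nrow(labs))) {
    row <- labs[i, ]
    g <- generate_cell_stack(design$geometry[[row$cell_type]],
                             design$intensity[[row$group]][[row$marker]],
                             acq, seed = row$seed)
    rows[[i]] <- suppressWarnings(quantify_cell(
      g$stack, config, cell_id = row$cell_id,
      labels = list(group = row$group, donor = row$donor,
                    cell_type = row$cell_type, marker = row$marker)))
  }
  dplyr::bind_rows(rows)
}
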