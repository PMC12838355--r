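#' Sum-project a stack along the optical axis
#'
#' Collapses a 3D channel to a 2D intensity map by summing voxel intensities
#' over z at each (y, x) position. No normalization is applied, so integer
#' inputs give exact integer sums and projection is linear in the stack.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name (or index).
#' @return Numeric `ny x nx` matrix.
#' @examples
#' acq <- acquisition_geometry(field_pixels = c(2, 2), n_slices = 2, dx = 1, dz = 1)
#' v <- array(c(1, 3, 2, 4, 10, 30, 20, 40), c(2, 2, 2, 1))
#' sum_project(image_stack(v, acq, "marker"), "marker")
#' @export
sum_project <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    ch <- match(channel, stack$channels)
    if (is.na(ch)) abort(sprintf("unknown channel '%s'.", channel))
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > length(stack$channels)) abort("channel index out of range.")
  }
  rowSums(stack$voxels[, , , ch, drop = FALSE], dims = 2)
}

#' Rescale a projection to the full 8-bit range
#'
#' Linear min-max stretch to \[0, 255\] with half-up rounding
#' (`floor(x + 0.5)`), fixed for cross-platform reproducibility. A constant
#' input has no contrast to stretch and maps to all zeros, which keeps the
#' downstream "non-zero pixel" count N at zero for empty signals.
#'
#' @param proj Non-negative numeric matrix.
#' @return Integer matrix with values in \[0, 255\]; any non-constant input
#'   attains both 0 and 255.
#' @examples
#' rescale_8bit(matrix(c(10, 20, 30), 1))
#' @export
rescale_8bit <- function(proj) {
  r <- range(proj)
  out <- if (r[1] == r[2]) {
    rep(0L, length(proj))
  } else {
    as.integer(floor((proj - r[1]) / (r[2] - r[1]) * 255 + 0.5))
  }
  matrix(out, nrow = nrow(proj))
}

#' Otsu's threshold over the 8-bit histogram
#'
#' Selects the threshold `t` in \[0, 255\] maximizing the between-class
#' variance of the classes `{v <= t}` and `{v > t}`; foreground is `v > t`.
#' Ties are broken toward the smallest maximizing `t`. A constant (single
#' class) image returns its own value as the threshold, flagged via the
#' `single_class` attribute, so the foreground is empty.
#'
#' @param img8 Integer matrix (or vector) with values in \[0, 255\].
#' @return Integer threshold with attribute `single_class` (logical).
#' @seealso [is_single_class()]
#' @export
otsu_threshold <- function(img8) {
  v <- as.integer(img8)
  if (length(v) == 0L) abort("image is empty.")
  if (min(v) < 0L || max(v) > 255L) abort("values must lie in [0, 255].")
  h <- as.numeric(tabulate(v + 1L, 256L))
  if (sum(h > 0) == 1L) {
    return(structure(which(h > 0) - 1L, single_class = TRUE))
  }
  n <- sum(h)
  k <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * k)
  mt <- m0[256]
  w1 <- n - w0
  sb <- ifelse(w0 == 0 | w1 == 0, -Inf, (mt * w0 - n * m0)^2 / (w0 * w1))
  structure(which.max(sb) - 1L, single_class = FALSE)
}

#' @rdname otsu_threshold
#' @param t A threshold returned by [otsu_threshold()].
#' @export
is_single_class <- function(t) isTRUE(attr(t, "single_class"))

# label TRUE runs per row, then merge runs across adjacent rows (union-find);
# run-based labelling keeps the R-level work proportional to the number of
# runs, not pixels
#' Label connected foreground components
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default; diagonal neighbours connect) or 4.
#' @return Integer matrix; 0 is background, components are numbered by the
#'   raster-order position of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  ny <- nrow(mask); nx <- ncol(mask)
  runs_row <- integer(0); runs_start <- integer(0); runs_end <- integer(0)
  for (i in seq_len(ny)) {
    r <- rle(mask[i, ])
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    runs_row <- c(runs_row, rep.int(i, sum(keep)))
    runs_start <- c(runs_start, starts[keep])
    runs_end <- c(runs_end, ends[keep])
  }
  nr <- length(runs_row)
  out <- matrix(0L, ny, nx)
  if (nr == 0L) return(out)
  parent <- seq_len(nr)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  off <- if (connectivity == 8) 1L else 0L
  prev <- which(runs_row == runs_row[1])
  i <- 1L
  while (i <= nr) {
    row <- runs_row[i]
    cur <- i
    while (i <= nr && runs_row[i] == row) i <- i + 1L
    cur <- cur:(i - 1L)
    if (length(prev) && runs_row[prev[1]] == row - 1L) {
      for (a in cur) {
        for (b in prev) {
          if (runs_start[a] <= runs_end[b] + off &&
              runs_end[a] >= runs_start[b] - off) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
          }
        }
      }
    }
    prev <- cur
  }
  roots <- vapply(seq_len(nr), find, integer(1))
  # number components by raster order of their first pixel
  first_px <- (runs_row - 1L) * nx + runs_start
  comp_first <- tapply(first_px, roots, min)
  ord <- names(sort(comp_first))
  lab_of_root <- setNames(seq_along(ord), ord)
  for (j in seq_len(nr)) {
    out[runs_row[j], runs_start[j]:runs_end[j]] <-
      lab_of_root[[as.character(roots[j])]]
  }
  out
}

#' Keep the largest contiguous object
#'
#' Designates the connected component with the greatest pixel count as the
#' object of interest (the cell). Ties are broken toward the component whose
#' first pixel comes earliest in raster order. An all-background mask is
#' returned unchanged with a "no foreground object" warning.
#'
#' @inheritParams label_components
#' @return Logical matrix retaining only the largest component.
#' @export
largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  k <- max(lab)
  if (k == 0L) {
    warn("no foreground object in mask.")
    return(mask & FALSE)
  }
  sizes <- tabulate(lab[lab > 0L], k)
  best <- which.max(sizes)  # labels are raster-ordered, so this is the tie-break
  lab == best
}

#' Nuclear mask from the nuclear-stain channel
#'
#' Applies Otsu's threshold to the nuclear-stain (DAPI) pixels restricted to
#' the cell mask; the nuclear mask is the thresholded foreground intersected
#' with the cell. All components are retained, since lobed nuclei are
#' legitimately non-contiguous. If the stain is constant within the cell
#' there is no nuclear contrast: the nucleus comes back empty (the cell is
#' treated as all cytoplasm) with a warning and `single_class` attribute.
#'
#' @param dapi8 8-bit nuclear-stain image (integer matrix in \[0, 255\]).
#' @param cell Logical cell mask of the same shape, with >= 1 pixel.
#' @return Logical nuclear mask (subset of `cell`), with attribute
#'   `single_class`.
#' @export
nucleus_mask <- function(dapi8, cell) {
  if (!all(dim(dapi8) == dim(cell))) abort("shape mismatch between image and mask.")
  if (!any(cell)) abort("cell mask has no foreground pixel.")
  t <- otsu_threshold(dapi8[cell])
  if (is_single_class(t)) {
    warn("nuclear stain is constant within the cell; treating cell as all cytoplasm.")
    return(structure(cell & FALSE, single_class = TRUE))
  }
  structure((dapi8 > t) & cell, single_class = FALSE)
}

#' Split a cell into nuclear and cytoplasmic compartments
#'
#' The nuclear compartment is `cell AND nucleus`, the cytoplasmic one
#' `cell AND NOT nucleus`; together they partition the cell exactly
#' (disjoint, union = cell).
#'
#' @param cell Logical cell mask.
#' @param nucleus Logical nuclear mask (intersected with `cell` first, so a
#'   nucleus leaking outside the cell is clipped).
#' @return An object of class `compartment_set`: list with logical masks
#'   `cell`, `nucleus`, `cytoplasm`.
#' @export
compartments <- function(cell, nucleus) {
  if (!all(dim(cell) == dim(nucleus))) abort("mask dimensions differ.")
  nucleus <- cell & nucleus
  structure(list(cell = cell, nucleus = nucleus, cytoplasm = cell & !nucleus),
            class = "compartment_set")
}

#' @export
print.compartment_set <- function(x, ...) {
  cat(sprintf("<compartment_set> cell %d px = nucleus %d + cytoplasm %d\n",
              sum(x$cell), sum(x$nucleus), sum(x$cytoplasm)))
  invisible(x)
}
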