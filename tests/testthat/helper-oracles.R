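# Independent oracles used across tests: deliberately naive re-derivations,
# sharing no code path with the package implementation.

# exhaustive Otsu: scan all 256 thresholds, integer arithmetic, compare
# between-class variances by cross-multiplication so ties resolve exactly
otsu_brute <- function(v) {
  v <- as.numeric(v)
  n <- length(v)
  best_t <- NA_integer_
  best_num <- -1; best_den <- 1
  for (t in 0:255) {
    a <- v[v <= t]
    b <- v[v > t]
    if (length(a) == 0 || length(b) == 0) next
    num <- (sum(v) * length(a) - n * sum(a))^2
    den <- length(a) * length(b)
    # num/den > best_num/best_den  <=>  num*best_den > best_num*den
    if (num * best_den > best_num * den) {
      best_num <- num; best_den <- den; best_t <- t
    }
  }
  best_t
}

# queue-based flood fill, labels in raster order of first pixel
bfs_components <- function(mask, connectivity = 8) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  if (connectivity == 8) {
    dy <- c(-1, -1, -1, 0, 0, 1, 1, 1); dxx <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dy <- c(-1, 1, 0, 0); dxx <- c(0, 0, -1, 1)
  }
  k <- 0L
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    k <- k + 1L
    queue <- list(c(i, j)); lab[i, j] <- k
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in seq_along(dy)) {
        yi <- p[1] + dy[d]; xi <- p[2] + dxx[d]
        if (yi >= 1 && yi <= ny && xi >= 1 && xi <= nx &&
            mask[yi, xi] && lab[yi, xi] == 0L) {
          lab[yi, xi] <- k
          queue[[length(queue) + 1L]] <- c(yi, xi)
        }
      }
    }
  }
  lab
}

# raster order above is row-major (rows outer); package labels are also
# raster-major on rows -- comparisons below only use component SETS and sizes

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# drop the single_class flag so masks compare structurally
strip_flags <- function(m) {
  attr(m, "single_class") <- NULL
  m
}

# small geometries used throughout
tiny_acq <- function() acquisition_geometry(field_pixels = c(48L, 48L),
                                            n_slices = 5L, dx = 0.4, dz = 1.2)
analysis_acq <- function() acquisition_geometry(field_pixels = c(64L, 64L),
                                                n_slices = 9L, dx = 0.28, dz = 0.655)

noiseless <- function(...) intensity_model(..., noise = "none", psf_sigma = 0)

# flattened-nucleus geometry keeping a strong marker ratio in the
# cell-vs-background Otsu regime (nuclear columns stay < ~2x cytoplasmic)
flat_nucleus_geom <- function() cell_geometry(nucleus_radii = c(3.5, 3.5, 1.0))
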