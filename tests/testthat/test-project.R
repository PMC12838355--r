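make_stack <- function(vox, channels = "marker") {
  d <- dim(vox)
  acq <- acquisition_geometry(field_pixels = d[1:2], n_slices = d[3],
                              dx = 1, dz = 1)
  image_stack(vox, acq, channels)
}

test_that("sum projection adds slices exactly and is linear", {
  v <- array(0, c(2, 2, 2, 1))
  v[, , 1, 1] <- matrix(c(1, 3, 2, 4), 2)
  v[, , 2, 1] <- matrix(c(10, 30, 20, 40), 2)
  s <- make_stack(v)
  expect_identical(sum_project(s, "marker"), matrix(c(11, 33, 22, 44), 2))

  one <- make_stack(array(v[, , 1, 1], c(2, 2, 1, 1)))
  expect_identical(sum_project(one, "marker"), v[, , 1, 1])
  expect_identical(sum_project(make_stack(array(0, c(3, 3, 4, 1))), "marker"),
                   matrix(0, 3, 3))
  expect_error(sum_project(s, "nope"), "unknown channel")

  set.seed(42)
  for (i in 1:20) {
    a <- array(sample(0:50, 3 * 4 * 5, TRUE), c(3, 4, 5, 1))
    b <- array(sample(0:50, 3 * 4 * 5, TRUE), c(3, 4, 5, 1))
    expect_identical(sum_project(make_stack(a + b), 1),
                     sum_project(make_stack(a), 1) + sum_project(make_stack(b), 1))
  }
})

test_that("8-bit rescale stretches linearly with half-up rounding", {
  expect_identical(rescale_8bit(matrix(c(10, 20, 30), 1)),
                   matrix(c(0L, 128L, 255L), 1))  # 127.5 rounds up
  expect_identical(rescale_8bit(matrix(5, 3, 3)), matrix(0L, 3, 3))
  bin <- matrix(c(0, 255, 255, 0), 2)
  expect_identical(rescale_8bit(bin), matrix(as.integer(bin), 2))

  set.seed(1)
  for (i in 1:50) {
    m <- matrix(runif(64, 0, 1000), 8)
    r <- rescale_8bit(m)
    expect_true(min(r) == 0L && max(r) == 255L)
    expect_true(all(r >= 0L & r <= 255L))
  }
})

test_that("Otsu separates a perfect bimodal image and flags constant input", {
  img <- matrix(c(rep(0L, 32), rep(255L, 32)), 8)
  t <- otsu_threshold(img)
  expect_false(is_single_class(t))
  expect_identical(img > t, img == 255L)

  t0 <- otsu_threshold(matrix(17L, 4, 4))
  expect_true(is_single_class(t0))
  expect_identical(as.integer(t0), 17L)
  expect_identical(sum(matrix(17L, 4, 4) > t0), 0L)  # empty foreground

  expect_error(otsu_threshold(matrix(300L, 2, 2)), "0, 255")
})

test_that("Otsu matches the exhaustive between-class-variance scan", {
  set.seed(123)
  for (i in 1:200) {
    img <- matrix(sample(0:255, 256, TRUE), 16)
    expect_identical(as.integer(otsu_threshold(img)), otsu_brute(img))
  }
  # low-contrast images exercise tie-breaking toward the smallest argmax
  set.seed(99)
  for (i in 1:100) {
    img <- matrix(sample(5:9, 64, TRUE), 8)
    expect_identical(as.integer(otsu_threshold(img)), otsu_brute(img))
  }
})

test_that("largest_component keeps the biggest blob with documented tie-breaks", {
  m <- matrix(FALSE, 5, 8)
  m[1:5, 2] <- TRUE            # 5-pixel blob
  m[2:4, 6] <- TRUE            # 3-pixel blob
  expect_identical(largest_component(m), m & (col(m) == 2))

  single <- matrix(FALSE, 4, 4); single[2:3, 2:3] <- TRUE
  expect_identical(largest_component(single), single)

  diagpair <- matrix(FALSE, 3, 3)
  diagpair[1, 1] <- diagpair[2, 2] <- TRUE
  expect_identical(largest_component(diagpair, connectivity = 8), diagpair)
  kept4 <- largest_component(diagpair, connectivity = 4)
  expect_identical(sum(kept4), 1L)
  expect_true(kept4[1, 1])     # tie broken by earliest raster-order pixel

  expect_warning(empty <- largest_component(matrix(FALSE, 3, 3)),
                 "no foreground")
  expect_identical(empty, matrix(FALSE, 3, 3))
})

test_that("component labelling agrees with a flood-fill oracle", {
  set.seed(7)
  for (i in 1:60) {
    m <- matrix(runif(256) < 0.4, 16)
    for (conn in c(8, 4)) {
      lab <- label_components(m, conn)
      ref <- bfs_components(m, conn)
      expect_identical(max(lab), max(ref))
      # same partition: labels must be a relabelling of each other
      expect_identical(lab > 0, ref > 0)
      if (max(ref) > 0) {
        expect_false(any(duplicated(unique(cbind(lab[m], ref[m]))[, 1])))
        if (any(m)) {
          expect_identical(suppressWarnings(largest_component(m, conn)),
                           {
                             sizes <- tabulate(ref[ref > 0])
                             ref == which.max(sizes)
                           })
        }
      }
    }
  }
})

test_that("nucleus mask recovers DAPI-defined regions inside the cell", {
  cell <- matrix(FALSE, 20, 20); cell[3:18, 3:18] <- TRUE
  dapi <- matrix(0L, 20, 20)
  disc <- (row(dapi) - 10)^2 + (col(dapi) - 10)^2 <= 16
  dapi[disc] <- 255L
  nm <- nucleus_mask(dapi, cell)
  expect_identical(strip_flags(nm), disc & cell)

  # multilobed, noiseless: mask equals the ground-truth nuclear footprint
  g <- generate_cell_stack(cell_geometry(nucleus_shape = "multilobed"),
                           noiseless(), tiny_acq(), seed = 31)
  d8 <- rescale_8bit(sum_project(g$stack, "dapi"))
  m8 <- rescale_8bit(sum_project(g$stack, "marker"))
  cellmask <- largest_component(m8 > otsu_threshold(m8))
  nm2 <- nucleus_mask(d8, cellmask)
  truth_foot <- apply(g$truth$nucleus_mask, c(1, 2), any)
  expect_identical(strip_flags(nm2), truth_foot)

  # constant stain within the cell: no nuclear contrast
  expect_warning(flat <- nucleus_mask(matrix(40L, 20, 20), cell),
                 "all cytoplasm")
  expect_true(attr(flat, "single_class"))
  expect_identical(sum(flat), 0L)
  expect_error(nucleus_mask(dapi, matrix(FALSE, 20, 20)), "no foreground")
})

test_that("compartments partition the cell exactly", {
  cell <- matrix(FALSE, 7, 7); cell[2:6, 2:6] <- TRUE
  nuc <- matrix(FALSE, 7, 7); nuc[3:5, 3:5] <- TRUE
  cs <- compartments(cell, nuc)
  expect_identical(sum(cs$cytoplasm), 16L)
  expect_identical(cs$nucleus & cs$cytoplasm, matrix(FALSE, 7, 7))
  expect_identical(cs$nucleus | cs$cytoplasm, cell)

  expect_identical(sum(compartments(cell, cell)$cytoplasm), 0L)
  expect_identical(compartments(cell, matrix(FALSE, 7, 7))$cytoplasm, cell)
  expect_error(compartments(cell, matrix(FALSE, 3, 3)), "dimensions")

  set.seed(5)
  for (i in 1:100) {
    a <- matrix(runif(144) < 0.5, 12)
    b <- matrix(runif(144) < 0.5, 12)
    cs <- compartments(a, b)
    expect_identical(sum(cs$nucleus) + sum(cs$cytoplasm), sum(a))
  }
})

test_that("cell segmentation recovers slab phantoms", {
  # noiseless: projection is piecewise constant, recovery is exact
  g <- generate_cell_stack(cell_geometry(), noiseless(), analysis_acq(),
                           seed = 17)
  m8 <- rescale_8bit(sum_project(g$stack, "marker"))
  cellmask <- largest_component(m8 > otsu_threshold(m8))
  foot <- apply(g$truth$cell_mask, c(1, 2), any)
  expect_identical(cellmask, foot)

  # sensor noise at 10% of the cytoplasmic mean barely perturbs the mask
  im <- intensity_model(noise_sigma = 9, psf_sigma = 0)
  for (seed in 1:5) {
    g <- generate_cell_stack(cell_geometry(), im, analysis_acq(), seed = seed)
    m8 <- rescale_8bit(sum_project(g$stack, "marker"))
    cellmask <- largest_component(m8 > otsu_threshold(m8))
    foot <- apply(g$truth$cell_mask, c(1, 2), any)
    expect_gte(jaccard(cellmask, foot), 0.95)
  }
})
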