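test_that("compartment histograms count non-zero pixel values exactly", {
  img <- matrix(c(0L, 3L, 3L, 7L), 2)
  h <- intensity_histogram(img, matrix(TRUE, 2, 2))
  expect_identical(h[3], 2L)
  expect_identical(h[7], 1L)
  expect_identical(sum(h), 3L)  # the zero pixel is outside the domain

  expect_identical(sum(intensity_histogram(img, matrix(FALSE, 2, 2))), 0L)
  hfull <- intensity_histogram(matrix(255L, 10, 10), matrix(TRUE, 10, 10))
  expect_identical(hfull[255], 100L)
  expect_error(intensity_histogram(img, matrix(TRUE, 3, 3)), "shape mismatch")
})

test_that("histogram_table mirrors the histogram in tidy form", {
  img <- matrix(c(0L, 3L, 3L, 7L), 2)
  tb <- histogram_table(img, matrix(TRUE, 2, 2), compartment = "nuclear")
  expect_identical(nrow(tb), 255L)
  expect_identical(tb$count[tb$k == 3], 2L)
  expect_identical(unique(tb$compartment), "nuclear")
})

test_that("N, S and MFI follow their definitions, with explicit missing values", {
  m <- compartment_metrics(matrix(c(0L, 3L, 3L, 7L), 2), matrix(TRUE, 2, 2))
  expect_identical(m$n, 3L)
  expect_identical(m$s, 13L)
  expect_equal(m$mfi, 13 / 3)

  z <- compartment_metrics(matrix(0L, 4, 4), matrix(TRUE, 4, 4))
  expect_identical(z$n, 0L)
  expect_identical(z$s, 0L)
  expect_true(is.na(z$mfi))

  const <- compartment_metrics(matrix(42L, 5, 5), matrix(TRUE, 5, 5))
  expect_identical(const$mfi, 42)
})

test_that("value-0 pixels change neither metrics nor histograms", {
  img <- matrix(c(5L, 9L, 0L, 0L, 0L, 0L), 2)
  small <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 2)
  big <- matrix(TRUE, 2, 3)  # adds only zero pixels
  expect_identical(compartment_metrics(img, small), compartment_metrics(img, big))
  expect_identical(intensity_histogram(img, small), intensity_histogram(img, big))
})

test_that("histogram identities N = sum H(k) and S = sum k H(k) hold exactly", {
  set.seed(11)
  for (i in 1:50) {
    img <- matrix(sample(0:255, 400, TRUE, prob = c(4, rep(1, 255))), 20)
    mask <- matrix(runif(400) < 0.6, 20)
    h <- intensity_histogram(img, mask)
    m <- compartment_metrics(img, mask)
    expect_identical(m$n, sum(h))
    expect_identical(m$s, sum((1:255) * h))
    if (m$n > 0) expect_true(m$mfi >= 1 && m$mfi <= 255)
  }
})

test_that("HWHM matches closed-form widths", {
  # point mass: zero width
  single <- integer(255); single[88] <- 1000L
  expect_identical(as.numeric(hwhm(single)), 0)

  # symmetric triangle peaking at 100, base 80..120: half-max at half-base
  tri <- numeric(255)
  tri[80:120] <- 20 - abs(80:120 - 100)
  expect_equal(as.numeric(hwhm(tri)), 10, tolerance = 1e-12)
  expect_equal(as.numeric(hwhm(tri, "left")), 10, tolerance = 1e-12)
  expect_equal(as.numeric(hwhm(tri, "right")), 10, tolerance = 1e-12)

  # gaussian histogram: HWHM -> sigma * sqrt(2 log 2)
  set.seed(42)
  draws <- round(rnorm(1e5, 128, 10))
  counts <- tabulate(draws[draws >= 1 & draws <= 255], 255)
  expect_equal(as.numeric(hwhm(counts)), 10 * sqrt(2 * log(2)),
               tolerance = 0.05)

  # mass piled against the domain edge: crossing clamps, truncation flagged
  edge <- numeric(255); edge[250:255] <- 100
  expect_true(attr(hwhm(edge), "truncated"))
  expect_error(hwhm(numeric(255)), "empty")
  expect_error(hwhm(numeric(10)), "length 255")
})

test_that("quantify_cell orders compartment MFIs by the generative model", {
  # strong nuclear enrichment with a flattened nucleus keeps the projection
  # in the cell-vs-background regime
  g <- generate_cell_stack(flat_nucleus_geom(),
                           noiseless(mu_nuc = 200, mu_cyt = 50),
                           tiny_acq(), seed = 2)
  q <- quantify_cell(g$stack)
  expect_gt(q$nuclear_mfi, q$cyto_mfi)
  expect_false(q$qc_no_object)

  # equal means and uniform depth: compartments agree within 2%
  g2 <- generate_cell_stack(cell_geometry(),
                            intensity_model(mu_nuc = 120, mu_cyt = 120,
                                            noise_sigma = 3, psf_sigma = 0),
                            tiny_acq(), seed = 3)
  q2 <- quantify_cell(g2$stack)
  expect_lt(abs(q2$nuclear_mfi - q2$cyto_mfi) / q2$cyto_mfi, 0.02)

  # determinism
  expect_identical(quantify_cell(g$stack), quantify_cell(g$stack))
})

test_that("noiseless blur-free quantification matches the closed-form oracle", {
  geom <- flat_nucleus_geom()
  im <- noiseless(mu_nuc = 200, mu_cyt = 50, mu_dapi = 150, background = 2)
  g <- generate_cell_stack(geom, im, analysis_acq(), seed = 19)
  q <- quantify_cell(g$stack)

  # oracle: expected projections from the truth masks and intensity model,
  # pushed through the pipeline arithmetic with the brute-force Otsu
  nz <- dim(g$truth$cell_mask)[3]
  cn <- apply(g$truth$nucleus_mask, c(1, 2), sum)
  cc <- apply(g$truth$cell_mask, c(1, 2), sum)
  proj_m <- im$mu_nuc * cn + im$mu_cyt * (cc - cn) + im$background * (nz - cc)
  proj_d <- im$mu_dapi * cn + im$background * (nz - cn)
  to8 <- function(p) {
    r <- range(p)
    floor((p - r[1]) / (r[2] - r[1]) * 255 + 0.5)
  }
  m8 <- to8(proj_m); d8 <- to8(proj_d)
  cellmask <- m8 > otsu_brute(m8)
  nucmask <- cellmask & (d8 > otsu_brute(d8[cellmask]))
  mfi_of <- function(mask) {
    v <- m8[mask]; sum(v) / sum(v > 0)
  }
  expect_lt(abs(q$nuclear_mfi / q$cyto_mfi -
                mfi_of(nucmask) / mfi_of(cellmask & !nucmask)) /
            (mfi_of(nucmask) / mfi_of(cellmask & !nucmask)), 0.01)
})

test_that("MFI ratio over many cells is seed-stable and above one", {
  geom <- flat_nucleus_geom()
  im <- intensity_model(mu_nuc = 200, mu_cyt = 50, noise_sigma = 5)
  run <- function() {
    r <- vapply(1:100, function(s) {
      q <- quantify_cell(generate_cell_stack(geom, im, tiny_acq(), seed = s)$stack)
      q$nuclear_mfi / q$cyto_mfi
    }, numeric(1))
    median(r)
  }
  m1 <- run()
  expect_gt(m1, 1)
  expect_identical(m1, run())
})

test_that("histogram breadth grows with generator noise", {
  mean_hwhm <- vapply(c(0, 2, 5, 10), function(sg) {
    im <- intensity_model(noise = if (sg == 0) "none" else "gaussian",
                          noise_sigma = sg)
    h <- vapply(1:12, function(s) {
      q <- quantify_cell(generate_cell_stack(cell_geometry(), im, tiny_acq(),
                                             seed = 100 + s)$stack)
      mean(c(q$nuclear_hwhm, q$cyto_hwhm))
    }, numeric(1))
    mean(h)
  }, numeric(1))
  expect_identical(cor(mean_hwhm, c(0, 2, 5, 10), method = "spearman"), 1)
})

test_that("degenerate stacks surface QC flags instead of errors", {
  acq <- tiny_acq()
  # constant marker channel: single-class Otsu, no object
  vox <- array(0, c(acq$ny, acq$nx, acq$n_slices, 2L))
  vox[, , , 2] <- 5
  vox[20:30, 20:30, , 1] <- 100  # some DAPI signal
  q <- suppressWarnings(quantify_cell(image_stack(vox, acq)))
  expect_true(q$qc_marker_single_class)
  expect_true(q$qc_no_object)
  expect_true(is.na(q$nuclear_mfi) && is.na(q$cyto_mfi))

  # all-zero stack
  q0 <- suppressWarnings(
    quantify_cell(image_stack(array(0, c(acq$ny, acq$nx, acq$n_slices, 2L)), acq)))
  expect_true(q0$qc_no_object)

  # tiny foreground trips the low-N flag
  vox2 <- array(0, c(acq$ny, acq$nx, acq$n_slices, 2L))
  vox2[24:25, 24:25, , 2] <- 50
  vox2[24, 24, , 1] <- 80
  q2 <- suppressWarnings(quantify_cell(image_stack(vox2, acq)))
  expect_true(q2$qc_low_n_nuclear || q2$qc_low_n_cyto)
})
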