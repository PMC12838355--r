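#' Configuration for a surrogate cohort replication run
#'
#' Bundles everything [run_replication()] needs: the cohort design (default:
#' two age groups x 8 donors x 30 cells x one cell type x one marker = 480
#' cells, the canonical cohort shape), acquisition geometry (default: an
#' analysis-scale sampling of 64 x 64 px at 0.28 um and 9 slices at 0.655
#' um, a 4x-binned version of the full single-cell geometry that keeps a
#' 480-cell cohort tractable), quantification settings, the comparison test,
#' and an optional planted effect.
#'
#' @param seed Master seed; overrides the design's seed.
#' @param design A [cohort_design()].
#' @param acq An [acquisition_geometry()].
#' @param quant A [quant_config()].
#' @param response,test,alpha Passed to [compartment_report()].
#' @param planted_effect `NULL` for a null run (both groups share identical
#'   generator parameters), or a list with elements `marker` and `factor`
#'   passed to [plant_translocation()] against the second group.
#' @param out_dir Optional output directory for CSVs and the manifest.
#' @return A list of class `replication_config`.
#' @export
replication_config <- function(seed = 1L,
                               design = cohort_design(seed = seed),
                               acq = acquisition_geometry(
                                 field_pixels = c(64L, 64L), n_slices = 9L,
                                 dx = 0.28, dz = 0.655),
                               quant = quant_config(),
                               response = "mfi",
                               test = "mann_whitney",
                               alpha = 0.05,
                               planted_effect = NULL,
                               out_dir = NULL) {
  design$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), design = design, acq = acq,
                 quant = quant, response = response, test = test,
                 alpha = alpha, planted_effect = planted_effect,
                 out_dir = out_dir),
            class = "replication_config")
}

#' Run the surrogate cohort experiment end to end
#'
#' Generates a two-group synthetic cohort (by default a null scenario:
#' identical generator parameters in both groups), quantifies every cell,
#' and produces the stratified junior-vs-senior compartment report. With a
#' planted effect, the second group's cytoplasmic marker mean is rescaled
#' first. When the configuration has an `out_dir`, `records.csv`,
#' `report.csv` and `manifest.json` are written there; the run is
#' deterministic for a fixed seed, so repeated runs produce byte-identical
#' CSVs.
#'
#' @param config A [replication_config()].
#' @return A list with `records` (per-cell tibble), `report` (stratified
#'   comparison tibble) and `manifest` (config snapshot, package version,
#'   output checksums, QC warning counts).
#' @export
run_replication <- function(config = replication_config()) {
  stopifnot(inherits(config, "replication_config"))
  design <- config$design
  if (!is.null(config$planted_effect)) {
    pe <- config$planted_effect
    design <- plant_translocation(
      design, group = pe$group %||% design$groups[length(design$groups)],
      marker = pe$marker %||% design$markers[1],
      factor = pe$factor %||% 2)
  }
  records <- quantify_cohort(design, config$acq, config$quant)
  report <- compartment_report(records, response = config$response,
                               test = config$test, alpha = config$alpha)
  qc_cols <- grep("^qc_", names(records), value = TRUE)
  warnings <- lapply(records[qc_cols], function(x) sum(x, na.rm = TRUE))
  manifest <- list(
    package = "nucyto",
    version = as.character(utils::packageVersion("nucyto")),
    seed = config$seed,
    n_records = nrow(records),
    design = list(groups = design$groups,
                  n_donors_per_group = design$n_donors_per_group,
                  cell_types = design$cell_types, markers = design$markers,
                  cells_per_donor = design$cells_per_donor),
    planted_effect = config$planted_effect,
    test = config$test, response = config$response, alpha = config$alpha,
    qc_warnings = warnings)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    rec_path <- file.path(config$out_dir, "records.csv")
    rep_path <- file.path(config$out_dir, "report.csv")
    readr::write_csv(records, rec_path)
    readr::write_csv(report, rep_path)
    manifest$checksums <- as.list(tools::md5sum(c(rec_path, rep_path)))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(records = records, report = report, manifest = manifest)
}

#' Write a small corpus of test fixtures
#'
#' Generates a dozen tiny phantom stacks spanning the pipeline's regimes --
#' noiseless and noisy, round / kidney / multilobed nuclei, Poisson noise,
#' blur, equal nuclear and cytoplasmic means, a strong nuclear:cytoplasmic
#' ratio with a flattened nucleus, a constant marker channel, and an all-zero
#' stack with no foreground -- each with ground-truth masks and a labels
#' table. Regeneration with the same seed is file-identical.
#'
#' @param out_dir Writable directory.
#' @param seed Master seed for the corpus.
#' @return Tibble of fixture names and stack paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acq <- acquisition_geometry(field_pixels = c(48L, 48L), n_slices = 5L,
                              dx = 0.4, dz = 1.2)
  base <- function(...) intensity_model(...)
  specs <- list(
    round_noiseless = list(cell_geometry(), base(noise = "none", psf_sigma = 0)),
    kidney_noiseless = list(cell_geometry(nucleus_shape = "kidney"),
                            base(noise = "none", psf_sigma = 0)),
    multilobed_noiseless = list(cell_geometry(nucleus_shape = "multilobed"),
                                base(noise = "none", psf_sigma = 0)),
    round_noisy = list(cell_geometry(), base()),
    poisson_noise = list(cell_geometry(), base(noise = "poisson")),
    blurred = list(cell_geometry(), base(noise = "none", psf_sigma = 0.3)),
    equal_mu = list(cell_geometry(), base(mu_nuc = 120, mu_cyt = 120,
                                          noise_sigma = 3)),
    noiseless_ratio4 = list(
      cell_geometry(nucleus_radii = c(3.5, 3.5, 1.0)),
      base(mu_nuc = 200, mu_cyt = 50, noise = "none", psf_sigma = 0)),
    high_noise = list(cell_geometry(), base(noise_sigma = 25)),
    offcenter = list(cell_geometry(center_jitter = 2.5), base()),
    monocyte_noisy = list(cell_geometry(nucleus_shape = "kidney"), base()),
    granulocyte_noisy = list(cell_geometry(nucleus_shape = "multilobed"), base())
  )
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, length(specs) + 1L))
  rows <- purrr::imap(specs, function(sp, name) {
    i <- match(name, names(specs))
    g <- generate_cell_stack(sp[[1]], sp[[2]], acq, seed = seeds[i])
    path <- file.path(out_dir, paste0(name, ".tif"))
    write_stack(g$stack, path)
    write_mask(g$truth$cell_mask,
               file.path(out_dir, paste0(name, "_cell_mask.tif")))
    write_mask(g$truth$nucleus_mask,
               file.path(out_dir, paste0(name, "_nucleus_mask.tif")))
    tibble(name = name, stack_path = path, seed = seeds[i])
  })
  # degenerate input the generator refuses to make: nothing in the field
  zero <- image_stack(array(0, c(acq$ny, acq$nx, acq$n_slices, 2L)), acq)
  zpath <- file.path(out_dir, "empty_foreground.tif")
  write_stack(zero, zpath)
  rows <- c(rows, list(tibble(name = "empty_foreground", stack_path = zpath,
                              seed = seeds[length(seeds)])))
  tbl <- dplyr::bind_rows(rows)
  # the index stores paths relative to the corpus directory so that two
  # corpora generated from one seed are file-identical
  idx <- dplyr::mutate(tbl, stack_path = basename(.data$stack_path))
  readr::write_csv(idx, file.path(out_dir, "fixtures.csv"))
  invisible(tbl)
}
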