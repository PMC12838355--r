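#' Cohort label table
#'
#' Expands a [cohort_design()] into one row per cell to image, with a
#' deterministic per-stack seed derived from the design's master seed.
#'
#' @param design A [cohort_design()].
#' @return A tibble with columns `cell_id`, `group`, `donor`, `cell_type`,
#'   `marker`, `cell_index`, `seed`.
#' @export
cohort_labels <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  labs <- tidyr::expand_grid(
    group = design$groups,
    donor_index = seq_len(design$n_donors_per_group),
    cell_type = design$cell_types,
    marker = design$markers,
    cell_index = seq_len(design$cells_per_donor)
  )
  labs <- dplyr::mutate(
    labs,
    donor = paste0(.data$group, "_D", .data$donor_index),
    cell_id = sprintf("%s_%s_%s_c%02d", .data$donor, .data$cell_type,
                      .data$marker, .data$cell_index)
  )
  seeds <- withr::with_seed(design$seed,
                            sample.int(.Machine$integer.max - 1L, nrow(labs)))
  labs$seed <- seeds
  dplyr::select(labs, "cell_id", "group", "donor", "cell_type", "marker",
                "cell_index", "seed")
}

#' Generate a full synthetic cohort
#'
#' Materializes every stack of a [cohort_design()], either in memory or as
#' multi-page TIFF files with ground-truth masks and a labels table. For
#' large cohorts prefer `out_dir` (or [quantify_cohort()], which streams
#' stacks without retaining them).
#'
#' @param design A [cohort_design()].
#' @param acq An [acquisition_geometry()] shared by all stacks.
#' @param out_dir Optional directory; when given, stacks are written as
#'   `<cell_id>.tif` (with `_cell_mask.tif` / `_nucleus_mask.tif` truth
#'   files and a JSON sidecar) plus `labels.csv`, and file paths are
#'   returned in place of in-memory stacks.
#' @return The label tibble; unless `out_dir` is given it carries list
#'   columns `stack` and `truth`, otherwise a `stack_path` column.
#' @export
generate_cohort <- function(design, acq = acquisition_geometry(),
                            out_dir = NULL) {
  labs <- cohort_labels(design)
  gen <- function(row) {
    generate_cell_stack(design$geometry[[row$cell_type]],
                        design$intensity[[row$group]][[row$marker]],
                        acq, seed = row$seed)
  }
  if (is.null(out_dir)) {
    out <- purrr::pmap(labs, function(...) gen(list(...)))
    labs$stack <- purrr::map(out, "stack")
    labs$truth <- purrr::map(out, "truth")
    return(labs)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labs$stack_path <- vapply(seq_len(nrow(labs)), function(i) {
    row <- as.list(labs[i, ])
    g <- gen(row)
    path <- file.path(out_dir, paste0(row$cell_id, ".tif"))
    write_stack(g$stack, path)
    write_mask(g$truth$cell_mask,
               file.path(out_dir, paste0(row$cell_id, "_cell_mask.tif")))
    write_mask(g$truth$nucleus_mask,
               file.path(out_dir, paste0(row$cell_id, "_nucleus_mask.tif")))
    path
  }, character(1))
  readr::write_csv(dplyr::select(labs, "stack_path", "cell_id", "group",
                                 "donor", "cell_type", "marker", "seed"),
                   file.path(out_dir, "labels.csv"))
  labs
}
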