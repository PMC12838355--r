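#' Stratified two-group compartment report
#'
#' Summarizes a quantification table the way an age-group imaging comparison
#' is reported: for every marker, cell type and compartment (nuclear /
#' cytoplasmic), the two groups are contrasted on the chosen metric with
#' descriptive medians, the test p-value, significance stars and flag.
#' Strata with too few observations are listed with a note rather than
#' fabricated; empty input yields an empty report.
#'
#' Cells are treated as independent observations by default, as implied by
#' cohort counts quoted per cell rather than per donor. Because 30 cells per
#' donor are pseudo-replicates of that donor, `by_donor = TRUE` first
#' collapses each donor to the median of its cells and tests donors instead.
#'
#' @param records Quantification tibble (from [quantify_cohort()] or
#'   [quantify_cell()]) with `group`, `cell_type`, `marker` labels.
#' @param response Metric to compare: `"mfi"`, `"hwhm"`, `"n"` or `"s"`.
#' @param test `"mann_whitney"` (default, matching a two-group contrast) or
#'   `"anova_tukey"`.
#' @param alpha Significance level.
#' @param by_donor Collapse cells to per-donor medians before testing.
#' @return A tibble with one row per (marker, cell_type, compartment):
#'   group sizes, medians, statistic, p-value, stars, `significant`, `note`.
#' @export
compartment_report <- function(records,
                               response = c("mfi", "hwhm", "n", "s"),
                               test = c("mann_whitney", "anova_tukey"),
                               alpha = 0.05, by_donor = FALSE) {
  response <- match.arg(response)
  test <- match.arg(test)
  empty <- tibble(marker = character(), cell_type = character(),
                  compartment = character(), response = character(),
                  group1 = character(), group2 = character(),
                  n1 = integer(), n2 = integer(),
                  median1 = numeric(), median2 = numeric(),
                  statistic = numeric(), p.value = numeric(),
                  stars = character(), significant = logical(),
                  note = character())
  if (nrow(records) == 0) return(empty)
  for (col in c("group", "cell_type", "marker", "donor")) {
    if (!col %in% names(records)) abort(sprintf("records lack a '%s' column.", col))
  }
  long <- tidyr::pivot_longer(
    records,
    cols = dplyr::all_of(paste0(c("nuclear_", "cyto_"), response)),
    names_to = "compartment", values_to = ".value_")
  long$compartment <- ifelse(startsWith(long$compartment, "nuclear"),
                             "nuclear", "cytoplasmic")
  if (by_donor) {
    long <- dplyr::summarise(
      dplyr::group_by(long, .data$marker, .data$cell_type, .data$compartment,
                      .data$group, .data$donor),
      .value_ = median(.data$.value_, na.rm = TRUE), .groups = "drop")
  }
  groups <- sort(unique(as.character(records$group)))
  if (length(groups) != 2L) abort("the report contrasts exactly 2 groups.")

  strata <- dplyr::group_split(
    dplyr::group_by(long, .data$marker, .data$cell_type, .data$compartment))
  rows <- purrr::map(strata, function(d) {
    x1 <- d$.value_[d$group == groups[1] & !is.na(d$.value_)]
    x2 <- d$.value_[d$group == groups[2] & !is.na(d$.value_)]
    out <- tibble(marker = d$marker[1], cell_type = d$cell_type[1],
                  compartment = d$compartment[1], response = response,
                  group1 = groups[1], group2 = groups[2],
                  n1 = length(x1), n2 = length(x2),
                  median1 = if (length(x1)) median(x1) else NA_real_,
                  median2 = if (length(x2)) median(x2) else NA_real_,
                  statistic = NA_real_, p.value = NA_real_,
                  stars = NA_character_, significant = NA,
                  note = NA_character_)
    if (length(x1) < 2 || length(x2) < 2) {
      out$note <- "insufficient data"
      return(out)
    }
    cmp <- compare_groups(
      data.frame(v = c(x1, x2),
                 g = rep(groups, c(length(x1), length(x2)))),
      "v", "g", test = test, alpha = alpha)
    out$statistic <- cmp$omnibus$statistic
    out$p.value <- cmp$omnibus$p.value
    out$stars <- p_stars(out$p.value)
    out$significant <- out$p.value < alpha
    out
  })
  dplyr::bind_rows(rows)
}
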