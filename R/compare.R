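#' Significance stars
#'
#' Conventional significance labels: `****` below 1e-4, `***` below 1e-3,
#' `**` below 0.01, `*` below 0.05, otherwise `ns`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- max(n1, n2) <= 20 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = if (exact) "mann_whitney_exact" else "mann_whitney_normal")
}

#' Compare a metric between groups
#'
#' Cohort-level comparison of a per-cell metric (HWHM, MFI, N or S) across
#' groups. Two tests are available: one-way ANOVA with Tukey's HSD for
#' all-pairs post-hoc comparisons, and the two-sided Mann-Whitney U test for
#' exactly two groups (exact enumeration up to group size 20 without ties,
#' normal approximation with continuity and tie correction otherwise).
#' Missing responses are dropped and counted.
#'
#' @param data A data frame (for example from [quantify_cohort()]).
#' @param response Name of the response column.
#' @param group Name of the grouping column (>= 2 levels after dropping
#'   missing responses; a group whose responses are all missing is an error).
#' @param test `"mann_whitney"` or `"anova_tukey"`.
#' @param alpha Significance level for the `significant` flags.
#' @return An object of class `group_comparison` with omnibus and pairwise
#'   results; see [tidy.group_comparison()] and [glance.group_comparison()].
#' @examples
#' df <- data.frame(v = c(rnorm(20), rnorm(20, 2)),
#'                  g = rep(c("a", "b"), each = 20))
#' cmp <- compare_groups(df, "v", "g")
#' tidy(cmp)
#' @export
compare_groups <- function(data, response, group,
                           test = c("mann_whitney", "anova_tukey"),
                           alpha = 0.05) {
  test <- match.arg(test)
  if (!response %in% names(data)) abort(sprintf("no column '%s' in `data`.", response))
  if (!group %in% names(data)) abort(sprintf("no column '%s' in `data`.", group))
  if (!isTRUE(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1).")
  g_all <- factor(data[[group]])
  x_all <- data[[response]]
  ok <- !is.na(x_all)
  dropped <- sum(!ok)
  all_missing <- setdiff(levels(g_all), unique(as.character(g_all[ok])))
  if (length(all_missing)) {
    abort(sprintf("group(s) with all-missing response: %s",
                  paste(all_missing, collapse = ", ")))
  }
  x <- x_all[ok]
  g <- droplevels(g_all[ok])
  if (nlevels(g) < 2L) abort("need at least 2 groups.")
  n_tbl <- dplyr::count(tibble(group = g), .data$group, name = "n")
  if (any(n_tbl$n < 2L)) abort("every group needs >= 2 non-missing observations.")

  if (test == "mann_whitney") {
    if (nlevels(g) != 2L) abort("mann_whitney requires exactly 2 groups.")
    lv <- levels(g)
    x1 <- x[g == lv[1]]; x2 <- x[g == lv[2]]
    mw <- mann_whitney(x1, x2)
    omnibus <- tibble(statistic = mw$statistic, p.value = mw$p.value,
                      method = mw$method)
    pairwise <- tibble(group1 = lv[1], group2 = lv[2],
                       estimate = median(x1) - median(x2),
                       p.value = mw$p.value, p.adjust = mw$p.value,
                       significant = mw$p.value < alpha)
  } else {
    fit <- aov(x ~ g)
    an <- summary(fit)[[1]]
    omnibus <- tibble(statistic = an[["F value"]][1],
                      p.value = an[["Pr(>F)"]][1],
                      df = an[["Df"]][1], df.residual = an[["Df"]][2],
                      method = "anova")
    tk <- TukeyHSD(fit)$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- tibble(
      group1 = vapply(pairs, `[`, "", 1),
      group2 = vapply(pairs, `[`, "", 2),
      estimate = tk[, "diff"],
      conf.low = tk[, "lwr"], conf.high = tk[, "upr"],
      p.adjust = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha)
  }
  structure(
    list(test = test, response = response, group = group, alpha = alpha,
         n = n_tbl, omnibus = omnibus, pairwise = pairwise,
         dropped = dropped, data = tibble(group = g, value = x)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s of %s by %s (%s)\n", x$test, x$response,
              x$group, paste(sprintf("%s n=%d", x$n$group, x$n$n), collapse = ", ")))
  cat(sprintf("  omnibus: statistic = %.4g, p = %.4g %s\n",
              x$omnibus$statistic, x$omnibus$p.value, p_stars(x$omnibus$p.value)))
  if (x$dropped > 0) cat(sprintf("  (%d missing responses dropped)\n", x$dropped))
  print(tidy(x))
  invisible(x)
}

#' Tidy pairwise comparisons
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble of pairwise contrasts with adjusted p-values, significance
#'   stars and flags.
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, stars = p_stars(.data$p.adjust))
}

#' One-row comparison summary
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble: test, omnibus statistic and p-value, group count,
#'   total n and number of dropped missing responses.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$omnibus$statistic,
         p.value = x$omnibus$p.value, n_groups = nrow(x$n),
         n_total = sum(x$n$n), dropped = x$dropped)
}

#' Plot a group comparison
#'
#' Box-and-jitter plot of the response by group, annotated with the omnibus
#' p-value and its significance stars.
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = object$group, y = object$response,
      subtitle = sprintf("%s: p = %.3g (%s)", object$test,
                         object$omnibus$p.value,
                         p_stars(object$omnibus$p.value))) +
    ggplot2::theme_minimal()
}
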