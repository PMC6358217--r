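#' Two-sided Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()] with the conventions used for per-oocyte
#' metric comparisons: two-sided; exact null distribution when the combined
#' sample size is at most `exact_limit` and there are no ties; otherwise the
#' normal approximation with tie and continuity correction. The method
#' actually used is recorded, and the p value is mapped to the usual
#' significance stars.
#'
#' @param x,y Numeric samples (n >= 1 each).
#' @param exact_limit Combined-size cutoff for the exact test.
#' @return An `mw_test` object: `u_statistic` (U for `x`), `p_value`,
#'   `method` (`"exact"` or `"normal-approximation"`), `stars`.
#' @export
mw_test <- function(x, y, exact_limit = 16) {
  if (length(x) < 1 || length(y) < 1) abort("Invalid input: empty sample.")
  if (any(!is.finite(c(x, y)))) abort("Samples must be finite.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_limit && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  p <- min(1, wt$p.value)
  structure(
    list(
      u_statistic = unname(wt$statistic),
      p_value = p,
      method = if (exact) "exact" else "normal-approximation",
      stars = p_stars(p),
      n1 = length(x),
      n2 = length(y)
    ),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g (%s) %s\n",
              x$u_statistic, x$n1, x$n2, x$p_value, x$method, x$stars))
  invisible(x)
}

#' @rdname mw_test
#' @param ... Unused.
#' @export
tidy.mw_test <- function(x, ...) {
  tibble(u_statistic = x$u_statistic, p_value = x$p_value,
         method = x$method, stars = x$stars, n1 = x$n1, n2 = x$n2)
}

#' Significance stars
#'
#' `p < 0.0001` gives `"****"`, `< 0.001` `"***"`, `< 0.01` `"**"`,
#' `< 0.05` `"*"`, otherwise `"NS"`.
#'
#' @param p P value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "NS"
  )
}

#' Group summaries with SEM and Tukey box-plot statistics
#'
#' Per-group mean, standard error of the mean (sample SD over the square
#' root of n; 0 with a flag when n = 1), median, type-7 quartiles and Tukey
#' whiskers (the most extreme data within 1.5 IQR of the quartiles).
#'
#' @param data A data frame of per-oocyte metrics.
#' @param value Column to summarise (tidy-eval).
#' @param ... Grouping columns (tidy-eval), e.g. `genotype, stage`.
#' @return A tibble with one row per group.
#' @export
summarize_groups <- function(data, value, ...) {
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sem = ifelse(dplyr::n() > 1, sd({{ value }}) / sqrt(dplyr::n()), 0),
      sem_undefined = dplyr::n() == 1,
      median = median({{ value }}),
      q1 = quantile({{ value }}, 0.25, names = FALSE),
      q3 = quantile({{ value }}, 0.75, names = FALSE),
      whisker_low = {
        v <- {{ value }}
        lo <- quantile(v, 0.25, names = FALSE)
        hi <- quantile(v, 0.75, names = FALSE)
        min(v[v >= lo - 1.5 * (hi - lo)])
      },
      whisker_high = {
        v <- {{ value }}
        lo <- quantile(v, 0.25, names = FALSE)
        hi <- quantile(v, 0.75, names = FALSE)
        max(v[v <= hi + 1.5 * (hi - lo)])
      },
      .groups = "drop"
    )
}

#' Pairwise Mann-Whitney comparisons across groups
#'
#' Runs [mw_test()] for every pair of levels of `group` (no multiplicity
#' correction, matching the original analysis).
#'
#' @param data Data frame.
#' @param value Metric column (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return Tibble of pairwise results: `group1`, `group2`, `n1`, `n2`,
#'   `u_statistic`, `p_value`, `method`, `stars`.
#' @export
compare_groups <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  levs <- levels(droplevels(g))
  if (length(levs) < 2) abort("Need at least two groups to compare.")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    res <- mw_test(v[g == pr[1]], v[g == pr[2]])
    dplyr::bind_cols(tibble(group1 = pr[1], group2 = pr[2]), tidy(res))
  })
}
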