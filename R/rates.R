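# Time calibration and chi-square machinery for comparing per-branch
# pseudogenization counts.

#' Time calibration for the lineage comparison
#'
#' @param divergence_mya Age of the ingroup/autosome split in My
#'   (default 2).
#' @param emergence_mya Age of the neo-sex chromosomes in My (default 1;
#'   1.5 is the alternative calibration).
#' @return A list of class `np_calibration`.
#' @export
time_calibration <- function(divergence_mya = 2, emergence_mya = 1) {
  if (!(emergence_mya > 0 && emergence_mya <= divergence_mya)) {
    abort("need 0 < emergence_mya <= divergence_mya")
  }
  structure(list(divergence_mya = divergence_mya,
                 emergence_mya = emergence_mya),
            class = "np_calibration")
}

#' Split lineage events into pre/post neo-sex windows
#'
#' Events on the autosomal comparison lineage are prorated linearly in time
#' (a constant pseudogenization rate): the post window, comparable to the
#' neo-sex branches, receives `events * emergence / divergence`; the rest is
#' the pre window. Fractional event counts are kept.
#'
#' @param pse_events Number of events on the comparison lineage (>= 0).
#' @param calibration A [time_calibration()].
#' @return A one-row tibble with `pre_window` and `post_window`.
#' @export
split_lineage_events <- function(pse_events,
                                 calibration = time_calibration()) {
  if (!inherits(calibration, "np_calibration")) {
    abort("`calibration` must come from time_calibration()")
  }
  if (pse_events < 0) abort("`pse_events` must be non-negative")
  post <- pse_events * calibration$emergence_mya / calibration$divergence_mya
  tibble(pre_window = pse_events - post, post_window = post)
}

.np_chi2 <- function(statistic, df, method, comparison = NULL) {
  structure(list(statistic = statistic, df = df,
                 p_value = chi2_upper_tail(statistic, df),
                 method = method, comparison = comparison),
            class = "np_chi2")
}

#' @export
print.np_chi2 <- function(x, ...) {
  cat(sprintf("%s: chi2 = %.1f, d.f. = %d, P = %.3g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.np_chi2 <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         method = x$method)
}

#' @export
glance.np_chi2 <- function(x, ...) tidy(x)

#' Equal-expectation goodness-of-fit on two counts
#'
#' One-degree-of-freedom chi-square goodness-of-fit of two observed counts
#' against equal expectation `(a + b) / 2`. Fractional counts (as produced
#' by the time-calibration split) are accepted without rounding; no
#' continuity correction is applied.
#'
#' @param a,b Non-negative counts (possibly fractional); `a + b > 0`.
#' @return An `np_chi2` object (statistic, df, upper-tail p-value).
#' @examples
#' chi2_gof2(168, 100.5) # prints 17.0
#' @export
chi2_gof2 <- function(a, b) {
  if (a < 0 || b < 0 || a + b == 0) {
    abort("counts must be non-negative with a positive sum")
  }
  e <- (a + b) / 2
  stat <- (a - e)^2 / e + (b - e)^2 / e
  .np_chi2(stat, 1L, "two-count goodness-of-fit")
}

#' Pearson chi-square on a 2x2 table
#'
#' Expected counts are derived from the row and column marginals; no
#' continuity correction is applied.
#'
#' @param table A 2x2 numeric matrix of non-negative counts with positive
#'   marginals.
#' @return An `np_chi2` object with one degree of freedom.
#' @examples
#' chi2_2x2(matrix(c(29, 16, 51, 13), 2)) # prints 3.1, P = 0.076
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    abort("`table` must be a 2x2 matrix of non-negative counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("all row and column marginals must be positive")
  }
  e <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum((table - e)^2 / e)
  .np_chi2(stat, 1L, "Pearson chi-square (2x2, no correction)")
}

#' Upper-tail probability of the chi-square distribution
#'
#' @param x Statistic (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return The survival probability `P(Chi2_df >= x)`.
#' @export
chi2_upper_tail <- function(x, df) {
  if (x < 0 || df < 1) abort("need x >= 0 and df >= 1")
  pchisq(x, df = df, lower.tail = FALSE)
}

#' Percentage of at-risk genes pseudogenized on a branch
#'
#' @param n_events Event count (possibly fractional).
#' @param n_groups At-risk denominator (> 0).
#' @return `100 * n_events / n_groups`.
#' @export
branch_proportion <- function(n_events, n_groups) {
  if (n_groups <= 0) abort("`n_groups` must be positive")
  100 * n_events / n_groups
}

#' Pairwise branch-rate comparisons
#'
#' Compares time-comparable event counts between branch pairs with the
#' equal-expectation goodness-of-fit test. The comparison-lineage (`Pse`)
#' count is prorated to the post-emergence window first, so all compared
#' counts cover the same time span.
#'
#' @param counts Per-branch counts from [count_events()].
#' @param calibration A [time_calibration()].
#' @param pairs List of 2-element character vectors of branch names
#'   (default: X vs Y, X vs Pse, X vs Anc).
#' @return A tibble with one row per comparison: branches, the compared
#'   counts, percentages of the at-risk denominator, statistic, df and
#'   p-value.
#' @export
compare_branch_rates <- function(counts, calibration = time_calibration(),
                                 pairs = list(c("X", "Y"), c("X", "Pse"),
                                              c("X", "Anc"))) {
  get_count <- function(branch) {
    n <- counts$n_events[counts$branch == branch]
    if (branch == "Pse") {
      n <- split_lineage_events(n, calibration)$post_window
    }
    n
  }
  n_at_risk <- counts$n_groups_at_risk[1]
  purrr::map_dfr(pairs, function(pr) {
    a <- get_count(pr[1])
    b <- get_count(pr[2])
    if (a + b == 0) {
      return(tibble(branch_a = pr[1], branch_b = pr[2], count_a = a,
                    count_b = b, pct_a = 0, pct_b = 0,
                    statistic = NA_real_, df = 1L, p_value = NA_real_))
    }
    test <- chi2_gof2(a, b)
    tibble(
      branch_a = pr[1], branch_b = pr[2],
      count_a = a, count_b = b,
      pct_a = if (is.na(n_at_risk)) NA_real_ else branch_proportion(a, n_at_risk),
      pct_b = if (is.na(n_at_risk)) NA_real_ else branch_proportion(b, n_at_risk),
      statistic = test$statistic, df = test$df, p_value = test$p_value
    )
  })
}
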