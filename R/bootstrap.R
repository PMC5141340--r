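# Monte-Carlo bootstrap test for a difference in medians between two
# groups of per-gene values (dN/dS ratios, F/M ratios, ...).

#' Bootstrap test for a difference in medians
#'
#' Resamples each group with replacement `reps` times, forms the bootstrap
#' distribution of `median(A*) - median(B*)`, and reports a two-sided
#' p-value `2 * min(P(diff <= 0), P(diff >= 0))` clamped to
#' `[1/reps, 1]`. Non-finite values (e.g. undefined dN/dS) are dropped and
#' counted.
#'
#' @param values_a,values_b Numeric vectors (non-empty after dropping
#'   non-finite values).
#' @param reps Bootstrap replicates (default 1000; fewer than 100 warns).
#' @param seed Optional integer seed for a reproducible resampling stream;
#'   `NULL` uses the current RNG state.
#' @return An object of class `np_boot_median` with the observed median
#'   difference, the p-value, replicate count and sample sizes.
#' @export
bootstrap_median_test <- function(values_a, values_b, reps = 1000,
                                  seed = NULL) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  n_dropped <- (length(values_a) - length(a)) + (length(values_b) - length(b))
  if (length(a) == 0 || length(b) == 0) {
    abort("both samples must be non-empty after dropping non-finite values")
  }
  if (reps < 100) warn("fewer than 100 bootstrap replicates is unreliable")
  run <- function() {
    diffs <- vapply(seq_len(reps), function(i) {
      median(sample(a, length(a), replace = TRUE)) -
        median(sample(b, length(b), replace = TRUE))
    }, numeric(1))
    p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
    min(max(p, 1 / reps), 1)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(
    estimate = median(a) - median(b),
    p_value = p, reps = reps,
    n_a = length(a), n_b = length(b), n_dropped = n_dropped
  ), class = "np_boot_median")
}

#' @export
print.np_boot_median <- function(x, ...) {
  cat(sprintf(
    "bootstrap median difference: %.4g (n = %d vs %d), P = %.3g (%d reps)\n",
    x$estimate, x$n_a, x$n_b, x$p_value, x$reps))
  invisible(x)
}

#' @export
tidy.np_boot_median <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p_value, reps = x$reps,
         n_a = x$n_a, n_b = x$n_b, n_dropped = x$n_dropped)
}

#' @export
glance.np_boot_median <- function(x, ...) tidy(x)
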