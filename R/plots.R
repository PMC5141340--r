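# ggplot2 views of the main result types.

#' Bar chart of per-branch pseudogenization rates
#'
#' @param counts Per-branch counts from [count_events()].
#' @param calibration A [time_calibration()]; the comparison-lineage count
#'   is prorated to the post-emergence window before plotting.
#' @return A ggplot object.
#' @export
plot_branch_rates <- function(counts, calibration = time_calibration()) {
  df <- counts[counts$branch %in% c("Anc", "X", "Y", "Pse"), ]
  df$n_plot <- ifelse(
    df$branch == "Pse",
    split_lineage_events(df$n_events[df$branch == "Pse"],
                         calibration)$post_window,
    df$n_events)
  df$pct <- 100 * df$n_plot / df$n_groups_at_risk
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$branch, levels = c("Anc", "X", "Y", "Pse")),
    y = .data$pct)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "branch", y = "% of at-risk genes pseudogenized") +
    ggplot2::theme_minimal()
}

#' Boxplot of F/M expression ratios by category (log scale)
#'
#' @param object An `np_fm_comparison` from [compare_fm_by_category()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.np_fm_comparison <- function(object, ...) {
  ggplot2::ggplot(object$values,
                  ggplot2::aes(x = .data$category, y = .data$fm_ratio)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = sprintf("F/M expression ratio (%s)",
                                        object$tissue)) +
    ggplot2::theme_minimal()
}

#' Boxplot of branch dN/dS by functionality category
#'
#' @param dnds Tibble from [dnds_by_group()] (needs a `category` column).
#' @param branches Branches to facet over (default Anc, X, Y).
#' @return A ggplot object.
#' @export
plot_dnds_by_category <- function(dnds, branches = c("Anc", "X", "Y")) {
  df <- dnds[dnds$branch %in% branches & is.finite(dnds$omega), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$omega)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~branch) +
    ggplot2::labs(x = NULL, y = "dN/dS") +
    ggplot2::theme_minimal()
}

#' Pseudogene:functional ratio by tissue of maximum expression
#'
#' @param ratios Tibble from [pseudo_functional_ratio_by_tissue()].
#' @return A ggplot object with bootstrap CI error bars.
#' @export
plot_tissue_pseudo_ratio <- function(ratios) {
  df <- ratios[is.finite(ratios$ratio), ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$tissue,
                                                      -.data$ratio),
                                   y = .data$ratio)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi),
                           width = 0.2) +
    ggplot2::labs(x = "tissue of maximum expression",
                  y = "pseudogene : functional ratio") +
    ggplot2::theme_minimal()
}
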