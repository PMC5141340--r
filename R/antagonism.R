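# Sexual-antagonism contingency analysis: do genes with female-benefit/
# male-detriment effects pseudogenize preferentially on the neo-X?

#' Functionality x sexual-antagonism contingency analysis
#'
#' Cross-tabulates neo-X functionality (functional vs pseudogene) against
#' sexual-antagonism labels transferred by homology (`Fb_Md`
#' female-benefit/male-detriment, `Mb_Fd` male-benefit/female-detriment,
#' `no_conflict`, `unclassified`). Groups without a label are counted as
#' `unclassified`; groups whose neo-X call is itself unclassified are
#' excluded. The chi-square test (Pearson, no continuity correction) is run
#' on the 2x2 sub-table of the two antagonism classes; the `no_conflict`
#' and `unclassified` columns appear in the table but not in the test.
#'
#' @param calls Classification tibble from [classify_genes()] (the neo-X
#'   rows are used).
#' @param labels Tibble `group_id`, `label`.
#' @return An object of class `np_antagonism` with `$table` (2x4 counts +
#'   totals), `$ratios` (Fb_Md:Mb_Fd per row) and `$test` (`np_chi2`).
#' @export
antagonism_contingency <- function(calls, labels) {
  if (nrow(labels) == 0) abort("empty label set")
  neox <- calls[calls$lineage_slot == "neox", c("group_id", "status")]
  neox <- neox[neox$status != "unclassified", ]
  joined <- left_join(neox, labels, by = "group_id")
  joined$label[is.na(joined$label)] <- "unclassified"
  joined$functionality <- ifelse(joined$status == "functional",
                                 "functional", "pseudo")
  label_levels <- c("Fb_Md", "Mb_Fd", "no_conflict", "unclassified")
  tab <- joined |>
    count(.data$functionality, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  for (lv in label_levels) {
    if (!lv %in% names(tab)) tab[[lv]] <- 0L
  }
  tab <- tab[match(c("functional", "pseudo"), tab$functionality),
             c("functionality", label_levels)]
  tab$functionality <- c("functional", "pseudo")
  tab[is.na(tab)] <- 0L
  tab$total <- rowSums(tab[, label_levels])
  sub <- as.matrix(tab[, c("Fb_Md", "Mb_Fd")])
  test <- chi2_2x2(sub)
  ratios <- tibble(
    functionality = tab$functionality,
    fb_md = tab$Fb_Md, mb_fd = tab$Mb_Fd,
    ratio = tab$Fb_Md / tab$Mb_Fd
  )
  structure(list(table = as_tibble(tab), ratios = ratios, test = test),
            class = "np_antagonism")
}

#' @export
print.np_antagonism <- function(x, ...) {
  print(x$table)
  cat(sprintf("Fb_Md:Mb_Fd ratio, functional %.2f vs pseudo %.2f\n",
              x$ratios$ratio[1], x$ratios$ratio[2]))
  print(x$test)
  invisible(x)
}

#' @export
tidy.np_antagonism <- function(x, ...) {
  tidyr::pivot_longer(x$table, cols = -"functionality",
                      names_to = "label", values_to = "n")
}

#' @export
glance.np_antagonism <- function(x, ...) {
  tibble(statistic = x$test$statistic, df = x$test$df,
         p.value = x$test$p_value,
         ratio_functional = x$ratios$ratio[1],
         ratio_pseudo = x$ratios$ratio[2])
}
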