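# One-call pipeline over an in-memory bundle (simulated or read from
# files): classification -> analysis set -> categories -> events -> counts
# -> branch-rate comparisons.

#' Run the pseudogenization pipeline on an input bundle
#'
#' @param bundle An `np_bundle` from [simulate_study()], or any list with
#'   `gene_models`, `ortholog_map` and `expression` tibbles.
#' @param config A [classifier_config()].
#' @param calibration A [time_calibration()].
#' @param drop_categories Categories removed before event counting (e.g.
#'   `"XP_YF"` for the feminization recount); default none.
#' @return A list of class `np_pipeline`: `calls`, `categories`, `events`,
#'   `counts`, `comparisons`, `n_groups`.
#' @export
run_pseudogene_pipeline <- function(bundle,
                                    config = classifier_config(),
                                    calibration = time_calibration(),
                                    drop_categories = NULL) {
  calls <- classify_genes(bundle$ortholog_map, bundle$gene_models,
                          bundle$expression, config)
  # analysis set: groups anchored by a functional outgroup copy
  ok_groups <- calls$group_id[calls$lineage_slot == "dobs" &
                                calls$status == "functional"]
  calls <- calls[calls$group_id %in% ok_groups, ]
  categories <- categorize_groups(calls)
  events <- assign_events(calls)
  counts <- count_events(events, categories,
                         drop_categories = drop_categories)
  comparisons <- compare_branch_rates(counts, calibration)
  structure(list(calls = calls, categories = categories, events = events,
                 counts = counts, comparisons = comparisons,
                 n_groups = length(unique(calls$group_id))),
            class = "np_pipeline")
}

#' @export
print.np_pipeline <- function(x, ...) {
  cat(sprintf("pseudogenization pipeline: %d ortholog groups\n",
              x$n_groups))
  cat("\nper-branch events:\n")
  print(x$counts)
  cat("\nbranch-rate comparisons (time-calibrated):\n")
  print(x$comparisons)
  invisible(x)
}

#' @export
glance.np_pipeline <- function(x, ...) {
  wide <- setNames(x$counts$n_events, x$counts$branch)
  tibble(n_groups = x$n_groups,
         events_anc = wide[["Anc"]], events_x = wide[["X"]],
         events_y = wide[["Y"]], events_pse = wide[["Pse"]],
         events_stem = wide[["Stem"]])
}
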