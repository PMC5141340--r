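# Parsimony assignment of pseudogenization events to branches of the fixed
# species tree (dobs, (dpse, (neox, neoy))).
#
# Branches: Pse (D. pseudoobscura terminal), X and Y (neo-sex terminals),
# Anc (ancestral branch between the ingroup split and the neo-X/neo-Y
# split) and Stem (the branch subtending the D. miranda + D. pseudoobscura
# ancestor; reported but excluded from the four focal branches).
#
# Causes: regulatory (silenced), coding (disrupted), both
# (silenced-and-disrupted), deletion (absent). If both neo-sex copies are
# pseudogenized with intersecting cause sets, a single shared event is
# placed on Anc; with disjoint cause sets two independent terminal events
# are inferred. If all three ingroup copies share a cause, a single Stem
# event explains them all.

.np_cause_set <- function(status) {
  switch(status,
         functional = character(0),
         silenced = "regulatory",
         disrupted = "coding",
         silenced_and_disrupted = c("regulatory", "coding"),
         absent = "deletion",
         unclassified = NA_character_)
}

.np_cause_label <- function(set) {
  if (setequal(set, c("regulatory", "coding"))) return("both")
  set[[1]]
}

#' Functionality category of each ortholog group
#'
#' Groups are labelled by the functionality of their neo-X and neo-Y copies:
#' `F` for functional, `P` for any pseudogene status (silenced, disrupted,
#' silenced-and-disrupted, or absent). A group with an unclassified neo-sex
#' copy is `UNASSIGNED`.
#'
#' @param calls Classification tibble from [classify_genes()].
#' @return A tibble with `group_id` and `category` (`XF_YF`, `XF_YP`,
#'   `XP_YF`, `XP_YP`, `UNASSIGNED`).
#' @export
categorize_groups <- function(calls) {
  wide <- calls |>
    select("group_id", "lineage_slot", "status") |>
    tidyr::pivot_wider(names_from = "lineage_slot", values_from = "status")
  fp <- function(status) {
    dplyr::case_when(
      is.na(status) ~ NA_character_,
      status == "functional" ~ "F",
      status %in% .np_pseudo_statuses ~ "P",
      TRUE ~ NA_character_
    )
  }
  x <- fp(wide$neox)
  y <- fp(wide$neoy)
  tibble(
    group_id = wide$group_id,
    category = ifelse(is.na(x) | is.na(y), "UNASSIGNED",
                      paste0("X", x, "_Y", y))
  )
}

# event assignment for a single group; statuses are strings
.np_assign_one <- function(dpse, neox, neoy) {
  cp <- .np_cause_set(dpse)
  cx <- .np_cause_set(neox)
  cy <- .np_cause_set(neoy)
  pseudo <- function(set) length(set) > 0 && !anyNA(set)
  uncl <- function(set) anyNA(set)
  events <- list()

  # all three ingroup copies lost with one common cause: a single stem event
  if (pseudo(cp) && pseudo(cx) && pseudo(cy)) {
    shared <- intersect(intersect(cp, cx), cy)
    if (length(shared) > 0) {
      return(list(list(branch = "Stem", cause = .np_cause_label(shared))))
    }
  }
  if (pseudo(cp)) {
    events <- c(events, list(list(branch = "Pse",
                                  cause = .np_cause_label(cp))))
  }
  if (!uncl(cx) && !uncl(cy)) {
    if (pseudo(cx) && pseudo(cy)) {
      shared <- intersect(cx, cy)
      if (length(shared) > 0) {
        events <- c(events, list(list(branch = "Anc",
                                      cause = .np_cause_label(shared))))
      } else {
        events <- c(events,
                    list(list(branch = "X", cause = .np_cause_label(cx))),
                    list(list(branch = "Y", cause = .np_cause_label(cy))))
      }
    } else if (pseudo(cx)) {
      events <- c(events, list(list(branch = "X",
                                    cause = .np_cause_label(cx))))
    } else if (pseudo(cy)) {
      events <- c(events, list(list(branch = "Y",
                                    cause = .np_cause_label(cy))))
    }
  }
  events
}

#' Assign pseudogenization events to branches by parsimony
#'
#' The outgroup copy anchors each group as ancestrally functional; the
#' observed statuses of the *D. pseudoobscura*, neo-X and neo-Y copies are
#' then explained with the minimum number of loss events, preferring shared
#' (deeper) events where the copies were lost by an intersecting cause set.
#' Groups with an unclassified neo-X or neo-Y copy contribute no X/Y/Anc
#' events (their placement would be a guess) but may still contribute a Pse
#' event.
#'
#' @param calls Classification tibble from [classify_genes()].
#' @return A tibble with one row per inferred event: `group_id`, `branch`
#'   (`Anc`, `X`, `Y`, `Pse` or `Stem`) and `cause` (`regulatory`, `coding`,
#'   `both`, `deletion`).
#' @export
assign_events <- function(calls) {
  wide <- calls |>
    select("group_id", "lineage_slot", "status") |>
    tidyr::pivot_wider(names_from = "lineage_slot", values_from = "status")
  rows <- purrr::map(seq_len(nrow(wide)), function(i) {
    ev <- .np_assign_one(wide$dpse[i], wide$neox[i], wide$neoy[i])
    if (length(ev) == 0) return(NULL)
    tibble(group_id = wide$group_id[i],
           branch = vapply(ev, `[[`, character(1), "branch"),
           cause = vapply(ev, `[[`, character(1), "cause"))
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble(group_id = character(0), branch = character(0),
                  cause = character(0))
  }
  out
}

#' Per-branch event counts with cause breakdown
#'
#' @param events Event tibble from [assign_events()].
#' @param categories Optional tibble from [categorize_groups()]; required
#'   when `drop_categories` is used and to size the at-risk denominator.
#' @param drop_categories Categories whose groups are removed before
#'   counting (e.g. `"XP_YF"` for the feminization recount).
#' @param n_groups At-risk denominator reported alongside the counts;
#'   defaults to the number of groups in `categories` (after dropping), or
#'   `NA`.
#' @return A tibble with one row per branch (`Anc`, `X`, `Y`, `Pse`,
#'   `Stem`): `n_events`, `n_regulatory`, `n_coding`, `n_both`,
#'   `n_deletion`, `n_groups_at_risk`.
#' @export
count_events <- function(events, categories = NULL, drop_categories = NULL,
                         n_groups = NULL) {
  if (!is.null(drop_categories)) {
    if (is.null(categories)) {
      abort("`categories` is required when dropping categories")
    }
    dropped <- categories$group_id[categories$category %in% drop_categories]
    events <- events[!events$group_id %in% dropped, ]
  }
  if (is.null(n_groups)) {
    n_groups <- if (is.null(categories)) NA_integer_ else {
      if (is.null(drop_categories)) nrow(categories) else {
        sum(!categories$category %in% drop_categories)
      }
    }
  }
  purrr::map_dfr(.np_branches, function(b) {
    ev <- events[events$branch == b, ]
    tibble(
      branch = b,
      n_events = nrow(ev),
      n_regulatory = sum(ev$cause == "regulatory"),
      n_coding = sum(ev$cause == "coding"),
      n_both = sum(ev$cause == "both"),
      n_deletion = sum(ev$cause == "deletion"),
      n_groups_at_risk = n_groups
    )
  })
}
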