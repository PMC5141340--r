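# Parsimony event assignment and counting.

test_that("the canonical assignment cases are reproduced", {
  expect_equal(package_assign_events("functional", "silenced", "silenced"),
               "Anc:regulatory")
  expect_equal(package_assign_events("functional", "silenced", "disrupted"),
               c("X:regulatory", "Y:coding"))
  expect_equal(package_assign_events("disrupted", "functional", "functional"),
               "Pse:coding")
  expect_equal(package_assign_events("functional", "functional", "functional"),
               character(0))
  expect_equal(package_assign_events("functional", "absent", "functional"),
               "X:deletion")
  # a shared cause across all three ingroup tips is a single stem event
  expect_equal(package_assign_events("silenced", "silenced", "silenced"),
               "Stem:regulatory")
  # overlapping but unequal cause sets still share the deeper event
  expect_equal(package_assign_events("functional", "silenced",
                                     "silenced_and_disrupted"),
               "Anc:regulatory")
  # parallel deletions on the neo pair collapse to one ancestral deletion
  expect_equal(package_assign_events("functional", "absent", "absent"),
               "Anc:deletion")
  # a deletion never shares an event with a silencing
  expect_equal(package_assign_events("functional", "absent", "silenced"),
               c("X:deletion", "Y:regulatory"))
})

test_that("assignment agrees with exhaustive minimum-change labelling on all state combinations", {
  states <- c("functional", "silenced", "disrupted",
              "silenced_and_disrupted", "absent")
  for (dpse in states) {
    for (neox in states) {
      for (neoy in states) {
        expect_equal(
          package_assign_events(dpse, neox, neoy),
          oracle_assign_events(dpse, neox, neoy),
          info = paste(dpse, neox, neoy))
      }
    }
  }
})

test_that("per-group events are at most three and Anc excludes X and Y", {
  states <- c("functional", "silenced", "disrupted",
              "silenced_and_disrupted", "absent")
  combos <- expand.grid(d = states, x = states, y = states,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    ev <- package_assign_events(combos$d[i], combos$x[i], combos$y[i])
    expect_lte(length(ev), 3)
    branches <- sub(":.*", "", ev)
    if ("Anc" %in% branches) {
      expect_false(any(c("X", "Y") %in% branches))
    }
    expect_false(any(duplicated(branches)))
  }
})

test_that("unclassified neo members block X/Y/Anc events but not Pse events", {
  ev <- package_assign_events("silenced", "unclassified", "silenced")
  expect_equal(ev, "Pse:regulatory")
  ev <- package_assign_events("functional", "unclassified", "disrupted")
  expect_equal(ev, character(0))
})

test_that("groups are categorized by neo-X/neo-Y functionality", {
  mk <- function(neox, neoy) {
    calls <- tibble::tibble(group_id = "g",
                            lineage_slot = c("dobs", "dpse", "neox", "neoy"),
                            status = c("functional", "functional", neox, neoy))
    categorize_groups(calls)$category
  }
  expect_equal(mk("functional", "silenced"), "XF_YP")
  expect_equal(mk("absent", "functional"), "XP_YF")
  expect_equal(mk("functional", "functional"), "XF_YF")
  expect_equal(mk("silenced_and_disrupted", "disrupted"), "XP_YP")
  expect_equal(mk("unclassified", "functional"), "UNASSIGNED")
})

test_that("count_events tallies per branch and honours category filters", {
  events <- tibble::tibble(
    group_id = c("g1", "g2", "g4"),
    branch = c("Anc", "X", "X"),
    cause = c("regulatory", "coding", "deletion"))
  categories <- tibble::tibble(
    group_id = c("g1", "g2", "g3", "g4"),
    category = c("XP_YP", "XP_YF", "XF_YF", "XP_YF"))
  counts <- count_events(events, categories)
  expect_equal(counts$n_events[counts$branch == "Anc"], 1)
  expect_equal(counts$n_events[counts$branch == "X"], 2)
  expect_equal(counts$n_events[counts$branch == "Y"], 0)
  expect_equal(counts$n_regulatory[counts$branch == "Anc"], 1)
  expect_equal(unique(counts$n_groups_at_risk), 4L)

  filtered <- count_events(events, categories, drop_categories = "XP_YF")
  expect_equal(filtered$n_events[filtered$branch == "X"], 0)
  expect_equal(filtered$n_events[filtered$branch == "Anc"], 1)
  expect_equal(unique(filtered$n_groups_at_risk), 2L)

  empty <- count_events(events[0, ], categories)
  expect_true(all(empty$n_events == 0))
})
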