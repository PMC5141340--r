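# Six-rule functionality classifier (toy_classify lives in the helpers).

test_that("the six classification rules fire on their defining predicates", {
  cases <- list(
    # expressed, complete, L — rule, status
    list(len = 90, fpkm = 10, args = list(), rule = "1",
         status = "functional"),                      # L = 1.0
    list(len = 71, fpkm = 10, args = list(), rule = "2",
         status = "disrupted"),                       # L = 0.789 < 0.8
    list(len = 90, fpkm = 0.5, args = list(), rule = "3",
         status = "silenced"),
    list(len = 45, fpkm = 0.5, args = list(), rule = "4",
         status = "silenced_and_disrupted"),
    list(len = 90, fpkm = 10, args = list(stop = FALSE), rule = "5",
         status = "disrupted"),
    list(len = 90, fpkm = 10, args = list(stop = FALSE, flank = TRUE),
         rule = "6", status = "unclassified")
  )
  for (cs in cases) {
    call <- do.call(toy_classify,
                    c(list(len = cs$len, fpkm = cs$fpkm), cs$args))
    expect_equal(call$status, cs$status, info = cs$rule)
    expect_equal(call$rule, cs$rule)
  }
})

test_that("the length and expression thresholds are inclusive boundaries", {
  expect_equal(toy_classify(len = 72)$status, "functional") # L = 0.8 exactly
  expect_equal(toy_classify(len = 71)$status, "disrupted")
  expect_equal(toy_classify(fpkm = 1.0)$status, "functional") # FPKM >= 1
  expect_equal(toy_classify(fpkm = 0.99)$status, "silenced")
})

test_that("an absent member is called absent with cause deletion", {
  gm <- dplyr::bind_rows(gm_row("a", "dobs"), gm_row("b", "dpse"),
                         gm_row("c", "neox"))
  expr <- dplyr::bind_rows(expr_row("a", 10), expr_row("b", 10),
                           expr_row("c", 10))
  calls <- classify_genes(one_group_map(neoy = NA), gm, expr)
  neoy <- calls[calls$lineage_slot == "neoy", ]
  expect_equal(neoy$status, "absent")
  expect_equal(neoy$causes, "deletion")
})

test_that("classification is exhaustive and exclusive over the predicate lattice", {
  grid <- expand.grid(expressed = c(TRUE, FALSE),
                      complete = c(TRUE, FALSE),
                      long = c(TRUE, FALSE),
                      flank = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    call <- toy_classify(len = if (g$long) 90 else 45,
                         stop = g$complete,
                         flank = g$flank,
                         fpkm = if (g$expressed) 10 else 0.2)
    expect_equal(length(call$status), 1L)
    expect_true(call$status %in% c("functional", "disrupted", "silenced",
                                   "silenced_and_disrupted",
                                   "unclassified"))
    # expected status from the rule text
    want <- if (g$expressed && g$complete) {
      if (g$long) "functional" else "disrupted"
    } else if (!g$expressed) {
      if (g$long) "silenced" else "silenced_and_disrupted"
    } else if (!g$flank) "disrupted" else "unclassified"
    expect_equal(call$status, want, info = paste(unlist(g), collapse = "/"))
  }
})

test_that("raising the CDS-fraction threshold never rescues a pseudogene", {
  for (len in c(45, 60, 71, 72, 80, 90)) {
    lo <- toy_classify(len = len,
                       config = classifier_config(cds_fraction_threshold = 0.6))
    hi <- toy_classify(len = len,
                       config = classifier_config(cds_fraction_threshold = 0.9))
    if (lo$status != "functional") {
      expect_false(hi$status == "functional", info = len)
    }
  }
})

test_that("reference length prefers complete members and averages them", {
  members <- dplyr::bind_rows(
    gm_row("a", "dobs", len = 900),
    gm_row("b", "dpse", len = 903),
    gm_row("d", "neoy", len = 100))
  expect_equal(reference_cds_length(members, "neoy"), 901.5)

  trunc <- dplyr::bind_rows(
    gm_row("a", "dobs", len = 900),
    gm_row("b", "dpse", len = 450, stop = FALSE),
    gm_row("d", "neoy", len = 100))
  expect_equal(reference_cds_length(trunc, "neoy"), 900)
  expect_equal(reference_cds_length(trunc, "neoy",
                                    config = classifier_config(reference_members = "all")),
               675)
  # no complete member at all: fall back to all present members
  none <- dplyr::mutate(trunc, has_stop_codon = FALSE)
  expect_equal(reference_cds_length(none, "neoy"), 675)
  only <- gm_row("d", "neoy")
  expect_error(reference_cds_length(only, "neoy"), "non-focal")
})

test_that("is_expressed applies the threshold over samples and handles absence", {
  expr <- dplyr::bind_rows(expr_row("g1", 0.2, "head", "F"),
                           expr_row("g1", 1.0, "testis", "M"))
  expect_true(is_expressed("g1", expr))
  expect_false(is_expressed("g1", expr, female_only = TRUE))
  expect_false(is_expressed("g2", expr))
  low <- dplyr::mutate(expr, fpkm = 0.99)
  expect_false(is_expressed("g1", low))
})

test_that("neo-X expression is judged from female samples when configured", {
  gm <- dplyr::bind_rows(gm_row("a", "dobs"), gm_row("b", "dpse"),
                         gm_row("c", "neox"), gm_row("d", "neoy"))
  expr <- dplyr::bind_rows(
    expr_row("a", 10), expr_row("b", 10), expr_row("d", 10),
    expr_row("c", 0.3, "head", "F"), expr_row("c", 50, "testis", "M"))
  on <- classify_genes(one_group_map(), gm, expr, classifier_config())
  expect_equal(on$status[on$lineage_slot == "neox"], "silenced")
  off <- classify_genes(one_group_map(), gm, expr,
                        classifier_config(neox_female_only = FALSE))
  expect_equal(off$status[off$lineage_slot == "neox"], "functional")
})

test_that("the genome-prediction rescue only moves calls out of silenced statuses", {
  # expressed genome prediction: silenced without rescue, functional with
  base <- toy_classify(src = "genome_prediction", fpkm = 10)
  expect_equal(base$status, "silenced")
  rescued <- toy_classify(src = "genome_prediction", fpkm = 10,
                          config = classifier_config(rescue_genome_predictions = TRUE))
  expect_equal(rescued$status, "functional")

  # property: across the predicate grid, rescue never creates a silenced
  # call that was not already silenced
  grid <- expand.grid(long = c(TRUE, FALSE), fpkm = c(10, 0.2),
                      stop = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    off <- toy_classify(len = if (g$long) 90 else 45, fpkm = g$fpkm,
                        stop = g$stop, src = "genome_prediction")
    on <- toy_classify(len = if (g$long) 90 else 45, fpkm = g$fpkm,
                       stop = g$stop, src = "genome_prediction",
                       config = classifier_config(rescue_genome_predictions = TRUE))
    silenced <- c("silenced", "silenced_and_disrupted")
    if (on$status %in% silenced) {
      expect_true(off$status %in% silenced)
    }
  }
})
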