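# Synthetic-data generator: determinism, planted truth, manifestations.

test_that("the same seed reproduces the bundle and byte-identical files", {
  p <- sim_params(n_groups = 12, seed = 99, n_codons = 40)
  b1 <- simulate_study(p)
  b2 <- simulate_study(p)
  expect_identical(b1$gene_models, b2$gene_models)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$truth, b2$truth)

  d1 <- file.path(withr::local_tempdir(), "one")
  d2 <- file.path(withr::local_tempdir(), "two")
  write_study_bundle(b1, d1)
  write_study_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("zero event probabilities yield an all-functional study", {
  p <- sim_params(n_groups = 15, seed = 5, n_codons = 40,
                  branch_event_prob = c(Anc = 0, X = 0, Y = 0, Pse = 0))
  b <- simulate_study(p)
  pipe <- run_pseudogene_pipeline(b)
  expect_true(all(pipe$calls$status == "functional"))
  expect_equal(nrow(pipe$events), 0)
  expect_true(all(pipe$categories$category == "XF_YF"))
})

test_that("planted events are recovered exactly by the classifier and assigner", {
  b <- simulate_study(sim_params(n_groups = 120, seed = 17, n_codons = 60))
  pipe <- run_pseudogene_pipeline(b)
  inferred <- pipe$events |>
    dplyr::group_by(group_id) |>
    dplyr::summarise(
      ev = paste(sort(sprintf("%s:%s", branch, cause)), collapse = ";"))
  truth <- vapply(strsplit(b$truth$events, ";"), function(x)
    paste(sort(x[x != ""]), collapse = ";"), character(1))
  got <- inferred$ev[match(b$truth$group_id, inferred$group_id)]
  got[is.na(got)] <- ""
  expect_equal(got, truth)
  expect_equal(
    pipe$categories$category[match(b$truth$group_id,
                                   pipe$categories$group_id)],
    b$truth$category)
})

test_that("event manifestations match their planted causes", {
  b <- simulate_study(sim_params(n_groups = 150, seed = 23, n_codons = 50))
  pipe <- run_pseudogene_pipeline(b)
  joined <- dplyr::inner_join(
    pipe$calls,
    tidyr::pivot_longer(
      dplyr::select(b$truth, group_id, status_dpse, status_neox,
                    status_neoy),
      -group_id, names_to = "lineage_slot", values_to = "planted",
      names_prefix = "status_"),
    by = c("group_id", "lineage_slot"))
  expect_true(all(joined$status == joined$planted))
  # silenced copies are silent in every sample of the expression matrix
  silent_ids <- joined$gene_id[joined$status == "silenced"]
  silent_fpkm <- b$expression$fpkm[b$expression$gene_id %in% silent_ids]
  expect_true(all(silent_fpkm < 1))
})

test_that("codon evolution respects branch length zero and omega zero", {
  withr::with_seed(3, {
    anc <- paste0("ATG", paste(
      sample(setdiff(names(GC)[GC != "*"], "ATG"), 300, replace = TRUE),
      collapse = ""), "TAA")
    expect_identical(simulate_codon_evolution(anc, 0, 1), anc)
    tip <- simulate_codon_evolution(anc, 0.1, omega = 0)
    est <- ng86(anc, tip)
    expect_equal(est$n_diffs, 0)
    expect_gt(est$s_diffs, 0)
  })
})

test_that("parameter validation rejects malformed settings", {
  expect_error(sim_params(cause_mix = c(regulatory = 0.5, coding = 0.2,
                                        both = 0.1, deletion = 0.1)),
               "sum to 1")
  expect_error(sim_params(branch_event_prob = c(Anc = 1.5, X = 0, Y = 0,
                                                Pse = 0)),
               "probabilities")
  expect_error(sim_params(seed = NA), "seed")
})

test_that("a planted male bias in XP_YF groups produces the lowest gonad F/M ratio", {
  b <- simulate_study(sim_params(n_groups = 260, seed = 41, n_codons = 40))
  pipe <- run_pseudogene_pipeline(b)
  genes <- dplyr::inner_join(
    dplyr::tibble(gene_id = paste0("dpse_", pipe$categories$group_id),
                  category = pipe$categories$category),
    dplyr::distinct(b$expression, gene_id), by = "gene_id")
  cmp <- compare_fm_by_category(b$expression, genes, "gonad",
                                reps = 300, seed = 7)
  med <- cmp$summary
  expect_equal(med$category[which.min(med$median)], "XP_YF")
})
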