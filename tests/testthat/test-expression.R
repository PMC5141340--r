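# F/M ratios, maximum-expression tissue and tissue-wise pseudogene ratios.

test_that("F/M ratios divide female by male with floor and pseudocount", {
  expr <- dplyr::bind_rows(
    expr_row("g1", 10, "head", "F"), expr_row("g1", 5, "head", "M"),
    expr_row("g2", 0, "head", "F"), expr_row("g2", 0, "head", "M"),
    expr_row("g3", 0, "head", "F"), expr_row("g3", 8, "head", "M"))
  r <- compute_fm_ratios(expr, "head")
  expect_equal(r$fm_ratio[r$gene_id == "g1"], 2)
  expect_true(is.na(r$fm_ratio[r$gene_id == "g2"])) # below the floor
  expect_equal(r$fm_ratio[r$gene_id == "g3"], 0)
  rp <- compute_fm_ratios(expr, "head", pseudocount = 0.1)
  expect_equal(rp$fm_ratio[rp$gene_id == "g3"], 0.1 / 8.1)
  expect_error(compute_fm_ratios(expr, "wing"), "unknown tissue")
})

test_that("the gonad tissue pairs ovary (F) with testis (M)", {
  expr <- dplyr::bind_rows(
    expr_row("g1", 4, "ovary", "F"), expr_row("g1", 16, "testis", "M"))
  r <- compute_fm_ratios(expr, "gonad")
  expect_equal(r$fm_ratio, 0.25)
})

test_that("maximum-expression tissue requires a clear fold dominance", {
  expr <- dplyr::bind_rows(
    expr_row("g1", 10, "testis", "M"), expr_row("g1", 4, "head", "F"),
    expr_row("g1", 1, "ovary", "F"),
    expr_row("g2", 10, "testis", "M"), expr_row("g2", 6, "head", "F"),
    expr_row("g3", 0, "testis", "M"), expr_row("g3", 0, "head", "F"))
  mx <- max_expression_tissue(expr)
  expect_equal(mx$tissue_max[mx$gene_id == "g1"], "testis") # 10 >= 2 x 4
  expect_true(is.na(mx$tissue_max[mx$gene_id == "g2"]))     # 10 < 2 x 6
  expect_true(is.na(mx$tissue_max[mx$gene_id == "g3"]))     # all zero

  # scale invariance
  scaled <- dplyr::mutate(expr, fpkm = fpkm * 37.5)
  expect_equal(max_expression_tissue(scaled)$tissue_max, mx$tissue_max)
})

test_that("category comparison recovers a planted male bias as the lowest F/M median", {
  set.seed(31)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:120),
    category = rep(c("XF_YF", "XF_YP", "XP_YF", "XP_YP"), each = 30))
  expr <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    male_biased <- genes$category[i] == "XP_YF"
    f <- rlnorm(1, 1.5, 0.5) / (if (male_biased) 6 else 1)
    m <- rlnorm(1, 1.5, 0.5) * (if (male_biased) 6 else 1)
    dplyr::bind_rows(expr_row(genes$gene_id[i], f, "ovary", "F"),
                     expr_row(genes$gene_id[i], m, "testis", "M"))
  })
  cmp <- compare_fm_by_category(expr, genes, "gonad", reps = 200, seed = 4)
  med <- cmp$summary$median[match(c("XF_YF", "XF_YP", "XP_YF", "XP_YP"),
                                  cmp$summary$category)]
  expect_equal(which.min(med), 3L)
  pw <- cmp$pairwise
  xp_rows <- pw[pw$category_a == "XP_YF" | pw$category_b == "XP_YF", ]
  expect_true(all(xp_rows$p_value < 0.05))
})

test_that("identical expression in all categories gives equal medians and null p-values", {
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                          category = rep(c("XF_YF", "XP_YF"), each = 20))
  expr <- purrr::map_dfr(genes$gene_id, function(g) {
    dplyr::bind_rows(expr_row(g, 6, "ovary", "F"),
                     expr_row(g, 3, "testis", "M"))
  })
  cmp <- compare_fm_by_category(expr, genes, "gonad", reps = 200, seed = 9)
  expect_true(all(cmp$summary$median == 2))
  expect_true(all(cmp$pairwise$p_value > 0.9))
})

test_that("tissue-wise pseudogene:functional ratios and CIs behave", {
  df <- tibble::tibble(
    tissue_max = c(rep("testis", 50), rep("head", 5), rep("ovary", 4), NA),
    is_pseudo = c(rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 10),
                  rep(FALSE, 5), rep(TRUE, 4), TRUE))
  r <- pseudo_functional_ratio_by_tissue(df, reps = 300, seed = 5)
  testis <- r[r$tissue == "testis", ]
  expect_equal(testis$ratio, 10 / 40)
  expect_true(testis$ci_lo <= testis$ratio && testis$ratio <= testis$ci_hi)
  head_row <- r[r$tissue == "head", ]
  expect_equal(head_row$ratio, 0)
  expect_equal(head_row$ci_lo, 0)
  ovary <- r[r$tissue == "ovary", ]
  expect_equal(ovary$ratio, Inf)
  expect_true(is.na(ovary$ci_lo))
  expect_false(any(is.na(r$tissue))) # NA tissue rows dropped
})
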