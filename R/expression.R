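# Sex-biased expression analyses: female-to-male ratios by functionality
# category and the maximum-expression-tissue view of pseudogenization.

.np_gonad_pair <- c(F = "ovary", M = "testis")

#' Female-to-male expression ratios for one tissue
#'
#' The special tissue `"gonad"` pairs ovary (female) with testis (male);
#' any other tissue uses its own female and male samples. Genes whose
#' female and male values both fall below the expression floor are excluded
#' (ratio `NA`): a ratio between two silent measurements is noise.
#'
#' @param expression Expression tibble (`gene_id`, `tissue`, `sex`,
#'   `fpkm`).
#' @param tissue Tissue label, or `"gonad"` for the ovary/testis pair.
#' @param pseudocount Added to numerator and denominator (default 0).
#' @param floor Expression floor in FPKM (default 1): `max(F, M)` must
#'   reach it.
#' @return A tibble `gene_id`, `fpkm_f`, `fpkm_m`, `fm_ratio` (NA when
#'   excluded).
#' @export
compute_fm_ratios <- function(expression, tissue, pseudocount = 0,
                              floor = 1) {
  if (tissue == "gonad") {
    f <- expression[expression$tissue == .np_gonad_pair[["F"]] &
                      expression$sex == "F", ]
    m <- expression[expression$tissue == .np_gonad_pair[["M"]] &
                      expression$sex == "M", ]
    if (nrow(f) == 0 && nrow(m) == 0) abort("no gonad samples in the table")
  } else {
    if (!tissue %in% expression$tissue) {
      abort(sprintf("unknown tissue: %s", tissue))
    }
    rows <- expression[expression$tissue == tissue, ]
    f <- rows[rows$sex == "F", ]
    m <- rows[rows$sex == "M", ]
  }
  both <- full_join(
    select(f, "gene_id", fpkm_f = "fpkm"),
    select(m, "gene_id", fpkm_m = "fpkm"),
    by = "gene_id"
  )
  both <- both[!is.na(both$fpkm_f) & !is.na(both$fpkm_m), ]
  mutate(both, fm_ratio = ifelse(
    pmax(.data$fpkm_f, .data$fpkm_m) < floor, NA_real_,
    (.data$fpkm_f + pseudocount) / (.data$fpkm_m + pseudocount)
  ))
}

#' F/M ratio distributions by functionality category
#'
#' Joins per-gene F/M ratios for one tissue to neo-sex functionality
#' categories and compares every category pair with the bootstrap median
#' test.
#'
#' @param expression Expression tibble (for the comparison species, e.g.
#'   the autosomal proxy of the ancestor).
#' @param categories Tibble `gene_id`, `category` mapping the expressed
#'   genes to `XF_YF`/`XF_YP`/`XP_YF`/`XP_YP` (UNASSIGNED rows are
#'   dropped).
#' @param tissue Tissue passed to [compute_fm_ratios()].
#' @param reps,seed Bootstrap settings (see [bootstrap_median_test()]).
#' @param ... Further arguments to [compute_fm_ratios()].
#' @return An object of class `np_fm_comparison`: `$values` (per-gene
#'   ratios with category), `$summary` (per-category n, median, quartiles
#'   and deciles), `$pairwise` (bootstrap p-values), `$tissue`.
#' @export
compare_fm_by_category <- function(expression, categories, tissue,
                                   reps = 1000, seed = NULL, ...) {
  ratios <- compute_fm_ratios(expression, tissue, ...)
  values <- ratios |>
    inner_join(select(categories, "gene_id", "category"), by = "gene_id") |>
    filter(.data$category != "UNASSIGNED", !is.na(.data$fm_ratio))
  summary <- values |>
    group_by(.data$category) |>
    summarise(
      n = dplyr::n(),
      median = median(.data$fm_ratio),
      q25 = quantile(.data$fm_ratio, 0.25),
      q75 = quantile(.data$fm_ratio, 0.75),
      q10 = quantile(.data$fm_ratio, 0.10),
      q90 = quantile(.data$fm_ratio, 0.90),
      .groups = "drop"
    )
  cats <- sort(unique(values$category))
  prs <- if (length(cats) >= 2) utils::combn(cats, 2, simplify = FALSE) else list()
  pairwise <- purrr::map_dfr(prs, function(pr) {
    va <- values$fm_ratio[values$category == pr[1]]
    vb <- values$fm_ratio[values$category == pr[2]]
    if (length(va) < 2 || length(vb) < 2) {
      warn(sprintf("category pair %s vs %s has < 2 members; skipped",
                   pr[1], pr[2]))
      return(NULL)
    }
    test <- bootstrap_median_test(va, vb, reps = reps, seed = seed)
    tibble(category_a = pr[1], category_b = pr[2],
           median_a = median(va), median_b = median(vb),
           estimate = test$estimate, p_value = test$p_value)
  })
  structure(list(values = values, summary = summary, pairwise = pairwise,
                 tissue = tissue),
            class = "np_fm_comparison")
}

#' @export
print.np_fm_comparison <- function(x, ...) {
  cat(sprintf("F/M expression ratios (%s), %d genes\n",
              x$tissue, nrow(x$values)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.np_fm_comparison <- function(x, ...) x$summary

#' @export
glance.np_fm_comparison <- function(x, ...) {
  tibble(tissue = x$tissue, n_genes = nrow(x$values),
         n_categories = nrow(x$summary))
}

#' Tissue of maximum expression under a fold-change rule
#'
#' Per gene, sexes are averaged into one cFPKM per tissue (an optional
#' per-tissue normaliser can be applied first); the tissue with maximal
#' cFPKM is reported only if it exceeds every other tissue by at least
#' `fold` (default twofold), otherwise the gene has no clear maximum tissue
#' (`NA`). The rule is scale-invariant within a gene.
#'
#' @param expression Expression tibble.
#' @param fold Required fold difference over every other tissue
#'   (default 2).
#' @param normalize `"none"` (raw FPKM, default) or `"upper_quartile"`
#'   (each tissue scaled by its upper-quartile FPKM across genes).
#' @return A tibble `gene_id`, `tissue_max` (`NA` if no tissue dominates),
#'   `cfpkm_max`.
#' @export
max_expression_tissue <- function(expression, fold = 2,
                                  normalize = c("none", "upper_quartile")) {
  normalize <- match.arg(normalize)
  cf <- expression |>
    group_by(.data$gene_id, .data$tissue) |>
    summarise(cfpkm = mean(.data$fpkm), .groups = "drop")
  if (normalize == "upper_quartile") {
    cf <- cf |>
      group_by(.data$tissue) |>
      mutate(cfpkm = .data$cfpkm /
               max(quantile(.data$cfpkm[.data$cfpkm > 0], 0.75), 1e-9)) |>
      ungroup()
  }
  cf |>
    group_by(.data$gene_id) |>
    summarise(
      tissue_max = {
        if (dplyr::n() < 2 || max(.data$cfpkm) <= 0) NA_character_ else {
          top <- which.max(.data$cfpkm)
          others <- .data$cfpkm[-top]
          if (length(others) == 0 || .data$cfpkm[top] >= fold * max(others)) {
            .data$tissue[top]
          } else {
            NA_character_
          }
        }
      },
      cfpkm_max = max(.data$cfpkm),
      .groups = "drop"
    )
}

#' Pseudogene:functional ratio by tissue of maximum expression
#'
#' For each tissue, the ratio of neo-X pseudogenes to neo-X functional
#' genes among the genes whose maximum expression falls in that tissue,
#' with a percentile bootstrap confidence interval from resampling genes
#' within the tissue.
#'
#' @param df Tibble with one row per gene: `tissue_max` (from
#'   [max_expression_tissue()]; `NA` rows are dropped) and logical
#'   `is_pseudo` (neo-X functionality).
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A tibble per tissue: `n_genes`, `n_pseudo`, `n_functional`,
#'   `ratio` (`Inf` when no functional gene; CI suppressed), `ci_lo`,
#'   `ci_hi`.
#' @export
pseudo_functional_ratio_by_tissue <- function(df, reps = 1000, seed = NULL,
                                              conf = 0.95) {
  df <- df[!is.na(df$tissue_max), ]
  alpha <- (1 - conf) / 2
  run <- function() {
    df |>
      group_by(tissue = .data$tissue_max) |>
      group_modify(function(g, key) {
        n_p <- sum(g$is_pseudo)
        n_f <- sum(!g$is_pseudo)
        ratio <- if (n_f == 0) Inf else n_p / n_f
        if (n_f == 0) {
          return(tibble(n_genes = nrow(g), n_pseudo = n_p,
                        n_functional = n_f, ratio = ratio,
                        ci_lo = NA_real_, ci_hi = NA_real_))
        }
        boots <- vapply(seq_len(reps), function(i) {
          s <- sample(g$is_pseudo, nrow(g), replace = TRUE)
          nf <- sum(!s)
          if (nf == 0) NA_real_ else sum(s) / nf
        }, numeric(1))
        qs <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE)
        tibble(n_genes = nrow(g), n_pseudo = n_p, n_functional = n_f,
               ratio = ratio, ci_lo = qs[[1]], ci_hi = qs[[2]])
      }) |>
      ungroup()
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
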