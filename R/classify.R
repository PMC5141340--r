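# Six-rule functionality classifier.
#
# A gene copy is compared against its ortholog group on three predicates:
#   E  expressed at >= fpkm_threshold in at least one sample,
#   C  carries both an initiation and a stop codon,
#   L  CDS length relative to the mean CDS length of the other members.
# Rules:
#   1  E,  C, L >= 0.8  -> functional
#   2  E,  C, L <  0.8  -> disrupted
#   3  !E,    L >= 0.8  -> silenced
#   4  !E,    L <  0.8  -> silenced_and_disrupted
#   5  E, !C, clean flanks     -> disrupted
#   6  E, !C, ambiguous flanks -> unclassified (possible assembly artefact)
# An absent member is `absent` (cause: deletion). Silenced, disrupted,
# silenced-and-disrupted and absent copies are pseudogenes.

#' Classifier configuration
#'
#' @param fpkm_threshold Expression floor; a gene is expressed if any sample
#'   reaches this FPKM (default 1).
#' @param cds_fraction_threshold Relative CDS length below which a gene is
#'   disrupted (default 0.8).
#' @param rescue_genome_predictions If `TRUE`, expression evidence also
#'   counts for genes annotated by genome-only prediction
#'   (`annotation_source == "genome_prediction"`); with the default `FALSE`
#'   their expression is disregarded, mirroring annotation pipelines whose
#'   transcript evidence cannot reach such genes. Turning the rescue on can
#'   only move calls out of the silenced statuses, never into them.
#' @param neox_female_only Evaluate neo-X expression from female samples
#'   only (default `TRUE`; male reads cannot be assigned unambiguously
#'   between the neo-X and neo-Y).
#' @param reference_members Which non-focal members define the reference
#'   CDS length: `"complete"` (default; members with both start and stop
#'   codons, falling back to all present members) or `"all"`.
#' @return A list of class `np_classifier_config`.
#' @export
classifier_config <- function(fpkm_threshold = 1,
                              cds_fraction_threshold = 0.8,
                              rescue_genome_predictions = FALSE,
                              neox_female_only = TRUE,
                              reference_members = c("complete", "all")) {
  if (fpkm_threshold <= 0 || cds_fraction_threshold <= 0 ||
      cds_fraction_threshold > 1) {
    abort("thresholds must be positive (CDS fraction in (0, 1])")
  }
  structure(list(
    fpkm_threshold = fpkm_threshold,
    cds_fraction_threshold = cds_fraction_threshold,
    rescue_genome_predictions = isTRUE(rescue_genome_predictions),
    neox_female_only = isTRUE(neox_female_only),
    reference_members = match.arg(reference_members)
  ), class = "np_classifier_config")
}

#' Is a gene expressed?
#'
#' @param gene_id Gene identifier.
#' @param expression Expression tibble (`gene_id`, `tissue`, `sex`, `fpkm`).
#' @param config A [classifier_config()].
#' @param female_only Restrict to female samples (used for neo-X genes).
#' @return `TRUE` iff any retained sample reaches the FPKM threshold; a gene
#'   absent from the table is not expressed.
#' @export
is_expressed <- function(gene_id, expression, config = classifier_config(),
                         female_only = FALSE) {
  rows <- expression[expression$gene_id == gene_id, ]
  if (female_only) rows <- rows[rows$sex == "F", ]
  nrow(rows) > 0 && max(rows$fpkm) >= config$fpkm_threshold
}

#' Reference CDS length for one member of an ortholog group
#'
#' The arithmetic mean CDS length of the other members of the group.
#' With `reference_members = "complete"` only members carrying both start
#' and stop codons enter the mean; if no such member exists the mean is
#' taken over all other present members.
#'
#' @param members Tibble with one row per present member: `lineage_slot`,
#'   `cds_length`, `has_start_codon`, `has_stop_codon`.
#' @param focal The lineage slot being classified.
#' @param config A [classifier_config()].
#' @return The reference length (numeric). Errors when no non-focal member
#'   is present.
#' @export
reference_cds_length <- function(members, focal,
                                 config = classifier_config()) {
  others <- members[members$lineage_slot != focal, ]
  if (nrow(others) == 0) {
    abort(sprintf("no non-focal member to define a reference length (focal %s)",
                  focal))
  }
  if (config$reference_members == "complete") {
    complete <- others[others$has_start_codon & others$has_stop_codon, ]
    if (nrow(complete) > 0) others <- complete
  }
  mean(others$cds_length)
}

.np_causes_of_status <- function(status) {
  switch(status,
         functional = "",
         silenced = "regulatory",
         disrupted = "coding",
         silenced_and_disrupted = "regulatory+coding",
         absent = "deletion",
         unclassified = "")
}

# core rule engine for one member; `gene` is a one-row tibble or NULL (absent)
.np_classify_one <- function(gene, ref_length, expressed, config) {
  if (is.null(gene)) {
    return(list(status = "absent", cds_ratio = NA_real_,
                expressed = NA, rule = "absent"))
  }
  e <- expressed
  if (!is.na(gene$annotation_source) &&
      gene$annotation_source == "genome_prediction" &&
      !config$rescue_genome_predictions) {
    e <- FALSE # expression evidence not usable for genome-only predictions
  }
  if (is.na(ref_length) || ref_length <= 0) {
    return(list(status = "unclassified", cds_ratio = NA_real_,
                expressed = e, rule = "undefined_reference"))
  }
  l <- gene$cds_length / ref_length
  c_ok <- gene$has_start_codon && gene$has_stop_codon
  thr <- config$cds_fraction_threshold
  if (e && c_ok) {
    status <- if (l >= thr) "functional" else "disrupted"
    rule <- if (l >= thr) "1" else "2"
  } else if (!e) {
    status <- if (l >= thr) "silenced" else "silenced_and_disrupted"
    rule <- if (l >= thr) "3" else "4"
  } else if (!gene$flank_has_ambiguity) {
    status <- "disrupted"
    rule <- "5"
  } else {
    status <- "unclassified"
    rule <- "6"
  }
  list(status = status, cds_ratio = l, expressed = e, rule = rule)
}

#' Classify every member of every ortholog group
#'
#' Applies the six-rule classifier to each lineage slot of each group.
#' Groups whose only present member is the focal one cannot be classified
#' and are dropped with a warning.
#'
#' @param ortholog_map Tibble from [read_ortholog_map()] (columns
#'   `group_id`, `dobs_id`, `dpse_id`, `neox_id`, `neoy_id`).
#' @param gene_models Tibble from [read_gene_models()].
#' @param expression Tibble from [read_expression_table()].
#' @param config A [classifier_config()].
#' @return A tibble with one row per group x slot: `group_id`,
#'   `lineage_slot`, `gene_id`, `status`, `causes`, `cds_ratio`,
#'   `expressed`, `rule`.
#' @export
classify_genes <- function(ortholog_map, gene_models, expression,
                           config = classifier_config()) {
  long <- tidyr::pivot_longer(
    ortholog_map,
    cols = c("dobs_id", "dpse_id", "neox_id", "neoy_id"),
    names_to = "lineage_slot", values_to = "gene_id"
  )
  long$lineage_slot <- sub("_id$", "", long$lineage_slot)
  gm <- select(gene_models, "gene_id", "cds_length", "has_start_codon",
               "has_stop_codon", "flank_has_ambiguity", "annotation_source")
  long <- left_join(long, gm, by = "gene_id")
  missing_model <- !is.na(long$gene_id) & is.na(long$cds_length)
  if (any(missing_model)) {
    abort(paste0("gene id(s) without a gene model: ",
                 paste(utils::head(long$gene_id[missing_model], 5),
                       collapse = ", ")))
  }

  # expression lookup: max FPKM per gene, all samples and female-only
  emax <- expression |>
    group_by(.data$gene_id) |>
    summarise(all_max = max(.data$fpkm),
              f_max = max(c(.data$fpkm[.data$sex == "F"], -Inf)),
              .groups = "drop")
  long <- left_join(long, emax, by = "gene_id")
  use_f <- config$neox_female_only & long$lineage_slot == "neox"
  obs_max <- ifelse(use_f, long$f_max, long$all_max)
  long$.expressed <- !is.na(obs_max) & obs_max >= config$fpkm_threshold

  out <- long |>
    group_by(.data$group_id) |>
    group_modify(function(df, key) {
      present <- df[!is.na(df$gene_id), ]
      purrr::map_dfr(seq_len(nrow(df)), function(i) {
        row <- df[i, ]
        if (is.na(row$gene_id)) {
          res <- .np_classify_one(NULL, NA, NA, config)
        } else {
          others <- present[present$lineage_slot != row$lineage_slot, ]
          ref <- if (nrow(others) == 0) NA_real_ else {
            reference_cds_length(present, row$lineage_slot, config)
          }
          if (nrow(others) == 0) {
            warn(sprintf("group %s: no non-focal member for %s; unclassified",
                         key$group_id, row$lineage_slot))
          }
          res <- .np_classify_one(row, ref, row$.expressed, config)
        }
        tibble(lineage_slot = row$lineage_slot,
               gene_id = row$gene_id,
               status = res$status,
               causes = .np_causes_of_status(res$status),
               cds_ratio = res$cds_ratio,
               expressed = res$expressed,
               rule = res$rule)
      })
    }) |>
    ungroup()
  out
}
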