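# Readers and writers for the standard input formats. GFF3 goes through
# rtracklayer, sequences through Biostrings, tables through readr.
# Coordinates are GFF3 1-based inclusive on disk; all slicing happens at
# this boundary so downstream code only ever sees sequences.

#' Read gene models from GFF3 + genome FASTA
#'
#' Builds one gene-model record per mRNA feature: the CDS is spliced from
#' the genome (minus-strand CDS are reverse-complemented onto the sense
#' strand), start/stop presence is determined from the sequence under the
#' standard genetic code, and the 100-nt genomic flanks on both sides of the
#' CDS span are scanned for ambiguous (non-ACGT) bases.
#'
#' The mRNA attributes `lineage_slot`, `species`, `element` and
#' `annotation_source` are carried into the output when present.
#'
#' @param gff3_path Path to a GFF3 file with gene/mRNA/CDS features.
#' @param genome_fasta_path Path to the matching genome FASTA.
#' @param flank Flank width scanned for ambiguous bases (default 100 nt).
#' @return A tibble with columns `gene_id`, `species`, `lineage_slot`,
#'   `element`, `cds_length`, `has_start_codon`, `has_stop_codon`,
#'   `flank_has_ambiguity`, `annotation_source` and `cds_seq`.
#' @export
read_gene_models <- function(gff3_path, genome_fasta_path, flank = 100L) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  genome <- Biostrings::readDNAStringSet(genome_fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  mrna <- gr[tolower(as.character(gr$type)) == "mrna"]
  cds <- gr[as.character(gr$type) == "CDS"]
  cds_parent <- vapply(as.list(cds$Parent), function(p) {
    if (length(p) > 0) p[[1]] else NA_character_
  }, character(1))

  attr_or_na <- function(x, nm) {
    if (nm %in% names(S4Vectors::mcols(x))) {
      as.character(S4Vectors::mcols(x)[[nm]])
    } else {
      rep(NA_character_, length(x))
    }
  }
  slot_attr <- attr_or_na(mrna, "lineage_slot")
  species_attr <- attr_or_na(mrna, "species")
  element_attr <- attr_or_na(mrna, "muller_element")
  source_attr <- attr_or_na(mrna, "annotation_source")

  rows <- purrr::map(seq_along(mrna), function(i) {
    id <- as.character(mrna$ID[i])
    parts <- cds[cds_parent == id]
    if (length(parts) == 0L) {
      warn(sprintf("mRNA %s has no CDS feature; skipped", id))
      return(NULL)
    }
    contig <- as.character(GenomicRanges::seqnames(parts))[1]
    if (!contig %in% names(genome)) {
      abort(sprintf("contig %s of mRNA %s not in genome FASTA", contig, id))
    }
    contig_seq <- genome[[contig]]
    if (max(GenomicRanges::end(parts)) > length(contig_seq) ||
        min(GenomicRanges::start(parts)) < 1L) {
      abort(sprintf("CDS of mRNA %s out of bounds on contig %s", id, contig))
    }
    parts <- parts[order(GenomicRanges::start(parts))]
    pieces <- Biostrings::DNAStringSet(contig_seq,
                                       start = GenomicRanges::start(parts),
                                       end = GenomicRanges::end(parts))
    seq <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
    minus <- as.character(GenomicRanges::strand(parts))[1] == "-"
    if (minus) {
      seq <- Biostrings::reverseComplement(seq)
    }
    span_lo <- min(GenomicRanges::start(parts))
    span_hi <- max(GenomicRanges::end(parts))
    fl_left <- Biostrings::subseq(contig_seq,
                                  start = max(1L, span_lo - flank),
                                  end = span_lo - 1L)
    fl_right <- Biostrings::subseq(contig_seq,
                                   start = span_hi + 1L,
                                   end = min(length(contig_seq),
                                             span_hi + flank))
    flank_chars <- paste0(as.character(fl_left), as.character(fl_right))
    seq_chr <- as.character(seq)
    n <- nchar(seq_chr)
    first_cod <- if (n >= 3) substr(seq_chr, 1, 3) else ""
    last_cod <- if (n >= 3) substr(seq_chr, n - 2, n) else ""
    has_start <- first_cod == "ATG"
    has_stop <- last_cod %in% c("TAA", "TAG", "TGA")
    if (n > 0 && has_start && has_stop && n %% 3 != 0) {
      warn(sprintf("mRNA %s: complete ORF but CDS length %d not a multiple of 3",
                   id, n))
    }
    tibble(
      gene_id = id,
      species = species_attr[i],
      lineage_slot = slot_attr[i],
      element = element_attr[i],
      cds_length = n,
      has_start_codon = has_start,
      has_stop_codon = has_stop,
      flank_has_ambiguity = grepl("[^ACGTacgt]", flank_chars),
      annotation_source = source_attr[i] %||% NA_character_,
      cds_seq = seq_chr
    )
  })
  out <- bind_rows(purrr::compact(rows))
  arrange(out, .data$gene_id)
}

#' Read a long-format expression table
#'
#' @param tsv_path TSV with header `gene_id`, `tissue`, `sex`, `fpkm`.
#' @return A tibble with those columns. Errors on negative FPKM, unknown sex
#'   tokens (anything but `F`/`M`) and duplicate (gene, tissue, sex) keys.
#' @export
read_expression_table <- function(tsv_path) {
  x <- readr::read_tsv(tsv_path, col_types = readr::cols(
    gene_id = readr::col_character(),
    tissue = readr::col_character(),
    sex = readr::col_character(),
    fpkm = readr::col_double()
  ), na = "NA")
  need <- c("gene_id", "tissue", "sex", "fpkm")
  if (!all(need %in% names(x))) {
    abort(paste0("expression table must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (nrow(x) == 0L) {
    return(as_tibble(x))
  }
  if (any(is.na(x$fpkm)) || any(x$fpkm < 0)) {
    abort("fpkm values must be non-negative and non-missing")
  }
  if (!all(x$sex %in% c("F", "M"))) {
    bad <- setdiff(unique(x$sex), c("F", "M"))
    abort(paste0("unknown sex token(s): ", paste(bad, collapse = ", ")))
  }
  dup <- duplicated(x[, c("gene_id", "tissue", "sex")])
  if (any(dup)) {
    abort(sprintf("duplicate expression keys, e.g. (%s, %s, %s)",
                  x$gene_id[dup][1], x$tissue[dup][1], x$sex[dup][1]))
  }
  as_tibble(x)
}

#' Read the ortholog-group table
#'
#' Rows whose outgroup (`dobs_id`) member is `NA` are excluded (the analysis
#' set requires an outgroup copy that anchors functionality); the number of
#' exclusions is reported as the `n_excluded_no_outgroup` attribute and via
#' a message.
#'
#' @param tsv_path TSV with columns `group_id`, `dobs_id`, `dpse_id`,
#'   `neox_id`, `neoy_id`; the literal token `NA` marks an absent member.
#' @param gene_models Gene-model tibble used to validate the gene ids.
#' @return Tibble of ortholog groups (absent members are `NA`).
#' @export
read_ortholog_map <- function(tsv_path, gene_models) {
  x <- readr::read_tsv(tsv_path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = "NA")
  need <- c("group_id", "dobs_id", "dpse_id", "neox_id", "neoy_id")
  if (!all(need %in% names(x))) {
    abort(paste0("ortholog table must have columns ",
                 paste(need, collapse = ", ")))
  }
  ids <- unlist(x[, c("dobs_id", "dpse_id", "neox_id", "neoy_id")])
  ids <- ids[!is.na(ids)]
  dangling <- setdiff(ids, gene_models$gene_id)
  if (length(dangling) > 0) {
    abort(paste0("ortholog table references unknown gene id(s): ",
                 paste(utils::head(dangling, 5), collapse = ", ")))
  }
  keep <- !is.na(x$dobs_id)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    inform(sprintf("excluded %d group(s) without an outgroup member",
                   n_excluded))
  }
  out <- as_tibble(x[keep, union(need, intersect(names(x), "element"))])
  attr(out, "n_excluded_no_outgroup") <- n_excluded
  out
}

#' Read per-group codon alignments from a FASTA file
#'
#' Records are named `group|slot` with slot one of `dobs`, `dpse`, `neox`,
#' `neoy`.
#'
#' @param fasta_path Path to the alignment FASTA.
#' @return A named list (by group id) of named character vectors of aligned
#'   sequences.
#' @export
read_codon_alignments <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- strsplit(names(seqs), "|", fixed = TRUE)
  groups <- vapply(nm, `[[`, character(1), 1)
  slots <- vapply(nm, `[[`, character(1), 2)
  split(setNames(as.character(seqs), slots), groups)
}

#' Read a sexual-antagonism label table
#'
#' @param tsv_path TSV with columns `group_id`, `label`; labels are
#'   `Fb_Md`, `Mb_Fd`, `no_conflict` or `unclassified`.
#' @return Tibble of labels.
#' @export
read_antagonism_labels <- function(tsv_path) {
  x <- readr::read_tsv(tsv_path, col_types = readr::cols(
    group_id = readr::col_character(),
    label = readr::col_character()
  ), na = "NA")
  ok <- c("Fb_Md", "Mb_Fd", "no_conflict", "unclassified")
  if (!all(x$label %in% ok)) {
    abort(paste0("unknown antagonism label(s): ",
                 paste(setdiff(unique(x$label), ok), collapse = ", ")))
  }
  if (anyDuplicated(x$group_id)) {
    abort("duplicate group ids in the label table")
  }
  as_tibble(x)
}
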