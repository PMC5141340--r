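# Synthetic study generator.
#
# Produces a complete, ground-truthed input bundle for the pipeline: per
# species gene models with genomic context (GFF3 + genome FASTA), an
# ortholog table, codon alignments evolved under branch-specific omega, a
# tissue x sex expression matrix, and sexual-antagonism labels. Planted
# pseudogenization events are manifested exactly the way the classifier is
# meant to detect them: regulatory loss as all-sample FPKM capped below the
# expression threshold, coding loss as CDS truncation (or a missing stop
# codon), deletion as an absent ortholog slot.

#' Simulation parameters
#'
#' Defaults describe the study system the pipeline targets: 1,282 ortholog
#' groups on one Muller element, per-branch event probabilities matching
#' the observed per-lineage pseudogenization proportions (neo-Y 0.584,
#' neo-X 0.189, ancestral neo-branch 0.066, autosomal comparison lineage
#' 0.179 over its full length), and branch lengths proportional to a 2 My
#' divergence with neo-sex emergence at 1 My.
#'
#' Event draws are hierarchical: a shared `Anc` event (both neo copies lost
#' for the same cause) pre-empts terminal `X`/`Y` draws; when both
#' terminals fire independently their causes are forced to differ, and a
#' `Pse` cause is forced to differ from a shared `Anc` cause, so that the
#' planted event set is exactly recoverable by parsimony (no sister-branch
#' homoplasy).
#'
#' @param n_groups Number of ortholog groups.
#' @param branch_event_prob Named probabilities for `Anc`, `X`, `Y`, `Pse`.
#' @param cause_mix Named probabilities over `regulatory`, `coding`,
#'   `both`, `deletion`.
#' @param omega_functional,omega_pseudo dN/dS used on branches where the
#'   copy is functional / pseudogenized.
#' @param branch_lengths Proposal substitution rates per site for branches
#'   `Dobs`, `Stem`, `Anc`, `Pse`, `X`, `Y`.
#' @param n_codons Codons per gene (including start and stop).
#' @param tissues Tissue vocabulary; `ovary` is female-only, `testis`
#'   male-only, the rest are sampled in both sexes.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters.
#' @param male_bias_fraction Fraction of X-pseudo/Y-functional groups whose
#'   comparison-species ortholog is planted male-biased.
#' @param male_bias_factor Fold shift applied to testis (up) expression of
#'   male-biased genes; ovary is shifted down by the same factor.
#' @param silenced_cap FPKM ceiling enforced for silenced copies
#'   (default 0.9, safely below the threshold of 1).
#' @param missing_stop_frac Fraction of coding-loss copies manifested as a
#'   missing stop codon instead of a truncation.
#' @param flank_ambiguity_frac Fraction of missing-stop copies whose flank
#'   carries an ambiguous base (yielding unclassifiable copies; default 0).
#' @param minus_strand_frac Fraction of genes placed on the minus strand.
#' @param label_freq_functional,label_freq_pseudo Antagonism label
#'   frequencies conditional on the planted neo-X functionality.
#' @param seed Integer seed (mandatory; the bundle is a pure function of
#'   the parameters).
#' @return A list of class `np_sim_params`.
#' @export
sim_params <- function(
    n_groups = 1282,
    branch_event_prob = c(Anc = 0.066, X = 0.189, Y = 0.584, Pse = 0.179),
    cause_mix = c(regulatory = 0.4, coding = 0.4, both = 0.1,
                  deletion = 0.1),
    omega_functional = 0.1,
    omega_pseudo = 0.7,
    branch_lengths = c(Dobs = 0.06, Stem = 0.02, Anc = 0.01, Pse = 0.02,
                       X = 0.01, Y = 0.01),
    n_codons = 150,
    tissues = c("ovary", "testis", "head", "thorax", "abdomen",
                "abdomen_no_gonad"),
    expr_meanlog = 1.2,
    expr_sdlog = 0.8,
    male_bias_fraction = 0.6,
    male_bias_factor = 8,
    silenced_cap = 0.9,
    missing_stop_frac = 0.25,
    flank_ambiguity_frac = 0,
    minus_strand_frac = 0.2,
    label_freq_functional = c(Fb_Md = 0.031, Mb_Fd = 0.054,
                              no_conflict = 0.911, unclassified = 0.004),
    label_freq_pseudo = c(Fb_Md = 0.048, Mb_Fd = 0.039,
                          no_conflict = 0.862, unclassified = 0.051),
    seed = 1L) {
  stopifnot(n_groups >= 1, n_codons >= 10)
  if (is.null(seed) || is.na(seed)) abort("`seed` is mandatory")
  p <- as.list(environment())
  bad <- c(p$branch_event_prob, p$cause_mix)
  if (any(bad < 0 | bad > 1)) abort("probabilities must be in [0, 1]")
  if (abs(sum(p$cause_mix) - 1) > 1e-8) abort("`cause_mix` must sum to 1")
  if (!all(.np_branches[-5] %in% names(p$branch_event_prob))) {
    abort("`branch_event_prob` needs Anc, X, Y, Pse")
  }
  structure(p, class = "np_sim_params")
}

.np_random_cds <- function(n_codons) {
  sense <- rownames(.np_site_table())
  internal <- setdiff(sense, "ATG")
  paste0("ATG",
         paste(sample(internal, n_codons - 2, replace = TRUE),
               collapse = ""),
         "TAA")
}

#' Evolve a coding sequence along one branch
#'
#' Candidate single-nucleotide changes are proposed at rate `length *
#' branch_length` (Poisson); a candidate is accepted with relative weight 1
#' when synonymous and `omega` when nonsynonymous, and rejected when it
#' creates a stop codon. The first (start) and last (stop) codons are held
#' fixed. Under purifying selection (`omega < 1`) the realized divergence
#' is accordingly below the proposal rate.
#'
#' @param sequence Stop-free-internal CDS string starting with `ATG`.
#' @param branch_length Proposal rate per site (>= 0).
#' @param omega Relative acceptance weight of nonsynonymous changes.
#' @return The evolved sequence (same length).
#' @export
simulate_codon_evolution <- function(sequence, branch_length, omega) {
  if (branch_length < 0) abort("`branch_length` must be >= 0")
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  mutable <- seq.int(4L, n - 3L) # spare start and stop codons
  n_prop <- rpois(1, n * branch_length)
  if (n_prop == 0) return(sequence)
  sites <- sample(mutable, n_prop, replace = TRUE)
  for (s in sites) {
    old <- chars[s]
    new <- sample(setdiff(.np_nucs, old), 1)
    cpos <- ((s - 1L) %/% 3L) * 3L + 1L
    cod_old <- paste(chars[cpos:(cpos + 2L)], collapse = "")
    cod_chars <- chars[cpos:(cpos + 2L)]
    cod_chars[s - cpos + 1L] <- new
    cod_new <- paste(cod_chars, collapse = "")
    aa_old <- .np_aa(cod_old)
    aa_new <- .np_aa(cod_new)
    if (aa_new == "*") next
    accept <- if (aa_new == aa_old) TRUE else runif(1) < omega
    if (accept) chars[s] <- new
  }
  paste(chars, collapse = "")
}

# draw one group's planted events under the no-homoplasy constraints:
# causes whose cause SETS overlap (e.g. "both" overlaps "regulatory")
# would be merged into a shared deeper event by parsimony, so a draw
# excludes every cause overlapping the given one
.np_plant_events <- function(p) {
  cause_set <- function(cause) {
    switch(cause, regulatory = "r", coding = "c", both = c("r", "c"),
           deletion = "d")
  }
  draw_cause <- function(exclude = NULL) {
    mix <- p$cause_mix
    if (!is.null(exclude)) {
      ex <- cause_set(exclude)
      keep <- vapply(names(mix), function(cs)
        length(intersect(cause_set(cs), ex)) == 0, logical(1))
      mix <- mix[keep]
    }
    sample(names(mix), 1, prob = mix)
  }
  events <- list()
  if (runif(1) < p$branch_event_prob[["Anc"]]) {
    events$Anc <- draw_cause()
  } else {
    if (runif(1) < p$branch_event_prob[["X"]]) events$X <- draw_cause()
    if (runif(1) < p$branch_event_prob[["Y"]]) {
      events$Y <- draw_cause(exclude = events$X)
    }
  }
  if (runif(1) < p$branch_event_prob[["Pse"]]) {
    events$Pse <- draw_cause(exclude = events$Anc)
  }
  events
}

.np_status_of_cause <- function(cause) {
  switch(cause,
         regulatory = "silenced",
         coding = "disrupted",
         both = "silenced_and_disrupted",
         deletion = "absent")
}

#' Simulate a complete study bundle
#'
#' Generates ortholog groups that are functional in the outgroup, plants
#' branch-specific pseudogenization events, evolves codon alignments under
#' branch-specific omega, manifests each event in the gene models and
#' expression matrix, and exports the full ground truth.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `np_bundle`: `gene_models`, `ortholog_map`,
#'   `expression`, `alignments` (named list of slot-named sequences),
#'   `labels`, `truth` (planted category, events, bias flags and internal
#'   node sequences) and `params`.
#' @export
simulate_study <- function(params = sim_params()) {
  if (!inherits(params, "np_sim_params")) {
    abort("`params` must come from sim_params()")
  }
  withr::with_seed(params$seed, .np_simulate_study(params))
}

.np_simulate_study <- function(p) {
  groups <- sprintf("og%04d", seq_len(p$n_groups))
  slots <- .np_slots
  contig_of <- c(dobs = "dobs_chrC", dpse = "dpse_chr3",
                 neox = "dmir_neoX", neoy = "dmir_neoY")
  species_of <- c(dobs = "Dobs", dpse = "Dpse", neox = "Dmir",
                  neoy = "Dmir")

  gene_rows <- list()
  aln <- list()
  truth_rows <- list()
  expr_rows <- list()
  label_rows <- list()

  for (gi in seq_along(groups)) {
    gid <- groups[gi]
    events <- .np_plant_events(p)
    slot_status <- c(dobs = "functional",
                     dpse = if (!is.null(events$Pse))
                       .np_status_of_cause(events$Pse) else "functional",
                     neox = if (!is.null(events$Anc))
                       .np_status_of_cause(events$Anc)
                     else if (!is.null(events$X))
                       .np_status_of_cause(events$X) else "functional",
                     neoy = if (!is.null(events$Anc))
                       .np_status_of_cause(events$Anc)
                     else if (!is.null(events$Y))
                       .np_status_of_cause(events$Y) else "functional")

    # --- sequence evolution over the tree -------------------------------
    root <- .np_random_cds(p$n_codons)
    om <- function(slot) {
      if (slot_status[[slot]] == "functional") p$omega_functional
      else p$omega_pseudo
    }
    seq_dobs <- simulate_codon_evolution(root, p$branch_lengths[["Dobs"]],
                                         p$omega_functional)
    node_a <- simulate_codon_evolution(root, p$branch_lengths[["Stem"]],
                                       p$omega_functional)
    seq_dpse <- simulate_codon_evolution(node_a, p$branch_lengths[["Pse"]],
                                         om("dpse"))
    omega_anc <- if (!is.null(events$Anc)) p$omega_pseudo else
      p$omega_functional
    node_b <- simulate_codon_evolution(node_a, p$branch_lengths[["Anc"]],
                                       omega_anc)
    seq_neox <- simulate_codon_evolution(node_b, p$branch_lengths[["X"]],
                                         om("neox"))
    seq_neoy <- simulate_codon_evolution(node_b, p$branch_lengths[["Y"]],
                                         om("neoy"))
    seqs <- c(dobs = seq_dobs, dpse = seq_dpse, neox = seq_neox,
              neoy = seq_neoy)

    cat_x <- if (slot_status[["neox"]] == "functional") "F" else "P"
    cat_y <- if (slot_status[["neoy"]] == "functional") "F" else "P"
    category <- paste0("X", cat_x, "_Y", cat_y)
    male_biased <- category == "XP_YF" && runif(1) < p$male_bias_fraction

    # --- per-slot gene models and expression ----------------------------
    for (slot in slots) {
      status <- slot_status[[slot]]
      if (status == "absent") next
      gene_id <- paste0(slot, "_", gid)
      full <- seqs[[slot]]
      cds <- full
      has_stop <- TRUE
      flank_amb <- FALSE
      coding_hit <- status %in% c("disrupted", "silenced_and_disrupted")
      if (coding_hit) {
        if (status == "disrupted" && runif(1) < p$missing_stop_frac) {
          # lost stop codon only, otherwise full length
          cds <- substr(full, 1, nchar(full) - 3)
        } else {
          # premature truncation; the stop codon is lost with the 3' end,
          # and the retained fraction stays strictly below the threshold
          retain <- runif(1, 0.2, 0.8)
          keep <- min(max(3, round(p$n_codons * retain)),
                      ceiling(0.8 * p$n_codons) - 1L)
          cds <- substr(full, 1, 3 * keep)
        }
        has_stop <- FALSE
        if (runif(1) < p$flank_ambiguity_frac) flank_amb <- TRUE
      }
      silenced_hit <- status %in% c("silenced", "silenced_and_disrupted")

      gene_rows[[length(gene_rows) + 1]] <- tibble(
        gene_id = gene_id,
        species = species_of[[slot]],
        lineage_slot = slot,
        element = "C",
        cds_length = nchar(cds),
        has_start_codon = TRUE,
        has_stop_codon = has_stop,
        flank_has_ambiguity = flank_amb,
        annotation_source = "transcriptome",
        cds_seq = cds,
        contig = contig_of[[slot]],
        group_id = gid
      )

      # expression: tissue x sex samples for this gene
      g_expr <- list()
      for (tis in p$tissues) {
        sexes <- if (tis == "ovary") "F" else if (tis == "testis") "M"
        else c("F", "M")
        if (slot == "neoy") sexes <- intersect(sexes, "M")
        for (sx in sexes) {
          v <- rlnorm(1, p$expr_meanlog, p$expr_sdlog)
          if (male_biased && slot == "dpse") {
            if (tis == "testis") v <- v * p$male_bias_factor
            if (tis == "ovary") v <- v / p$male_bias_factor
            if (tis == "abdomen" && sx == "M") v <- v * 2
          }
          if (silenced_hit) {
            v <- min(v, runif(1, 0, p$silenced_cap))
          }
          g_expr[[length(g_expr) + 1]] <-
            list(gene_id = gene_id, tissue = tis, sex = sx, fpkm = v)
        }
      }
      if (!silenced_hit) {
        # guarantee detectable expression; the neo-X is only ever assessed
        # from female samples, so its guaranteed sample must be female
        eligible <- seq_along(g_expr)
        if (slot == "neox") {
          eligible <- which(vapply(g_expr, function(r) r$sex == "F",
                                   logical(1)))
        }
        pick <- eligible[sample.int(length(eligible), 1)]
        g_expr[[pick]]$fpkm <- max(g_expr[[pick]]$fpkm, 1.5)
      }
      expr_rows <- c(expr_rows, g_expr)
    }

    aln[[gid]] <- seqs[slot_status[slots] != "absent"]

    label_pool <- if (slot_status[["neox"]] == "functional")
      p$label_freq_functional else p$label_freq_pseudo
    label_rows[[length(label_rows) + 1]] <- list(
      group_id = gid,
      label = sample(names(label_pool), 1, prob = label_pool))

    truth_rows[[length(truth_rows) + 1]] <- tibble(
      group_id = gid,
      category = category,
      status_dpse = slot_status[["dpse"]],
      status_neox = slot_status[["neox"]],
      status_neoy = slot_status[["neoy"]],
      events = paste(sprintf("%s:%s", names(events), unlist(events)),
                     collapse = ";"),
      n_events = length(events),
      male_biased = male_biased,
      seq_node_a = node_a,
      seq_node_b = node_b
    )
  }

  gene_models <- bind_rows(gene_rows)
  truth <- bind_rows(truth_rows)
  expression <- bind_rows(purrr::map(expr_rows, as_tibble))
  labels <- bind_rows(purrr::map(label_rows, as_tibble))

  ortholog_map <- truth |>
    select("group_id") |>
    mutate(
      dobs_id = paste0("dobs_", .data$group_id),
      dpse_id = ifelse(truth$status_dpse == "absent", NA,
                       paste0("dpse_", .data$group_id)),
      neox_id = ifelse(truth$status_neox == "absent", NA,
                       paste0("neox_", .data$group_id)),
      neoy_id = ifelse(truth$status_neoy == "absent", NA,
                       paste0("neoy_", .data$group_id)),
      element = "C"
    )

  structure(list(
    gene_models = gene_models,
    ortholog_map = ortholog_map,
    expression = expression,
    alignments = aln,
    labels = labels,
    truth = truth,
    params = p
  ), class = "np_bundle")
}

#' @export
print.np_bundle <- function(x, ...) {
  cat(sprintf(
    "synthetic study bundle: %d ortholog groups, %d gene models, %d expression samples\n",
    nrow(x$truth), nrow(x$gene_models), nrow(x$expression)))
  invisible(x)
}

#' Write a simulated bundle to disk in standard formats
#'
#' Emits per-species GFF3 + genome FASTA (genes laid out with 100-nt
#' flanks, a fraction on the minus strand), the expression, ortholog and
#' label TSVs, the codon alignments (records `group|slot`), the true
#' ancestral sequences and the truth table. Given the same bundle the
#' output files are byte-identical.
#'
#' @param bundle An `np_bundle` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_study_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "np_bundle")) abort("`bundle` must be an np_bundle")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- bundle$params
  paths <- list()

  # deterministic layout randomness, separated from the bundle stream
  withr::with_seed(p$seed + 1L, {
    gm <- bundle$gene_models
    gm$strand <- ifelse(runif(nrow(gm)) < p$minus_strand_frac, "-", "+")
    flank_pool <- function(n) {
      paste(sample(.np_nucs, n, replace = TRUE), collapse = "")
    }
    gm$flank_up <- vapply(seq_len(nrow(gm)), function(i) flank_pool(100),
                          character(1))
    gm$flank_dn <- vapply(seq_len(nrow(gm)), function(i) flank_pool(100),
                          character(1))
    amb <- gm$flank_has_ambiguity
    if (any(amb)) {
      gm$flank_dn[amb] <- vapply(gm$flank_dn[amb], function(fl) {
        pos <- sample.int(100, 1)
        substr(fl, pos, pos) <- "N"
        fl
      }, character(1))
    }
  })

  species_files <- split(gm, gm$species)
  for (sp in names(species_files)) {
    rows <- species_files[[sp]]
    gff <- list()
    contigs <- list()
    for (ct in unique(rows$contig)) {
      sub <- rows[rows$contig == ct, ]
      pos <- 1L
      pieces <- character(0)
      for (i in seq_len(nrow(sub))) {
        cds <- sub$cds_seq[i]
        insert <- if (sub$strand[i] == "-") {
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cds)))
        } else {
          cds
        }
        up <- if (sub$strand[i] == "-") sub$flank_dn[i] else sub$flank_up[i]
        dn <- if (sub$strand[i] == "-") sub$flank_up[i] else sub$flank_dn[i]
        pieces <- c(pieces, up, insert, dn)
        start <- pos + 100L
        end <- start + nchar(cds) - 1L
        gff[[length(gff) + 1]] <- tibble(
          contig = ct, start = start, end = end,
          strand = sub$strand[i], gene_id = sub$gene_id[i],
          lineage_slot = sub$lineage_slot[i], species = sub$species[i],
          element = sub$element[i],
          annotation_source = sub$annotation_source[i]
        )
        pos <- end + 101L
      }
      contigs[[ct]] <- paste(pieces, collapse = "")
    }
    gff <- bind_rows(gff)

    fasta_path <- file.path(dir, paste0(tolower(sp), "_genome.fa"))
    dna <- Biostrings::DNAStringSet(unlist(contigs))
    names(dna) <- names(contigs)
    Biostrings::writeXStringSet(dna, fasta_path, width = 80)

    gff_path <- file.path(dir, paste0(tolower(sp), "_genes.gff3"))
    .np_write_gff3(gff, gff_path)
    paths[[paste0(tolower(sp), "_genome")]] <- fasta_path
    paths[[paste0(tolower(sp), "_gff3")]] <- gff_path
  }

  tsv <- function(x, name) {
    path <- file.path(dir, name)
    readr::write_tsv(x, path, na = "NA")
    path
  }
  paths$expression <- tsv(bundle$expression, "expression.tsv")
  paths$orthologs <- tsv(bundle$ortholog_map, "orthologs.tsv")
  paths$labels <- tsv(bundle$labels, "labels.tsv")
  paths$truth <- tsv(select(bundle$truth, -"seq_node_a", -"seq_node_b"),
                     "truth.tsv")

  aln_seqs <- unlist(lapply(names(bundle$alignments), function(g) {
    setNames(bundle$alignments[[g]],
             paste0(g, "|", names(bundle$alignments[[g]])))
  }))
  aln_path <- file.path(dir, "alignments.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(aln_seqs), aln_path,
                              width = 80)
  paths$alignments <- aln_path

  anc <- c(setNames(bundle$truth$seq_node_a,
                    paste0(bundle$truth$group_id, "|node_a")),
           setNames(bundle$truth$seq_node_b,
                    paste0(bundle$truth$group_id, "|node_b")))
  anc_path <- file.path(dir, "ancestral_truth.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(anc), anc_path,
                              width = 80)
  paths$ancestral <- anc_path
  invisible(paths)
}

# write gene/mRNA/CDS triplets through rtracklayer
.np_write_gff3 <- function(gff, path) {
  mk <- function(type, id, parent) {
    gr <- GenomicRanges::GRanges(
      seqnames = gff$contig,
      ranges = IRanges::IRanges(gff$start, gff$end),
      strand = gff$strand
    )
    gr$type <- type
    gr$ID <- id
    if (!is.null(parent)) gr$Parent <- parent
    gr
  }
  gene <- mk("gene", paste0(gff$gene_id, ".g"), NULL)
  mrna <- mk("mRNA", gff$gene_id, paste0(gff$gene_id, ".g"))
  mrna$lineage_slot <- gff$lineage_slot
  mrna$species <- gff$species
  # "element" is a reserved metadata name in GRanges
  mrna$muller_element <- gff$element
  mrna$annotation_source <- gff$annotation_source
  cds <- mk("CDS", paste0(gff$gene_id, ".cds"), gff$gene_id)
  cds$phase <- 0L
  out <- c(gene, mrna, cds)
  out <- out[order(GenomicRanges::seqnames(out), GenomicRanges::start(out))]
  rtracklayer::export(out, path, format = "gff3")
}
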