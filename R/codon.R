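# Nei-Gojobori style codon counting machinery.
#
# Synonymous/nonsynonymous site fractions are computed per codon by
# enumerating the nine single-nucleotide mutants under the standard genetic
# code; differences between two codons are averaged over all minimal
# substitution pathways (1, 2 or 6 orderings for 1, 2 or 3 differing
# positions), excluding pathways that pass through a stop codon.

.np_nucs <- c("A", "C", "G", "T")

# amino acid for a codon ("*" for stop), standard code via Biostrings
.np_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

.np_all_codons <- function() {
  if (is.null(.np_cache$codons)) {
    g <- expand.grid(p3 = .np_nucs, p2 = .np_nucs, p1 = .np_nucs,
                     stringsAsFactors = FALSE)
    .np_cache$codons <- paste0(g$p1, g$p2, g$p3)
  }
  .np_cache$codons
}

.np_is_stop <- function(codons) .np_aa(codons) == "*"

.np_check_codon <- function(codon, arg = "codon") {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    abort(sprintf("`%s` must be a single 3-letter string", arg))
  }
  codon <- toupper(codon)
  if (!all(strsplit(codon, "")[[1]] %in% .np_nucs)) {
    abort(sprintf("`%s` contains a non-ACGT base: %s", arg, codon))
  }
  if (.np_is_stop(codon)) {
    abort(sprintf("`%s` is a stop codon (%s); stop codons carry no sites",
                  arg, codon))
  }
  codon
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three codon positions, the fraction of the three possible
#' single-nucleotide mutations that are synonymous under the standard genetic
#' code is accumulated into the synonymous site count; mutations that create
#' a stop codon count as nonsynonymous. Site counts always sum to 3.
#'
#' @param codon A single sense codon (3 characters over ACGT).
#' @return A named numeric vector with elements `n_sites` and `s_sites`.
#' @examples
#' codon_site_counts("TTT") # 1/3 synonymous site at position 3
#' @export
codon_site_counts <- function(codon) {
  codon <- .np_check_codon(codon)
  tab <- .np_site_table()
  c(n_sites = tab[codon, "n_sites"], s_sites = tab[codon, "s_sites"])
}

# 61 x 2 lookup of site counts for sense codons
.np_site_table <- function() {
  if (!is.null(.np_cache$site_table)) {
    return(.np_cache$site_table)
  }
  codons <- .np_all_codons()
  sense <- codons[!.np_is_stop(codons)]
  s <- vapply(sense, function(cod) {
    aa0 <- .np_aa(cod)
    chars <- strsplit(cod, "")[[1]]
    syn <- 0
    for (pos in 1:3) {
      for (nt in setdiff(.np_nucs, chars[pos])) {
        mut <- chars
        mut[pos] <- nt
        mutc <- paste(mut, collapse = "")
        aa1 <- .np_aa(mutc)
        if (aa1 != "*" && aa1 == aa0) syn <- syn + 1 / 3
      }
    }
    syn
  }, numeric(1))
  tab <- cbind(n_sites = 3 - s, s_sites = s)
  rownames(tab) <- sense
  .np_cache$site_table <- tab
  tab
}

#' Nonsynonymous and synonymous differences between two codons
#'
#' Differences are averaged over all minimal substitution pathways between
#' the two codons; pathways whose intermediate codons are stop codons are
#' excluded. If every pathway passes through a stop, all pathways are used
#' with a warning. The two counts always sum to the number of differing
#' positions.
#'
#' @param c1,c2 Sense codons (3-character strings over ACGT).
#' @return A named numeric vector with elements `n_diffs` and `s_diffs`.
#' @examples
#' codon_pair_diffs("TTT", "TTA") # one nonsynonymous difference (Phe -> Leu)
#' @export
codon_pair_diffs <- function(c1, c2) {
  c1 <- .np_check_codon(c1, "c1")
  c2 <- .np_check_codon(c2, "c2")
  .np_pair_diffs(c1, c2)
}

# permutations of 1..n (n <= 3), deterministic order
.np_perms <- function(n) {
  switch(n,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

.np_pair_diffs <- function(c1, c2, warn_stop_paths = TRUE) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0L) {
    return(c(n_diffs = 0, s_diffs = 0))
  }
  paths <- .np_perms(k)
  tally <- function(order, count_stops) {
    cur <- a
    nd <- 0
    sd <- 0
    for (p in pos[order]) {
      nxt <- cur
      nxt[p] <- b[p]
      cod0 <- paste(cur, collapse = "")
      cod1 <- paste(nxt, collapse = "")
      aa0 <- .np_aa(cod0)
      aa1 <- .np_aa(cod1)
      if (aa1 == "*" && !count_stops && cod1 != c2) {
        return(NULL) # pathway passes through a stop codon
      }
      if (aa0 == aa1) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd, sd)
  }
  res <- purrr::compact(purrr::map(paths, tally, count_stops = FALSE))
  if (length(res) == 0L) {
    if (warn_stop_paths) {
      warn(sprintf(
        "all substitution pathways between %s and %s pass through a stop codon; including them",
        c1, c2))
    }
    res <- purrr::map(paths, tally, count_stops = TRUE)
  }
  m <- do.call(rbind, res)
  c(n_diffs = mean(m[, 1]), s_diffs = mean(m[, 2]))
}

# full 64x64 difference lookup tables (sense codons only; others NA)
.np_pair_tables <- function() {
  if (!is.null(.np_cache$pair_tables)) {
    return(.np_cache$pair_tables)
  }
  codons <- .np_all_codons()
  sense <- codons[!.np_is_stop(codons)]
  n <- length(sense)
  nd <- matrix(NA_real_, n, n, dimnames = list(sense, sense))
  sd <- nd
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- suppressWarnings(.np_pair_diffs(sense[i], sense[j],
                                           warn_stop_paths = FALSE))
      nd[i, j] <- nd[j, i] <- d[["n_diffs"]]
      sd[i, j] <- sd[j, i] <- d[["s_diffs"]]
    }
  }
  .np_cache$pair_tables <- list(n = nd, s = sd)
  .np_cache$pair_tables
}

# split an aligned CDS string into codons
.np_codons_of <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) {
    abort(sprintf("sequence length %d is not a multiple of 3", n))
  }
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Pairwise dN/dS by Nei-Gojobori counting
#'
#' Sums synonymous/nonsynonymous sites (averaged over the two sequences) and
#' pathway-averaged differences over all comparable codons of an aligned CDS
#' pair, converts the proportions to distances with the Jukes-Cantor
#' correction `d = -(3/4) log(1 - 4p/3)`, and reports their ratio. Codons
#' containing a gap or an ambiguous base in either sequence, and stop
#' codons, are excluded from the comparison.
#'
#' @param seq_a,seq_b Aligned coding sequences of equal length (multiple of
#'   3). Gaps are `-`.
#' @return A one-row tibble with columns `n_sites`, `s_sites`, `n_diffs`,
#'   `s_diffs`, `pn`, `ps`, `dn`, `ds`, `omega` and `n_codons`. `omega` is
#'   `NA` when `ds` is 0 or a proportion is at or beyond the Jukes-Cantor
#'   saturation point (p >= 3/4).
#' @examples
#' ng86("TTT", "TTA")
#' @export
ng86 <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("aligned sequences must have equal length")
  }
  ca <- .np_codons_of(seq_a)
  cb <- .np_codons_of(seq_b)
  sense <- rownames(.np_site_table())
  ok <- ca %in% sense & cb %in% sense
  if (!any(ok)) {
    abort("no comparable codons (all gapped, ambiguous or stop)")
  }
  ca <- ca[ok]
  cb <- cb[ok]
  st <- .np_site_table()
  n_sites <- (sum(st[ca, "n_sites"]) + sum(st[cb, "n_sites"])) / 2
  s_sites <- (sum(st[ca, "s_sites"]) + sum(st[cb, "s_sites"])) / 2
  pt <- .np_pair_tables()
  idx <- cbind(match(ca, rownames(pt$n)), match(cb, colnames(pt$n)))
  n_diffs <- sum(pt$n[idx])
  s_diffs <- sum(pt$s[idx])
  pn <- n_diffs / n_sites
  ps <- s_diffs / s_sites
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dn <- jc(pn)
  ds <- jc(ps)
  omega <- if (is.na(dn) || is.na(ds) || ds == 0) NA_real_ else dn / ds
  tibble(
    n_sites = n_sites, s_sites = s_sites,
    n_diffs = n_diffs, s_diffs = s_diffs,
    pn = pn, ps = ps, dn = dn, ds = ds,
    omega = omega, n_codons = sum(ok)
  )
}
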