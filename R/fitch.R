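# Fitch parsimony ancestral reconstruction on the fixed four-taxon tree
#
#   (dobs, (dpse, (neox, neoy)))
#
# Node A is the D. miranda / D. pseudoobscura ancestor; node B the
# neo-X / neo-Y ancestor. States are encoded as bitmasks so every column is
# processed vectorised: A=1, C=2, G=4, T=8, gap=16; other IUPAC characters
# are treated as fully ambiguous {A,C,G,T}.

.np_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L, `-` = 16L)

.np_encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  v <- unname(.np_bits[chars])
  v[is.na(v)] <- 15L # ambiguity codes = {A,C,G,T}
  v
}

.np_decode_bits <- function(v) {
  out <- rep("N", length(v))
  for (nm in names(.np_bits)) out[v == .np_bits[[nm]]] <- nm
  paste(out, collapse = "")
}

# single bit -> TRUE
.np_one_bit <- function(v) v > 0L & bitwAnd(v, v - 1L) == 0L

# choose a state from each set: first preference, then second, then the
# fixed order A < C < G < T < gap
.np_pick_state <- function(set, pref1, pref2 = 0L) {
  out <- integer(length(set))
  hit <- .np_one_bit(pref1) & bitwAnd(set, pref1) > 0L
  out[hit] <- pref1[hit]
  if (length(pref2) == 1L) pref2 <- rep(pref2, length(set))
  hit2 <- out == 0L & .np_one_bit(pref2) & bitwAnd(set, pref2) > 0L
  out[hit2] <- pref2[hit2]
  for (b in unname(.np_bits)) {
    need <- out == 0L & bitwAnd(set, b) > 0L
    out[need] <- b
  }
  out
}

#' Fitch ancestral sequences on the four-taxon species tree
#'
#' Reconstructs nucleotide sequences at the two internal nodes of the fixed
#' topology `(dobs, (dpse, (neox, neoy)))`: node A (the ingroup/outgroup
#' split, i.e. the *D. miranda*/*D. pseudoobscura* ancestor) and node B (the
#' neo-X/neo-Y ancestor). Per column, Fitch state sets are formed bottom-up
#' with the outgroup as root; final states are resolved top-down
#' deterministically: node A breaks ties toward the outgroup state when it
#' is in the set, node B toward its parent's resolved state (which keeps
#' the labelling at the Fitch minimum) and then the outgroup state; any
#' remaining tie takes the first state in the order A, C, G, T, gap.
#'
#' @param alignment Named character vector (or list) of equal-length aligned
#'   sequences with names `dobs`, `dpse`, `neox`, `neoy`.
#' @return A list with elements `node_a`, `node_b` (character sequences) and
#'   `n_changes`, the Fitch minimum number of state changes over the tree.
#' @export
fitch_ancestral <- function(alignment) {
  alignment <- unlist(alignment)
  names(alignment) <- tolower(names(alignment))
  missing <- setdiff(.np_slots, names(alignment))
  if (length(missing) > 0) {
    abort(paste0("alignment is missing sequences: ",
                 paste(missing, collapse = ", ")))
  }
  lens <- nchar(alignment[.np_slots])
  if (length(unique(lens)) != 1L) {
    abort("aligned sequences must have equal length")
  }
  x <- .np_encode_seq(alignment[["neox"]])
  y <- .np_encode_seq(alignment[["neoy"]])
  p <- .np_encode_seq(alignment[["dpse"]])
  o <- .np_encode_seq(alignment[["dobs"]])

  # bottom-up state sets, counting union events (the Fitch change count)
  ib <- bitwAnd(x, y)
  union_b <- ib == 0L
  sb <- ifelse(union_b, bitwOr(x, y), ib)
  ia <- bitwAnd(sb, p)
  union_a <- ia == 0L
  sa <- ifelse(union_a, bitwOr(sb, p), ia)
  root_change <- bitwAnd(sa, o) == 0L
  n_changes <- sum(union_b) + sum(union_a) + sum(root_change)

  # top-down resolution: node A prefers the outgroup state; node B must
  # prefer its parent's state first (anything else can add a change), then
  # the outgroup state
  o_pref <- ifelse(.np_one_bit(o), o, 0L)
  fa <- .np_pick_state(sa, o_pref)
  fb <- .np_pick_state(sb, fa, pref2 = o_pref)

  list(node_a = .np_decode_bits(fa),
       node_b = .np_decode_bits(fb),
       n_changes = n_changes)
}

#' Branch-specific dN/dS on the neo-sex tree
#'
#' Reconstructs the two internal nodes with [fitch_ancestral()] and applies
#' Nei-Gojobori counting ([ng86()]) to the three focal branches: `Anc`
#' (node A to node B), `X` (node B to the neo-X tip) and `Y` (node B to the
#' neo-Y tip). If either neo-sex tip is missing from the alignment the
#' internal node B cannot be placed and no branch estimate is returned.
#'
#' @param alignment Named character vector of aligned CDS, names `dobs`,
#'   `dpse`, `neox`, `neoy` (missing neo tips allowed, see above).
#' @return A tibble with one row per estimable branch: `branch` plus the
#'   [ng86()] columns.
#' @export
branch_dnds <- function(alignment) {
  alignment <- unlist(alignment)
  names(alignment) <- tolower(names(alignment))
  have <- intersect(.np_slots, names(alignment[!is.na(alignment)]))
  if (!all(c("dobs", "dpse", "neox", "neoy") %in% have)) {
    return(tibble(branch = character(0)))
  }
  anc <- fitch_ancestral(alignment)
  bind_rows(
    mutate(ng86(anc$node_a, anc$node_b), branch = "Anc", .before = 1),
    mutate(ng86(anc$node_b, alignment[["neox"]]), branch = "X", .before = 1),
    mutate(ng86(anc$node_b, alignment[["neoy"]]), branch = "Y", .before = 1)
  )
}

#' Branch dN/dS for a set of ortholog groups
#'
#' @param alignments Named list of alignments (each as accepted by
#'   [branch_dnds()]), names are group ids.
#' @param categories Optional tibble with columns `group_id` and `category`
#'   (from [categorize_groups()]) joined onto the result.
#' @return A tibble with one row per group x branch.
#' @export
dnds_by_group <- function(alignments, categories = NULL) {
  res <- purrr::imap(alignments, function(aln, gid) {
    est <- branch_dnds(aln)
    if (nrow(est) == 0) return(NULL)
    mutate(est, group_id = gid, .before = 1)
  })
  out <- bind_rows(purrr::compact(res))
  if (!is.null(categories) && nrow(out) > 0) {
    out <- left_join(out, select(categories, "group_id", "category"),
                     by = "group_id")
  }
  out
}
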