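---
title: "Measuring pseudogenization on young neo-sex chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pseudogenization on young neo-sex chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neopseudo)
library(dplyr)
```

`neopseudo` quantifies how fast genes die on a young sex-chromosome pair.
The design needs four homologous gene copies per ancestral gene: an
outgroup copy that certifies the gene was functional before the
chromosome became sex-linked, a copy on the orthologous autosome of a
sister species, and the neo-X and neo-Y copies of the focal species. This
vignette explains the model behind each stage, the tunable parameters,
the numerical decisions, and what the synthetic-data generator does and
does not emulate.

## Functionality classification

A gene copy is reduced to three predicates:

* **E** — *expressed*: FPKM at or above `fpkm_threshold` (default 1, in
  FPKM units) in at least one tissue × sex sample. The threshold is
  inclusive: a gene at exactly 1 FPKM is expressed.
* **C** — *complete ORF*: the CDS begins with `ATG` and ends with a stop
  codon under the standard genetic code.
* **L** — *relative CDS length*: the copy's CDS length divided by the
  mean CDS length of the other members of its ortholog group. A copy with
  `L < cds_fraction_threshold` (default 0.8, dimensionless, inclusive on
  the functional side) has lost a substantial part of its reading frame.

The six rules are: E∧C with L ≥ 0.8 → `functional`; E∧C with L < 0.8 →
`disrupted`; ¬E with L ≥ 0.8 → `silenced`; ¬E with L < 0.8 →
`silenced_and_disrupted`; E∧¬C with clean 100-nt flanks → `disrupted`;
E∧¬C with an ambiguous base in a flank → `unclassified`, because the
missing terminus may be an assembly artefact rather than a mutation. A
missing ortholog slot is `absent`. Everything except `functional` and
`unclassified` is a pseudogene. The rules are exhaustive and exclusive
over the predicate lattice, which the test suite checks by enumeration.

Design points that the rule text leaves open, and the choices made here:

* **Reference length membership.** The mean could run over all non-focal
  members or only those with complete ORFs. The default uses complete
  members (falling back to all present members when none is complete):
  a truncated member would drag the reference down and mask disruptions
  in the remaining copies. `classifier_config(reference_members = "all")`
  restores the literal all-member average.
* **Non-expressed copies without start/stop** are classified by length
  alone (rules 3–4), a literal reading of the rule set.
* **Degenerate reference.** If the reference length is zero or no
  non-focal member exists, the copy is `unclassified` (with a warning)
  rather than forcing a division by zero.
* **Neo-X expression from females only.** Male RNA cannot be assigned
  unambiguously between neo-X and neo-Y, so by default
  (`neox_female_only = TRUE`) only female samples count toward E for
  neo-X copies. A male-limited neo-X gene is therefore at risk of being
  called silenced; the `rescue_genome_predictions` mode re-admits
  expression evidence for genome-only predictions
  (`annotation_source == "genome_prediction"`), which can only move calls
  out of the silenced statuses, never into them — also a property test.

## Parsimony event assignment

Statuses map to cause sets — silenced = {regulatory}, disrupted =
{coding}, silenced-and-disrupted = {regulatory, coding}, absent =
{deletion} — and events are placed on the tree
`(outgroup, (sister, (neoX, neoY)))` with the minimum number of losses,
preferring deeper events on ties:

* both neo copies pseudogenized with intersecting cause sets → one shared
  event on the ancestral branch `Anc`, labelled with the intersection
  (`both` when it contains regulatory *and* coding);
* disjoint cause sets → independent events on `X` and `Y`;
* one cause common to sister, neo-X *and* neo-Y → a single `Stem` event
  on the branch subtending their common ancestor. `Stem` events are
  reported separately and excluded from the four focal branches: folding
  them into `Anc` or `Pse` would silently inflate those rates.

Two deliberate conventions: a deletion is its own cause and is never
"shared" with a silencing (mechanistically independent mutations), and a
group with an unclassified neo-X or neo-Y copy contributes no
`X`/`Y`/`Anc` events — their placement would be a guess — but may still
contribute a `Pse` event. The assigner is verified against an exhaustive
minimum-change labelling of the internal nodes (monotone cause-set
growth, ties toward deeper labellings) over all 125 status combinations.

## Time calibration and χ² comparisons

Branch counts are only comparable over equal time spans. With divergence
at `divergence_mya` (default 2 My) and neo-sex emergence at
`emergence_mya` (default 1 My, alternative 1.5 My), sister-lineage events
are prorated linearly — a constant-rate assumption — giving fractional
counts that are kept unrounded. Two counts are compared with a 1-d.f.
equal-expectation goodness-of-fit, `(a−e)²/e + (b−e)²/e` with
`e = (a+b)/2`; the contingency analysis of antagonism labels uses the
Pearson 2×2 statistic. No continuity correction is applied anywhere and
no multiple-testing correction is attempted; p-values are upper tails of
the χ² distribution (`stats::pchisq`).

## Branch-specific dN/dS

Ancestral sequences at the two internal nodes are reconstructed per
nucleotide column by Fitch parsimony, with the outgroup as root. The
top-down pass is deterministic: the ingroup/outgroup node breaks ties
toward the outgroup state; the neo ancestor prefers its parent's state
(anything else could add a change), then the outgroup state, then the
fixed order A < C < G < T < gap. Ambiguity codes enter as {A,C,G,T}.
Nucleotide-level (rather than codon-state) reconstruction was chosen for
reproducibility and speed; the implied change count is verified against
an exhaustive per-column minimum.

Each branch (`Anc` = node-to-node, `X` and `Y` = node-to-tip) is then
scored by Nei–Gojobori counting: per-codon synonymous site fractions from
the nine single-nucleotide mutants (mutations to stops count as
nonsynonymous), differences averaged over all minimal substitution
pathways with stop-crossing pathways excluded (if every pathway crosses a
stop they are all used, with a warning), and the Jukes–Cantor correction
`d = −(3/4)·log(1 − 4p/3)`. ω is undefined when dS = 0 or a proportion
reaches the saturation point p ≥ 3/4; undefined values are excluded from
medians and reported as counts — boxplots cannot hold infinities, and any
imputation would be arbitrary. Codons containing a gap, an ambiguity or a
stop in either sequence are excluded pairwise. This estimator was chosen
because it is fully specifiable and standard; the scientific claims it
feeds are ordinal (one category's ω exceeds another's), which is robust
to the choice of counting method.

Category comparisons use a Monte-Carlo bootstrap of the median
difference: each group resampled with replacement, two-sided p-value
`2·min(P(Δ ≤ 0), P(Δ ≥ 0))` clamped to `[1/reps, 1]`, default
`reps = 1000`. The seed is an explicit argument everywhere randomness
occurs; the same seed gives bit-identical results without disturbing the
caller's RNG state.

## Expression analyses

F/M ratios are computed per tissue with a pseudocount of 0 and an
expression floor instead: a gene whose female and male values are both
below 1 FPKM is excluded rather than contributing a fabricated ratio.
The special tissue `"gonad"` pairs ovary (F) with testis (M);
gonad-removed abdomen is a first-class tissue label. The
maximum-expression tissue of a gene is accepted only if its cFPKM exceeds
every other tissue at least twofold — a scale-invariant rule, so the
default cFPKM is simply the sex-averaged FPKM, with an upper-quartile
per-tissue normaliser available (`normalize = "upper_quartile"`) for
matrices whose tissues were sequenced at very different depths.
Pseudogene:functional ratios per tissue carry 95% percentile bootstrap
CIs from resampling genes within the tissue; a tissue with no functional
gene reports an infinite ratio with the CI suppressed.

## The synthetic-data generator

`sim_params()` defaults describe the study system the pipeline targets:
1,282 ortholog groups on one Muller element; per-branch event
probabilities 0.066 (`Anc`), 0.189 (`X`), 0.584 (`Y`) and 0.179 (`Pse`,
over its full 2-My length), matching the per-lineage pseudogenization
proportions of the motivating system; emergence at half the divergence
time, reflected in branch lengths (substitution proposals per site) of
0.02 for the 2-My sister branch and 0.01 for the 1-My neo branches;
ω = 0.1 on functional branches (typical purifying selection) versus 0.7
on pseudogenized ones (relaxed constraint); 150 codons per gene;
log-normal expression with meanlog 1.2 and sdlog 0.8 (median ≈ 3.3
FPKM); a male-bias factor of 8 applied to 60% of X-pseudo/Y-functional
groups in the sister species; and antagonism label frequencies
conditional on neo-X functionality taken from the observed contingency
proportions.

Planted events are manifested exactly as the classifier is meant to see
them: regulatory loss caps every sample at 0.9 FPKM (safely below the
threshold, avoiding knife-edge flakiness), coding loss truncates the CDS
to a uniform 20–80% retained fraction — strictly below the 0.8 threshold
after rounding — or removes only the stop codon
(`missing_stop_frac = 0.25` of disrupted copies), and deletion empties
the ortholog slot. Truncated copies lose their stop codon with the 3′
end, so they never contaminate the complete-member reference length of
their group. Event draws are hierarchical and homoplasy-free by
construction: a shared `Anc` event pre-empts terminal draws, terminal
causes are forced to have disjoint cause sets, and a `Pse` cause never
overlaps a shared `Anc` cause — otherwise parsimony would (correctly)
merge the planted events into a deeper one and exact recovery would be
impossible by design rather than by defect. With these constraints the
pipeline recovers the planted event set exactly, which is an acceptance
property of the package.

What the generator does *not* emulate: indels (alignments are gapless by
construction, though the estimators accept gaps), transition/transversion
bias and codon-usage bias, rate variation among genes and sites, linked
selection, demography, recombination, transposable-element insertions,
partial silencing across tissues, and biological or technical replicates
in the expression matrix. Passing tests therefore demonstrate the
correctness of the inference machinery under its own assumptions, not
robustness to every property of real sequencing data.

## Problem sizes and reproducibility

The test suite runs the full oracle comparisons (125 status
combinations; all 61 sense codons; 100 random codon pairs), end-to-end
recovery on bundles of 120–260 groups at 40–60 codons, and bootstrap
calibration with 150 null trials at 300 replicates — sizes chosen so the
whole suite completes in well under a minute while leaving the statistics
comfortably away from their assertion bounds. `scripts/acceptance.R`
runs the synthetic study at the full default scale (1,282 groups, 150
codons) and finishes in well under a minute. Every stochastic step is
seeded; bundles and written files are byte-identical under a fixed seed.

## Known limitations

* The parsimony assigner cannot distinguish a shared ancestral loss from
  parallel same-cause losses on the two neo branches; such homoplasy is
  biologically plausible (e.g. silencing of both copies) and would be
  undercounted on the terminals.
* Proration of sister-lineage events assumes a constant pseudogenization
  rate over the divergence window.
* NG86 with Jukes–Cantor correction underestimates distances at high
  divergence and ignores transition bias; it is used for ordinal
  comparisons, not absolute rate estimation.
* Antagonism labels transferred by homology from a distant model species
  carry that assumption with them; the package records and tests the
  association but cannot validate the transfer.
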