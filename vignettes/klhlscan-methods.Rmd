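---
title: "Methods: conservation profiling and the cysteine code of Kelch-like proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation profiling and the cysteine code of Kelch-like proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klhlscan)
```

## Scope and scientific background

Keap1 (KLHL19) is the redox-sensing ubiquitin-ligase adapter that represses
the transcription factor Nrf2. Its regulation runs through two residue-level
mechanisms: covalent modification of reactive cysteines, whose reactivity is
raised by nearby basic residues (H/K/R) that stabilize the thiolate anion,
and competitive binding at the Kelch β-propeller surface that docks Nrf2's
ETGE/DLG motifs. klhlscan implements a comparative pipeline for placing
these features in their family context: which proteins qualify as Kelch-like
(BTB + BACK + Kelch-repeat architecture), how the family splits into clades,
how conserved each alignment column is, and how each reference cysteine is
distributed across ortholog group, clade and family — the "cysteine code".

The package operates on inputs a user assembles (sequences as FASTA, domain
hits as HMMER/Pfam tables, an alignment, optionally a PDB structure). It
does not run profile searches or alignment programs itself, and it does not
attempt to reproduce database-scale census numbers, which depend on
proteome versions.

## Family selection

A protein is accepted when its domain-hit table contains at least one BTB
hit, one BACK hit and `min_kelch` Kelch hits, each at or below its e-value
threshold (`filter_by_architecture()`). All thresholds default to the loose
architecture-check value of 0.1 with a single Kelch repeat required,
because Pfam typically detects only a subset of the six propeller blades
(three or four hits are common in genuine family members). Overlapping hits
count separately — the rule counts Pfam hits, it does not merge intervals.
Rejections name the first missing requirement in BTB, BACK, Kelch order.
Isoform deduplication keeps the longest sequence per gene; length ties are
broken by the lexicographically smallest id so the result is reproducible.
Loosening any threshold can only grow the accepted set, a property the test
suite checks.

## Distances and the tree

Pairwise distances are maximum-likelihood estimates under the JTT
amino-acid substitution model with uniform rates across sites. The
generator matrix Q is assembled from the published JTT exchangeabilities
and equilibrium frequencies, with rows summing to zero and scaled so one
unit of time equals one expected substitution per site at equilibrium.
For two aligned rows the likelihood of the observed residue pairs,
$\sum_{\text{sites}} \log(\pi_a P_{ab}(t))$ with $P(t) = e^{Qt}$, is
maximized over $t \in [0, t_{\max}]$ ($t_{\max} = 10$) by derivative-free
(golden-section) search with tolerance 1e-6. Columns with a gap or X in
either row are removed pairwise; identical rows return exactly 0; pairs
whose optimum reaches $t_{\max}$ are reported at the cap with a warning, as
saturation means the data carry no finite estimate. $P(t)$ is computed from
a single cached eigendecomposition of the reversible generator's symmetric
similarity transform, so each likelihood evaluation is two 20×20 matrix
products. In tests the optimizer is checked against a brute-force grid
search of the same likelihood using `Matrix::expm`, and against
`phangorn::dist.ml`, an independent implementation.

The tree is built by the standard Saitou–Nei neighbor-joining
agglomeration on the Q-criterion, written here rather than wrapped from
`ape::nj` because the contract pins down two behaviours that matter for
reproducibility: negative branch-length estimates are clamped to zero, and
ties in Q are resolved by the lexicographically smallest pair of cluster
representatives, making the topology independent of input row order. On
additive matrices NJ is exact; the suite verifies topology and path-length
recovery (to 1e-10) against trees the matrices were generated from, using
`ape` only as the comparison oracle. Two taxa produce a two-edge tree whose
path length equals the input distance.

Bootstrap support resamples the selected columns with replacement,
recomputes distances and the NJ tree per replicate, and reports for each
internal edge of the point-estimate tree the percentage of replicates
containing the same bipartition (counted with `ape::prop.clades`).
Replicates in which some pair has no comparable columns are skipped and
removed from the denominator, which the result records. Support is mapped
onto the point-estimate tree; no consensus tree is built, matching how
such trees are usually presented. A fixed seed reproduces the run exactly.

Conserved blocks stand in for manual block curation: a column qualifies
when its gap fraction is at most `max_gap_fraction` (default 0.2) and its
top-residue rank at least `min_rank` (default 0.5), and qualifying runs
shorter than `min_block_len` (default 3) are dropped. The defaults are a
deliberate automation of a manual step and are exposed for tuning.

## Column statistics

The rank of a column is the frequency of its most common residue among
non-gap rows; gaps are excluded from the denominator by default because a
gappy column should not look artificially variable (an all-rows
denominator is available via `denominator = "all"`). Classes use the
33/50/66% boundaries: ultra (≥ 0.66), conservative ([0.50, 0.66)), weak
([0.33, 0.50)), excluded (< 0.33). Each interval is closed at its lower
bound, the convention that makes the classes disjoint; the boundary table
{0.329, 0.33, 0.499, 0.50, 0.659, 0.66} →
{excluded, weak, weak, conservative, conservative, ultra} is frozen in the
tests.

The consensus takes the most frequent non-gap residue per column, breaking
ties alphabetically and reporting every tie-break. Penalty scores compare
a sequence to the consensus (or to a named reference row): each selected
column where the sequence differs from the target residue adds the target
residue's frequency in that column, so losing a near-invariant residue
costs close to 1 while losing a variable one costs little. A gap in the
scored row counts as a mismatch; in reference mode, columns where the
reference itself is gapped define no target and are skipped — both choices
are printed in the output so alternative conventions can be recomputed.
Bimodal positions report columns where one residue dominates one clade and
a different residue another (within-clade frequency ≥ θ, default 0.8, over
non-gap rows) — the signature of lineage-specific substitutions such as
tyrosine/phenylalanine swaps between neighboring clades.

## The cysteine report

`build_cysteine_report()` assembles, for every cysteine of the reference
row: its alignment column (via the reference position map), a domain label
from a user-supplied coordinate table, conservation calls in the reference
ortholog group, the reference's clade, and the whole family, and whether
basic residues flank it in the reference sequence. Conservation of a
residue in a group is `NotAlignable` when fewer than half the group's rows
are non-gap at the column (threshold exposed as `alignable`); otherwise the
presence fraction p (gaps count as absence) is called Yes at p ≥ 0.9,
Partially at 0.5 ≤ p < 0.9, No below. The 0.9/0.5 values are this
package's numeric interpretation of qualitative Yes/Partially/No
published calls; they are configurable and the fractions are always
printed so any re-thresholding is transparent. A second report section
lists family cysteine columns the reference does not share: any column,
not a reference cysteine, whose family-level call or any clade-level call
is Yes/Partially, with the clades that carry it.

The basic-flank window defaults to ±1 residue in sequence — the strict
reading of "flanked" — while spatial proximity is handled separately by
the structure module, because sequence adjacency and 3D contact are
different claims (a basic residue 20 positions away can still touch the
thiol). Reported flank sets at a given window are always supersets of
smaller windows. Motif scans use a small pattern language (exact residues,
`x` any, `b` basic H/K/R, `h` large hydrophobic L/I/V/M/F, bracketed sets)
and report all matches including overlaps; typical patterns are `KRR`
(arginine-triad mimic), `hxE` (the Cullin-binding hydrophobic–x–glutamate
motif) and `YxxGG` (the Kelch blade motif). A spacing table of cysteine
positions is available (`cysteine_spacing()`) for descriptive use; no
periodicity claim is asserted or tested.

## Structure proximity

`read_structure()` parses fixed-width ATOM records of the first model,
resolves alternate locations to the highest-occupancy conformer and
validates coordinate fields with line-numbered errors; it is cross-checked
against `bio3d::read.pdb` in the tests. `cys_basic_proximity()` measures,
for each cysteine SG, the minimum distance to the charge-bearing
side-chain nitrogens of each H/K/R (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2) —
the metric that corresponds to reported thiol–guanidinium contact
distances — with an all-atom minimum available behind `metric =
"all-atom"`. The default neighbor cutoff is 8 Å; 12 Å is used when
validating the five-residue basic environment of the reactive BTB
cysteine, since no cutoff is implied by that observation. Distances are
invariant under rigid motion of the coordinates, which the suite checks
with a random rotation.

## Synthetic families and what they do and do not show

`generate_family()` draws a root sequence from the JTT equilibrium and
evolves it down a star-of-stars clade tree using the same embedded JTT
kernel as the distance estimator, so distance-recovery experiments are
model-consistent by construction. Defaults — 5 clades × 8 taxa, 300
columns, inter-clade branches of 0.8 and intra-clade branches of 0.05
expected substitutions/site, and 15% of columns planted at each of the
ultra/conservative/weak classes — emulate a vertebrate ortholog-family
design: several species per gene, deep splits between paralog clades,
shallow divergence within them, and a conserved core. After evolution,
chance cysteines are replaced by serine (the most common residue) so that
cysteine columns exist exactly where the plan puts them; planted
conservation columns are overwritten to a target top-residue frequency
drawn away from the class boundaries (≥ 0.05 margin, so rounding cannot
flip a class); planted cysteines, lysine flanks and motif instances are
written last, and the returned truth records every engineered cell. Gap
runs can be injected afterwards (`corrupt_alignment()`) to exercise block
selection and `NotAlignable` handling, keeping the gap mask as truth.

The generator deliberately omits indels (the true alignment is the matrix
itself), alignment error, rate heterogeneity across sites and
domain-architecture structure. Passing recovery tests therefore shows that
the estimators and the report logic are correct on data matching their
model assumptions — not that a real family, with alignment uncertainty and
non-JTT evolution, will be recovered at the same rates. The architecture
filter is consequently tested on constructed hit tables, not on simulated
sequences.

## Problem sizes and numerical choices

The test suite and the acceptance script use the study-scale design:
100 seeded generator runs (5 clades × 8 taxa × 300 columns) for the clade
monophyly rate, 100 bootstrap replicates for support values, and 1e-3/1e-4
two-stage likelihood grids for the distance oracle; these sizes give
stable rates while keeping a full run in the low minutes on one CPU.
Derived seeds stay below 2^31. Optimization runs on [0, 10] with
tolerance 1e-6; transition probabilities clip eigen-decomposition
round-off at zero; branch lengths are serialized with 15 significant
digits so Newick round trips preserve path lengths to well below 1e-9.

## Surrogates for literature features

Checks that would need the real human Keap1/KLHL7 sequences or the BTB
crystal structure are run against engineered synthetic surrogates
(`keap1_surrogate()`, `klhl7_surrogate()`, `btb_site_model()`). These
plant, at the literature-documented coordinates, the 27 Keap1 cysteines,
the 10 basic-flanked cysteines, the M115–S116–E117 Cullin-binding motif,
the KLHL7 K338–R339–R340 triad mimic, and the 3.6 Å thiol–guanidinium
contact with the five-residue basic environment of C151 — on an otherwise
inert filler background, so every reported hit is a planted feature. They
validate the scanners, not the biology: reproducing the published numbers
on the real molecules requires downloading the UniProt entries and PDB
4CXI and running the same functions. Note the published record itself
carries a tension between a 10-cysteine flank list and a count of nine
"neighbored" cysteines, which hinges on an unstated neighbor definition;
the package reports the scanned set at an explicit window rather than
asserting either count as ground truth.

## Known limitations

* Clade definitions are an input (a table, or a tree cut chosen by the
  user); the package does not decide how many clades a family has.
* The JTT model is fixed; no gamma rate heterogeneity, no alternative
  exchangeability matrices.
* Domain labels in the cysteine report come from the supplied coordinate
  table; no built-in Keap1 coordinates are shipped because a complete,
  authoritative boundary table is not available offline.
* The pipeline consumes alignments; it never aligns. Alignment quality
  directly limits every column statistic.
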