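---
title: "Methods: mitogenome characterisation and TDRL rearrangement inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome characterisation and TDRL rearrangement inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorearr)
```

This vignette is the package's account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The data model

An annotated mitogenome is a circular genome of known length plus an
ordered feature table. Coordinates are 1-based and inclusive on both ends
(the GenBank convention); they always refer to the heavy (H) strand, and
light (L) strand features are reverse-complemented only when sequence is
extracted. Wrap-around features (`end < start`) have length
`genome_length - start + 1 + end`. Feature classes are PCG, tRNA, rRNA, CR
(control region) and OL (light-strand replication origin); duplicated
names are disambiguated with numeric suffixes in file order (CR1, CR2).

Validation reports rather than repairs: the shipped *Muraenesox cinereus*
table (GenBank MT571331) is carried exactly as published, including its
two internal inconsistencies. First, COI's printed length (1603 bp) is
not divisible by 3 net of a complete stop, so the validator warns; the
arithmetic of the genome's own codon totals (11,454 coding nt = 3,818
amino acids across 13 PCGs whose printed lengths sum to 11,487) works out
exactly when COI ends in an incomplete `T-` stop, which is what the
synthetic twin uses. Second, the published per-junction intergenic column
disagrees with the published coordinates at one junction (OL/trnC:
printed 7, coordinates give 11), which is why "89 bp of spacers" (the
column total) and 93 bp (the coordinate total) coexist; the spacer report
carries both and flags the discrepant junction.

## Composition, skew, codon usage

AT-skew `(A - T)/(A + T)` and GC-skew `(G - C)/(G + C)` are computed at
full precision and rounded only for display; they are identical whether
computed from counts or from the corresponding percentages. Per-gene
composition is reported on the H strand for every feature regardless of
coding strand — the convention under which the published ND6 row (an
L-strand gene) is reproducible — with `strand = "coding"` available as the
alternative. Ambiguity codes are excluded from the four counts and
tallied separately. Undefined skews (A+T = 0 or G+C = 0) are errors, not
NaNs.

Codon analysis uses the vertebrate mitochondrial code (NCBI table 2:
AGA/AGG stops, ATA Met, TGA Trp), which the genome's own AGA/AGG stop
codons require. Incomplete stop nucleotides are trimmed before counting;
a gene whose trimmed length is not a codon multiple is skipped with a
warning and listed. Ser and Leu are each treated as single six-fold
families. Amino-acid frequencies exclude the stop family from the
denominator, and gene-initial non-ATG codons (the GTG start of COI) are
counted as Met, the convention of standard codon-usage software. A
gene-inclusion filter (`exclude`) is provided rather than guessing
whether published frequencies included ND6.

## Gene orders and comparison

A gene order is a circular vector of signed tokens (`-` marks L-strand);
equality is rotation-invariant. The canonical vertebrate order is a fixed
39-token sequence starting at trnF, with OL and CR included as tokens
(control regions behave as mobile elements in rearranged genomes).

`compare_orders` first resolves duplicated labels by context: the copy
whose neighbours match the reference context is the resident element, the
rest are duplicates (both mappings are reported when the context scores
tie). It then seeks the smallest contiguous block whose removal makes the
two orders identical up to rotation. Two genuinely open numerical choices
live here:

* **Tie-break.** On a circular order, a moved block always admits a
  complementary explanation (moving the jumped-over segment the other
  way), and the two can have equal size. Ties among equally small blocks
  are broken lexicographically (C locale) on the signed block labels —
  deterministic and locale-independent. For the *M. cinereus* order this
  selects (−ND6, −E) over (Cytb, T), the description under which the
  duplicated CR sits adjacent to the moved block.
* **Anchor.** Rotation is fixed by anchoring at the reference's first
  token (conventionally trnF) before alignment.

A sign-flipped, order-reversed block is an inversion; a same-sign moved
block is a translocation (or "shuffling" when it is a single tRNA
displaced by at most two positions); anything beyond one block move plus
duplications falls back to a longest-common-subsequence decomposition and
is called complex.

`map_character_on_tree` treats the input tree as rooted as given and
reports per-state monophyly plus the smallest clade containing each
state's tips; it is deliberately a monophyly check only, not ancestral
state reconstruction.

## TDRL events and inference

A TDRL event duplicates a contiguous window of the reference in tandem
and loses duplicates: each window element is kept in copy 1, copy 2, or
both; `result = prefix + copy1-kept + copy2-kept + suffix`, both copies
in window order. An element kept in neither copy would be a deletion and
is rejected. Strand signs ride along unchanged — a TDRL event can never
invert — which gives an O(n) infeasibility short-circuit for any
sign-mismatched pair of orders.

Single-event inference scans every rotation, window start and window
length (cap 12 tokens, ample for mitogenome-scale events), and uses the
interleaving criterion: the observed tokens of the window image must
split at some point into two subsequences, each respecting window order.
This is equivalent to — and is tested against — brute-force enumeration
of all loss bipartitions. Retention in both copies is restricted to
CR-class labels by default (`both_kept` relaxes this): control regions
are the elements for which retained duplicates are actually observed, and
the restriction keeps the search space small. Scenarios are ordered by
(number of events, total window length, window, kept-in-copy-1), so the
first scenario is a minimal one; for the *M. cinereus* order the
six-token window is the unique minimum, with larger windows providing the
same transformation padded by elements kept in place.

Multi-event search (up to 3 events) is iterative-deepening: non-final
events are enumerated generatively as pure bipartitions (no both-copy
retention, so intermediate orders stay duplicate-free) and the final
event is found by the guided scan. The enumeration is exponential in
window length, so depths ≥ 2 are attempted only for desk-scale orders
(≤ 12 tokens); larger inputs report an incomplete search rather than
claiming infeasibility. Scenario results equal the observed arrangement
up to the numbering of retained copies (which copy is "CR1" is an
artefact of the loss pattern, not of the arrangement).

## Model adjudication

Four mechanisms are screened with explicit, rule-based predicates:

* **Recombination** is plausible iff an inverted block exists — it is the
  only mechanism here that reverses fragments.
* **TDRL** is plausible iff a scenario exists and, when a spacer report is
  supplied, at least 2 positive spacers fall inside or immediately flank
  the duplicated window's image in the observed order. Spacers are read
  as duplication remnants; the threshold of 2 is deliberately below the 4
  observed here, so the rule does not overfit one genome. For
  *M. cinereus* the supporting spacers are exactly the four published
  intervals (35, 4, 1, 23 bp).
* **TDNL** (duplication with loss determined by transcriptional polarity)
  is plausible iff some single event explains the order with loss exactly
  along the polarity split — copy 1 keeping the window's H-strand
  elements and copy 2 its L-strand elements (or vice versa) and nothing
  retained twice. The observed order fails this on both counts: every
  explanatory event retains the CR in both copies, and the image is
  H|L|H rather than two clean polarity blocks.
* **DRRL** (double replication between two control regions) is plausible
  iff the order carries two CRs and the elements strictly between them
  are a polarity-partitioned copy of a contiguous reference window
  containing the CR. Here *Cytb*/*trnT* lie outside the CR–CR span, so
  the predicate fails.

These are operational plausibility screens over gene orders, not
mechanistic probability statements; they are designed to be checkable
from an annotation alone and to discriminate the textbook cases (a pure
inversion, a polarity-split translocation, a CR-driven sorted
duplication) that the test suite constructs explicitly.

## The synthetic generator

`synthesis_config()` defaults define the study conditions: canonical
vertebrate template, the six-element TDRL event applied, published gene
lengths and junction gaps (reproducing the published coordinates
feature-for-feature, total 17,673 nt), background base probabilities
equal to the published whole-genome composition (A 32.1, C 23.8, G 16.6,
T 27.6, normalised), uniform sense-codon bias (a neutral default — the
composition targets only non-coding regions), and `TACAT`/`ATGTA` motifs
planted at fixed offsets in each control region. One seed drives a single
pseudo-random stream; emission is byte-reproducible.

Protein-coding genes are filled constraint-aware: start and stop anchors
are stamped first, sense codons are drawn from the bias subject to bases
already fixed by overlapping genes, and draws avoid completing a stop
triplet in any overlapping reading frame. This makes the recorded
per-gene codons exact ground truth even across the ATP8/ATP6 (10 nt) and
ND4L/ND4 (7 nt) overlaps, at the cost that codon draws inside overlaps
are not exactly bias-distributed — a few codons out of 3,828.

What the generator emulates: the layout statistics of a real rearranged
mitogenome (lengths, gaps, overlaps, strand assignment, codon structure,
CR motifs). What it does not: real nucleotide evolution — no substitution
model, no codon autocorrelation, no realistic tRNA/rRNA secondary
structure, no AT-richness gradient inside the control region. Passing
tests therefore certify the analysis machinery (slicing, frame handling,
order algebra, inference), not robustness to evolutionary noise in real
sequences.

## Problem sizes and tolerances

The test suite runs at desk scale by design: full 39/40-token orders for
the single-event analyses, 6–10-token orders for the 100-case round-trip
and oracle-equivalence checks (windows to length 6–8), and one 17,673 nt
synthetic genome per seed. Composition recovery is asserted within 3
multinomial standard errors at the region's length; codon-count recovery
and spacer-plan recovery are exact; skews recomputed from percentages are
compared at the 3-decimal precision of the published table, asserting
only the rows that are arithmetically reproducible from rounded
percentages (ND6, rRNA AT-skew) and requiring the rest to agree within
the rounding budget.

## Known limitations

* Losses (elements present in the reference but absent from the observed
  order) are outside the TDRL event model; they surface in
  `compare_orders` but make `infer_tdrl` report infeasibility.
* Multi-event scenarios that retain duplicates in a non-final event are
  not enumerated.
* The GenBank reader covers the flat-file subset this package consumes
  (LOCUS length, CDS/tRNA/rRNA/D-loop/rep_origin with gene/product/
  anticodon qualifiers), not the full format.
* Rearrangement distances (breakpoint, DCJ) and rearrangement-aware
  phylogenetics are out of scope; the tree utility checks monophyly only.
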