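---
title: "Processing and annotating immunoglobulin lineage trees"
author: "iglineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and annotating immunoglobulin lineage trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iglineage)
```

## The model

A B-cell clonal lineage is modelled as a rooted tree. The root is the
unmutated common ancestor (UCA), the germline-configuration V(D)J sequence
from which the clone descends; leaves (and occasionally internal nodes) are
observed, sequenced antibodies; the remaining internal nodes are branch
points (BPs) carrying reconstructed intermediate sequences. All node
sequences live in one shared nucleotide alignment, so every node's sequence
has the tree-wide alignment length. This is the structure that
maximum-likelihood programs emit: PHYLIP's `dnaml` stores both the topology
and the reconstructed interior sequences in its output text file (when run
with outgroup rooting on the UCA and hypothetical-sequence reconstruction),
while IgPhyML emits a newick tree per clone plus an ancestral-sequence
FASTA, with observed sequences carried in the AIRR rearrangement table.

Three post-processing steps turn a raw inference into a clean lineage:

1. **Ambiguity resolution.** `dnaml` reconstructions may contain IUPAC
   ambiguity codes at BP positions. For each such position the code is
   replaced by the base, among those the code denotes, that is most frequent
   at that position across the sequences of the *observed* descendants of
   that BP. Observed sequences are the only empirical evidence, so UCA and
   other BP sequences do not vote, and each observed leaf votes once
   regardless of how many identical copies were sequenced. Ties break by
   the fixed order A < C < G < T, making the procedure deterministic; a
   position where no descendant carries any denoted base becomes `N` with a
   warning rather than aborting the run. IgPhyML's reconstruction resolves
   ambiguities itself, so on that input route resolution runs only when
   codes are actually detected.

2. **Collapsing.** A BP whose sequence equals one of its children is a
   reconstructed intermediate that corresponds to a real antibody; the two
   nodes are merged bottom-up until a fixed point. Identity is
   case-insensitive and treats `.` and `-` as the same gap character
   (alignment artifacts), while `N` matches only `N` (explicit
   uncertainty is not a wildcard). When a BP equals several children it
   merges with the earliest in input order; the merged node keeps the
   child's identity and appends the BP's member labels. A BP equal to its
   *parent* is deliberately not collapsed — the collapse rule models the
   "theoretical BP is an existing Ig" case, which is child-directed.

3. **Clustering.** Observed sibling leaves with identical sequences are
   drawn as one node listing every member label, preserving the union of
   labels tree-wide.

After processing, surviving BPs are relabelled `BP1`, `BP2`, ... in a
deterministic pre-order traversal so repeated runs are bit-stable. A
historical member label from a collapsed-away BP that would collide with a
fresh label gets a trailing `*`.

## Mutation annotation

Every edge parent → child is compared position by position. A mutation
event is a position where both sequences hold a concrete base (A/C/G/T)
and the bases differ. Gap or `N` positions are not substitution events —
indels and uncertainty are different phenomena — but they are counted in a
separate `untallied` field so nothing is silently dropped.

Positions are reported 1-based in **alignment coordinates** (gap columns
counted), which keeps displayed positions stable across nodes; the codon
index is computed on the **gap-stripped** sequence, read in frame from
alignment position 1 (the inputs are V(D)J sequences starting at the V
gene, following the IMGT convention), which keeps translation correct.
Inserting a shared gap column therefore shifts nucleotide positions but
never changes codon indices, amino-acid effects or R/S calls. An event
whose codon context is not a clean A/C/G/T triplet on either side cannot
be translated; rather than inventing a classification it is counted in an
`untranslatable` field.

Each event's codons are translated with the standard genetic code;
replacement (R) means the amino acid changed — including changes to or
from a stop codon, printed `*` — and silent (S) means it did not. The
edge summary `nt (aa)` counts nucleotide events and the number of codons
whose translation changed (two substitutions in one codon are one
amino-acid mutation); per-region R/S tallies use the event counts, so they
always reconcile exactly with the edge's R and S event totals.

Regions come from a single-record FASTA whose sequence is the IMGT-gapped
UCA and whose header lists 6 or 7 strictly increasing 1-based inclusive
nucleotide end positions (FW1, CDR1, FW2, CDR2, FW3, CDR3, optionally
FW4) — exactly what IMGT/V-QUEST reports. Region *k* spans from the end
of region *k − 1* plus one through its own end; positions beyond the last
boundary are `UNASSIGNED`. Amino-acid positions are labelled by absolute
codon index by default; a two-column TSV can supply an alternative
numbering (e.g. Kabat with insertion codes such as `52a`). Numbering is
offline-only by design: an absolute index is always reproducible, whereas
an online numbering service is not, and the mapping file covers users who
need legacy numbering.

## The synthetic-lineage generator

`simulate_lineage()` draws a random bifurcating topology by sequential
edge splitting, an in-frame stop-free random UCA (default 360 nt, a
typical heavy-chain V(D)J length), and 1–4 substitutions per edge by
default, at positions biased 5-fold toward the CDRs — a conventional
magnitude for SHM targeting of the antigen-binding loops. With reversions
disabled (the default) a site mutated on a root path never mutates again
on that path, so the events on any edge are exactly the difference between
the endpoint sequences and path unions are exactly recoverable; this is
what makes ground-truth recovery testable bit-for-bit. Optional knobs
rewrite a fraction of BP positions as two-base IUPAC codes whose true base
retains a strict observed-descendant majority (exercising resolution), and
duplicate a fraction of leaves verbatim as siblings (exercising
clustering).

The generator emulates the *shapes and dialects* of real data — the
PHYLIP 3.69-family `dnaml` outfile (branch table plus interleaved
60-column reconstructed-sequence blocks) and the Immcantation triple — and
deliberately not SHM's sequence biology: there is no hot-spot motif model
(RGYW/WRCY), no context-dependent substitution matrix, no indels and no
sequencing error. Passing the round-trip suites therefore demonstrates
that parsing, processing, annotation and serialization are exact, not that
the package would reconstruct biology correctly from noisy real data —
reconstruction quality is the upstream tools' responsibility.

## Numerical and design choices

* **Tie-breaks** are all fixed and documented: base order A < C < G < T in
  resolution votes, earliest-child order in collapsing, pre-order BP
  numbering. Determinism was preferred over modelling freedom everywhere a
  rule was underdetermined.
* **Degenerate inputs.** A two-taxon `dnaml` document (UCA plus one
  antibody) builds a root with a single child; a one-leaf clone is UCA →
  observed. Out-of-frame translations warn and mark the trailing partial
  codon `X`.
* **Low-confidence bases.** `dnaml` prints reconstructed bases in
  lowercase when their posterior is at or below 0.95. They are normalized
  to uppercase for all computation and the positions retained per node for
  display, since silently discarding the flag would lose information and
  treating such bases differently in arithmetic would make results depend
  on a presentation detail.
* **Newick handling.** Branch lengths are parsed but never used — edges
  are annotated by mutation counts, not by time estimates. The germline
  leaf is found by a configurable label pattern (default: contains
  `GERM`, case-insensitive); after re-rooting on it, an unlabeled internal
  node left with a single child (typically the old newick root) is spliced
  out, and any other unlabeled internal node is a fatal error pointing at
  the `--asr` requirement, because positional matching of anonymous nodes
  to FASTA records cannot be guaranteed.
* **Serialization.** The XML schema is this package's own, versioned, and
  round-trips the complete data model byte-stably; the selection-analysis
  FASTA marks the germline record with a `>>` header prefix (the grouped
  submission convention; a sample accepted results file ships in
  `inst/extdata/baseline_output_synthetic.tsv`, which is synthetic). SVG
  is written directly as text so renders are byte-identical across runs.

## Problem sizes used in the test suite

The suite verifies exact ground-truth recovery on 100 seeded simulations
of 2–12 leaves at the generator's default 360 nt through both input
routes, collapse/cluster invariants (with a naive quadratic oracle for
trees of at most 12 nodes) on 200 seeded trees, ambiguity recovery on 25
simulations at a 5% perturbation rate, serialization round trips on 10
trees, and one 1000-leaf lineage run end to end — sizes chosen to exercise
every code path, the documented tie-breaks and the tool's intended scale
while keeping the suite quick to run during development.

## Known limitations

* Insertion/deletion events are surfaced only as untallied differences,
  never called as events; alignment repair is out of scope.
* The collapse rule is BP-versus-child only, and observed-leaf votes are
  unweighted by duplicate multiplicity; both are declared conventions, not
  claims about what any other implementation does.
* Kabat numbering requires a user-supplied mapping; no online lookup is
  performed.
* Selection-pressure statistics are delegated: the package writes the
  input FASTA for, and reads the summary from, the external BASELINe
  service, but does not reimplement its model.
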