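# iglineage

Processing, annotation and export of immunoglobulin (Ig) clonal lineage
trees.

## The problem

Affinity maturation drives B cells through rounds of somatic hypermutation
(SHM), producing a clonal lineage that extends from an unmutated common
ancestor (UCA) to the sequenced antibodies. Maximum-likelihood phylogenetics
— PHYLIP's `dnaml`, or IgPhyML inside the Immcantation framework — infers
the lineage topology together with reconstructed intermediate ("branch
point", BP) sequences. Turning that raw inference into something an
immunologist can interrogate requires a consistent post-processing layer:

* **Ambiguity resolution.** `dnaml` can leave IUPAC ambiguity codes in
  reconstructed BP sequences. For a code at position *p* of a BP, the base
  chosen is the one, among the bases the code denotes, that is most frequent
  at *p* across the *observed* sequences below that BP (ties break toward
  A < C < G < T; no evidence at all gives `N`).
* **Collapsing.** A BP whose sequence is identical to a child's corresponds
  to an antibody that actually exists; the two nodes are merged (bottom-up,
  to a fixed point).
* **Clustering.** Identical observed sibling sequences are drawn as one
  node listing all member labels.
* **Mutation annotation.** Every edge parent → child is annotated with its
  nucleotide substitutions; each substitution's codon is translated and the
  event classified replacement (R, amino acid changes) or silent (S), placed
  in its FW/CDR region (from an IMGT-gapped UCA FASTA whose header lists the
  region end positions), and labelled by absolute amino-acid position or by
  a user-supplied (e.g. Kabat) numbering map. Edge labels read `nt (aa)`.

Inputs are either the `dnaml` output text file (run with outgroup rooting on
the UCA and hypothetical-sequence reconstruction, menu option 5), or the
Immcantation triple: AIRR rearrangement TSV, IgPhyML clone/tree tab file and
the ancestral-sequence FASTA from `--asr`, plus a clone id. Outputs are a
lossless XML round-trip format, a JSON dump, alignment TSVs (nucleotide and
protein, with a region ruler and the UCA in the first lane), the grouped
FASTA consumed by the BASELINe selection-pressure service, and SVG/PNG/EPS
tree renderings.

A seeded simulator (`simulate_lineage()`) generates ground-truth lineages
under SHM-like edge substitutions and emits byte-valid files in every input
dialect, so the whole pipeline is testable without running any external
tool.

## Worked example

```r
library(iglineage)

sim <- simulate_lineage(seed = 1, n_leaves = 5, uca_length = 360)
files <- write_simulation_bundle(sim, "fixture")

tree <- read_dnaml_lineage(files[["dnaml"]])
tree$region_map <- parse_region_fasta(files[["region"]])
tree <- annotate_tree(tree)
tree
#> <lineage_tree> 10 nodes (5 observed, 4 branch points), alignment length 360
#>   source: DNAML
#>   9 annotated edges

ann <- tree$annotations[[tree$edges$child[[2]]]]
ann$nt_count                 # substitutions on that edge
#> [1] 3
ann$events[, c("nt_position", "from_nt", "to_nt", "aa_label",
               "from_aa", "to_aa", "rs_class", "region")]
#>   nt_position from_nt to_nt aa_label from_aa to_aa rs_class region
#> 1          91       A     G       31       S     G        R   CDR1
#> 2         175       A     C       59       N     H        R   CDR2
#> 3         304       A     T      102       M     L        R    FW3
```

Each row is one nucleotide substitution: its 1-based alignment position,
the codon (amino-acid) position it falls in, the amino-acid change, the
replacement/silent call and the FW/CDR region. The same tree exports with

```r
write_lineage_xml(tree, "tree.xml")     # lossless, byte-stable round trip
write_alignment_tsv(tree, "aln_aa.tsv", mode = "protein")
write_baseline_fasta(tree, "baseline_input.fasta")
render_tree(tree, "tree.svg")
```

or in one shot from the shell (sub-folder named after the input file):

```sh
Rscript inst/exec/iglineage run-dnaml fixture/dnaml_outfile.txt \
    --region-fasta fixture/region_uca.fasta --out output
```

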