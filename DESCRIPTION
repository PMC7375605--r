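Package: iglineage
Title: Processing, Annotation and Export of Immunoglobulin Clonal Lineage Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-processing B-cell receptor clonal lineage trees
    inferred by maximum-likelihood phylogenetics. Parses PHYLIP dnaml output
    files with reconstructed ancestral sequences, and the Immcantation triple
    (AIRR rearrangement TSV, IgPhyML clone/tree table and ancestral-sequence
    FASTA), into a common rooted lineage-tree model with the unmutated common
    ancestor (UCA) at the root. Resolves IUPAC ambiguity codes at inferred
    branch points by descendant majority vote, collapses branch points whose
    sequence equals a child, clusters identical observed sequences, and
    annotates every edge with nucleotide and amino-acid mutations classified
    as replacement or silent and mapped to antibody framework and CDR
    regions. Exports annotated trees as XML, JSON, region-ruled alignment
    TSV, selection-analysis FASTA input and static SVG/PNG/EPS renderings.
    Includes a seeded simulator of somatic-hypermutation lineages that emits
    byte-valid input files in every supported dialect, and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    xml2,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
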