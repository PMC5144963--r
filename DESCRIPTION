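Package: phylomic
Title: Phylogenomic Supermatrix Assembly and Gene-Tree Concordance Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building phylogenomic data matrices from single-copy
    ortholog sets and for quantifying incongruence among the gene trees that
    underlie them. Covers BUSCO-style genome-completeness classification from
    candidate-hit tables, genetic-code-aware translation (including the yeast
    CUG-Ser code in which CUG encodes serine), threading of coding sequences
    onto amino-acid alignments, first-and-second codon position (C12) matrix
    extraction, long-branch (spurious sequence) and length/occupancy filters,
    amino-acid and C12 supermatrix concatenation with partition and occupancy
    records, and bipartition-based signal statistics: internode certainty
    (IC/ICA) over full and partial gene trees, average bootstrap support and
    relative tree certainty for gene ranking, conflict counting between
    species trees, and the multilocus bootstrap. A synthetic-data generator
    produces species trees, discordant partial gene trees, codon alignments
    with CUG-Ser taxa and injected long-branch rogues, bootstrap tree sets,
    and labelled hit tables so the whole pipeline can be exercised and
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
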