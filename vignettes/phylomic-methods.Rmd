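---
title: "Methods: matrix construction and gene-tree concordance in phylomic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matrix construction and gene-tree concordance in phylomic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phylomic` covers the road from per-gene ortholog data to phylogenomic data
matrices and branch-wise concordance statistics. This vignette documents the
models and rules the package implements, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where more than one reasonable convention exists.

## Genome-completeness classification

Candidate hits for a BUSCO gene in a genome carry an alignment bit-score
and an aligned length; the per-gene reference standards are a bit-score
cutoff (90% of the lowest bit-score among the reference genomes) and a
reference aligned length. `classify_gene()` applies, in order:

1. retain hits with bit-score **strictly greater** than the cutoff — no
   retained hit means *missing*;
2. if every retained hit is **strictly shorter** than 95% of the reference
   aligned length, *fragmented*;
3. otherwise count the full-length retained hits (length at or above the
   95% mark, ties counting as full length): one → *complete*, two or more
   → *duplicated*.

Both boundary conventions (strict cutoff, inclusive 95% mark) are package
decisions; "higher than a preset cutoff" reads naturally as strict, and a
hit at exactly the length standard is not meaningfully "shorter". The
upstream homology search (tBLASTn, gene prediction, HMM alignment) is out
of scope: the classifier consumes its tabulated output. Only *complete*,
single-copy genes that are additionally free of in-frame stop codons count
toward the "phylo" (matrix-usable) tally; percentages are reported to one
decimal using R's `round()` (round-half-even).

## Genetic codes, translation and threading

Translation is parameterised by a genetic code so that standard-code and
CUG-Ser taxa (CUG → serine instead of leucine; stop codons unchanged) can
coexist in one ortholog group. Conventions:

* whole-codon gaps `---` translate to `-`; gaps inside a codon are a frame
  error (alignments built by threading can only contain whole-codon gaps);
* a codon containing any non-ACGT character translates to `X`; `X` counts
  as data for occupancy but is excluded from GC tallies. How the original
  pipelines translated ambiguity codes is unstated anywhere authoritative;
  `X` is this package's convention;
* any stop codon — terminal included — disqualifies a sequence: the filter
  is "no in-frame stop codons", with no terminal exception.

`thread_codons()` back-translates a (trimmed) amino-acid alignment by
replacing each residue with its source codon and each gap with `---`,
verifying per taxon that the CDS translates exactly to the ungapped row
under that taxon's code. Threading a CUG-containing CDS from a CUG-Ser
taxon under the standard code fails loudly, naming taxon and column — the
error a wrong code assignment should produce. The round trip
(translate ∘ thread) is the identity, and is tested as a property.

`extract_c12()` drops every third codon position. Third positions show much
higher GC variation across taxa than first and second positions (the
`gc_by_codon_position()` diagnostic), so C12 matrices trade a third of the
sites for reduced compositional heterogeneity and saturation. The column
law |C12| = 2 × |AA| holds per gene and for any concatenated total.

## Quality filters

* **Long branches.** A sequence is spurious or paralogous when its terminal
  branch in the per-gene ML tree is at least `factor` (default 20) times
  the median of all terminal branch lengths. The comparison is inclusive
  (≥) and the median is computed once, over the original tree — a single
  exclusion round, not an iterative peel — because one round is what the
  procedure this implements describes. The rule is scale-invariant.
* **Length.** Genes with trimmed codon alignments shorter than 500 bp
  (nucleotides, strictly) are dropped.
* **Occupancy.** Genes with fewer than ⌈`min_taxa_frac` × *n*ₜₐₓₐ⌉ taxa are
  dropped; the ceiling reproduces the 48-of-96 threshold at half occupancy
  and generalises it to any taxon count.

Sequence removal runs before the length/occupancy filters; both of those
are evaluated on the post-removal alignments, so their mutual order is
immaterial (asserted by a permutation test). Alignment trimming itself
(e.g. trimAl) is out of scope; after row removals the package only drops
columns that became entirely gap, whole codons at a time.

## Supermatrices

Genes are concatenated in lexicographic name order (fixed, for reproducible
output). A taxon absent from a gene has that gene's partition filled with
`?`, which downstream tools distinguish from within-alignment `-` indels;
which character the original matrices used is unstated, and `?` is the
choice here. Partition coordinates are 0-based half-open internally and
1-based inclusive in the emitted RAxML-style partition file, whose model
labels (`LG` for AA, `GTR` for C12) are metadata only — no model fitting
happens in this package. The relaxed-PHYLIP writer/reader pair is written
in-package because the round trip must reproduce rows, order, `?`
characters and partitions byte-for-byte, which generic `phyDat`-based IO
(which recodes characters) does not guarantee.

## Bipartitions and internode certainty

All topological comparison runs on nontrivial bipartitions (splits), stored
canonically as the block not containing the alphabetically first taxon. For
a reference bipartition *B* and a set of gene trees:

* a gene tree is **informative** iff *B* restricted to its leaf set still
  has ≥ 2 taxa in both blocks;
* an informative tree **supports** *B* when it displays the restricted
  bipartition, and otherwise every bipartition of that tree incompatible
  with the restricted reference is tallied as a **conflict**;
* conflicting bipartitions observed on different taxon subsets are pooled
  into a class when their restrictions to the shared taxa coincide (greedy
  union; the representative is the variant with the most taxa). Class
  frequencies are raw tree counts, normalised — when an adjusted frequency
  is wanted — by the reference's informative-tree count. This is the
  "observed frequency" treatment of partial trees; the exact lossless
  adjustment of Kobert-style partial IC is a documented alternative, not
  implemented, and mean-IC values computed here on real partial-tree sets
  are expected to differ somewhat from implementations that use it.

With support frequency *f₀* and the most prevalent conflict *f₁*,
`internode_certainty()` computes IC = 1 + Σ pᵢ log₂ pᵢ over
pᵢ = fᵢ/(f₀+f₁); ICA uses the reference plus all retained conflicts with
logarithm base *k*+1. The value is negated when the reference is not the
most frequent bipartition, so conflicted internodes where the evaluated
tree loses the plurality score negative. No observed conflict gives 1; no
observations at all give `NA` rather than a number. For a two-way conflict
in proportions (*q*, 1−*q*) the magnitude is 1 − H₂(*q*) (binary entropy),
which the tests check at *q* ∈ {0.5, 0.75, 0.9}.

ICA retains conflicts with frequency ≥ 5% of the informative trees by
default (`ica_threshold`): with the full unbounded tail, many near-zero
splits drive the base-(k+1) logarithm up and the score toward a degenerate
value. The threshold is exposed; 0 restores tail inclusion.

Per-gene signal is quantified by ABS (mean percent of bootstrap replicates
displaying each ML-tree internode) and RTC (mean IC of the ML tree's
internodes computed from its bootstrap trees). `rank_genes()` sorts by
score descending with ties broken by gene name ascending — deterministic
across runs — and takes ⌊`top_frac` × *n*⌋ genes. Conflicts between two
resolved species trees are counted as bipartitions of one tree absent from
the other (half the Robinson–Foulds distance), which is this package's
operational definition of "topological differences"; the multilocus
bootstrap draws one tree per gene per replicate, independently and with
replacement, under a fixed seed. Bootstrap support labels are rounded to
integer percent; IC values are reported to three decimals by the print
methods.

## The synthetic-data generator

The generator exists so that every downstream stage can be validated
against known truth. Its defaults are the shape of the study it emulates:
96 taxa, 1233 genes, 10% per-taxon per-gene missingness (mean occupancy
≈ 90%), a rogue-injection rate of 0.034 (≈ 42 affected groups in 1233),
rogue branches at 40 × the median terminal length, and alignment lengths of
167–4854 codons (501–14,562 bp). The discordant fraction defaults to 0.15,
which puts mean IC in the ~0.4 neighbourhood typical of deep yeast
phylogenomic matrices. Mechanisms, chosen for controllability rather than
realism:

* **Discordance** is a single NNI at one designated internode (the most
  balanced split of the species tree), applied to a Bernoulli share of
  genes — not a multispecies-coalescent simulation. This gives exact
  control of *which* internode conflicts and with *what* alternative,
  which is precisely what validating IC needs.
* **Sequence evolution** is i.i.d. Jukes–Cantor per nucleotide along
  branches, with stop codons rejected and resampled; no dN/dS, no rate
  heterogeneity. Downstream stages test filters and tree statistics, not
  model fit.
* **Rogues** rescale the chosen taxon's terminal branch to
  `rogue_branch_factor` × the median terminal branch length *of the
  emitted tree* (the median is solved with the rogue branch already at the
  top). Defining the multiple against the post-injection median makes
  "factor 40 injected, factor 20 detected" an exact guarantee rather than
  a distribution-dependent one, because the detector sees the same median.
  The rescaled length is recorded in the emitted gene tree, so the filter
  is testable on trees alone.
* **Bootstrap sets** (`gen_signal_genes()`) emulate heterogeneous per-gene
  signal with a quality draw *q* per gene: the gene tree is the species
  tree perturbed by Poisson(3(1−*q*)) random NNIs and each bootstrap
  replicate adds Poisson(4(1−*q*)) more. Accuracy and bootstrap sharpness
  are thereby coupled, which is what makes ABS ranking enrich for
  species-tree concordance. No attempt is made to mimic RAxML's rapid
  bootstrap algorithm.
* Gene trees never drop below 4 leaves (bipartitions are undefined
  otherwise); offending missingness draws are redone.

Passing tests on this generator therefore demonstrates correctness of the
classification, filtering, threading, concatenation and concordance
machinery under controlled pathology — not robustness to alignment error,
model misspecification, paralogy masquerading at normal branch lengths, or
coalescent gene-tree heterogeneity, none of which the generator produces.

## Validation problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own validation design: exhaustive split-oracle comparison on
all unrooted binary topologies with ≤ 7 leaves (1068 trees, plus sampled
restriction and conflict pairs); rogue recovery at the full 96-taxon,
200-gene setting with short (30–60 codon) alignments, since recovery is a
tree property and alignment length is irrelevant to it; the AA/C12 column
law at the full 1233-gene, 609,899-site scale on a 6-taxon tree; and
signal enrichment at 24 taxa × 60 genes × 40 bootstrap replicates.
Determinism is byte-level: identical config and seed reproduce identical
FASTA/Newick/TSV/JSON outputs, and the pipeline manifest records
parameters, seeds, input hashes and per-stage counts.

## Interface notes and limitations

The package's interface is its functions: generators (`synth_config()`,
`gen_*()`, `write_synth_data()`), stage functions, and the `run_pipeline()`
orchestrator driven by a config list or YAML file. No shell entry point is
shipped; the functions compose in scripts exactly as the worked example in
the README shows.

Known limitations: partial-tree IC uses the observed-frequency treatment
described above; only the standard and CUG-Ser codes are built in (the
code table is pluggable, but CUG-Ala/CUG-Leu clades are not predefined);
tree inference, alignment, trimming and model selection are deliberately
external; and the conflict count between barely-resolved trees assumes
binary inputs (polytomies reduce the bipartition sets and the count is then
asymmetric).
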