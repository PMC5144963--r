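#' Quality filters for ortholog alignments and gene trees
#'
#' Three bespoke filters applied before matrix construction: removal of
#' spurious or paralogous sequences flagged by extreme terminal branch
#' lengths in the per-gene ML tree, a minimum trimmed-alignment length,
#' and a minimum taxon occupancy per gene.
#'
#' @name qc_filters
NULL

#' Detect long-branch (spurious) sequences in a gene tree
#'
#' Flags every leaf whose terminal branch length is at least `factor`
#' times the median of all terminal branch lengths of the tree. The median
#' is computed once over the original tree (a single exclusion round, not
#' iterated), and the rule is scale-invariant: rescaling all branch
#' lengths leaves the flagged set unchanged.
#'
#' @param tree [ape::phylo] with branch lengths, at least 4 leaves.
#' @param factor positive multiplier of the median (default 20).
#' @return Character vector of flagged taxa, with attributes `median`
#'   (the median terminal branch length) and `lengths` (named numeric,
#'   flagged taxa's terminal lengths).
#' @export
detect_long_branches <- function(tree, factor = 20) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    err("tree has no branch lengths", "phylomic_invalid_argument")
  ntip <- length(tree$tip.label)
  if (ntip < 4L)
    err("tree must have at least 4 leaves", "phylomic_invalid_argument")
  tip_edge <- tree$edge[, 2L] <= ntip
  lens <- stats::setNames(tree$edge.length[tip_edge],
                          tree$tip.label[tree$edge[tip_edge, 2L]])
  med <- stats::median(lens)
  flagged <- lens[lens >= factor * med]
  structure(names(flagged), median = med, lengths = flagged)
}

#' Remove sequences from a codon alignment
#'
#' Drops the given taxa's rows, then drops any codon column that is gap in
#' every remaining row (whole codons only, so the result is still a valid
#' codon alignment).
#'
#' @param aln a [codon_alignment].
#' @param remove character vector of taxa to drop (must be a subset of the
#'   alignment's taxa; removing every taxon is an error).
#' @return A [codon_alignment].
#' @export
apply_sequence_removal <- function(aln, remove) {
  stopifnot(inherits(aln, "codon_alignment"))
  remove <- unique(as.character(remove))
  bad <- setdiff(remove, names(aln$seqs))
  if (length(bad))
    err(paste("taxa not in alignment:", paste(bad, collapse = ", ")),
        "phylomic_invalid_argument")
  keep <- setdiff(names(aln$seqs), remove)
  if (length(keep) == 0L)
    err("removal would empty the alignment", "phylomic_empty_alignment")
  seqs <- aln$seqs[keep]
  ncod <- nchar(seqs[[1L]]) %/% 3L
  if (ncod > 0L) {
    cod <- vapply(seqs, split_codons, character(ncod))
    cod <- matrix(cod, nrow = ncod) # one column per taxon
    all_gap <- apply(cod == "---", 1L, all)
    if (any(all_gap)) {
      cod <- cod[!all_gap, , drop = FALSE]
      seqs <- stats::setNames(apply(cod, 2L, paste, collapse = ""), keep)
    }
  }
  codon_alignment(aln$gene, seqs, aln$codes[keep])
}

#' Filter a gene set by alignment length and taxon occupancy
#'
#' A gene is retained iff it is not on the exclusion list, its trimmed
#' codon alignment is at least `min_len_bp` nucleotides long, and it
#' contains at least `ceiling(min_taxa_frac * total_taxa)` taxa (at the
#' study scale of 96 taxa and a 50% threshold this is 48). Both predicates
#' are evaluated on the post-removal alignment, so their order is
#' immaterial.
#'
#' @param alns list of [codon_alignment]s (after sequence removal).
#' @param min_len_bp minimum alignment length in nucleotides (default 500).
#' @param min_taxa_frac minimum fraction of the taxon universe per gene
#'   (default 0.5).
#' @param total_taxa size of the taxon universe.
#' @param excluded_genes character vector of gene names to drop outright.
#' @return List with `retained` (the surviving alignments) and `report`
#'   (data frame: `gene`, `length_bp`, `n_taxa`, `taxon_threshold`,
#'   `excluded`, `length_pass`, `occupancy_pass`, `retained`).
#' @export
filter_gene_set <- function(alns, min_len_bp = 500, min_taxa_frac = 0.5,
                            total_taxa, excluded_genes = character()) {
  if (!is_count(total_taxa) || total_taxa < 4)
    err("total_taxa must be a count >= 4", "phylomic_invalid_argument")
  thr <- ceiling(min_taxa_frac * total_taxa)
  rows <- lapply(alns, function(a) {
    stopifnot(inherits(a, "codon_alignment"))
    data.frame(gene = a$gene,
               length_bp = nchar(a$seqs[[1L]]),
               n_taxa = length(a$seqs),
               taxon_threshold = thr,
               excluded = a$gene %in% excluded_genes,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report$length_pass <- report$length_bp >= min_len_bp
  report$occupancy_pass <- report$n_taxa >= thr
  report$retained <- !report$excluded & report$length_pass & report$occupancy_pass
  list(retained = alns[report$retained], report = report)
}

#' Run long-branch screening over a set of gene trees and alignments
#'
#' Convenience wrapper over [detect_long_branches()] and
#' [apply_sequence_removal()] producing the per-removal report (gene,
#' taxon, terminal branch length and the tree's median at removal time).
#'
#' @param alns named list of [codon_alignment]s.
#' @param trees named list of [ape::phylo] gene trees (same names).
#' @param factor multiplier passed to [detect_long_branches()].
#' @return List with `alignments` (post-removal) and `removals` (data
#'   frame: `gene`, `taxon`, `terminal_length`, `median_length`).
#' @export
screen_long_branches <- function(alns, trees, factor = 20) {
  stopifnot(identical(sort(names(alns)), sort(names(trees))))
  removals <- list()
  out <- alns
  for (g in names(alns)) {
    hit <- detect_long_branches(trees[[g]], factor)
    flagged <- intersect(as.character(hit), names(alns[[g]]$seqs))
    if (length(flagged)) {
      lens <- attr(hit, "lengths")
      removals[[g]] <- data.frame(gene = g, taxon = flagged,
                                  terminal_length = unname(lens[flagged]),
                                  median_length = attr(hit, "median"),
                                  stringsAsFactors = FALSE)
      out[[g]] <- apply_sequence_removal(alns[[g]], flagged)
    }
  }
  list(alignments = out,
       removals = if (length(removals)) do.call(rbind, c(removals, list(make.row.names = FALSE)))
       else data.frame(gene = character(), taxon = character(),
                       terminal_length = numeric(), median_length = numeric(),
                       stringsAsFactors = FALSE))
}
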