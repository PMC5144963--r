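#' Bipartitions (splits) of unrooted trees
#'
#' A bipartition is the two-block partition of a tree's leaf set induced by
#' removing one internal edge. It is the unit of all topological comparison
#' in this package: conflict counting, internode certainty, and bootstrap
#' support are defined on bipartitions, not on clades, because gene trees
#' are unrooted and may contain only a subset of the taxa.
#'
#' Bipartitions are stored in canonical form: the block that does *not*
#' contain the alphabetically first taxon of the universe, so that equality
#' reduces to comparison of a single key string.
#'
#' @param block character vector, taxa on one side of the split.
#' @param taxa  character vector, the full taxon set the split is defined on
#'   (for partial gene trees this is the tree's own leaf set).
#' @return An object of class `bipartition` with elements `block`, `taxa`
#'   and `key`.
#' @seealso [bipartitions()], [restrict_split()], [splits_conflict()]
#' @export
bipartition <- function(block, taxa) {
  taxa <- sort(unique(as.character(taxa)))
  block <- sort(unique(as.character(block)))
  if (!all(block %in% taxa))
    err("bipartition block contains taxa outside the universe",
        "phylomic_invalid_argument")
  if (taxa[1L] %in% block) block <- setdiff(taxa, block)
  if (length(block) < 2L || length(taxa) - length(block) < 2L)
    err("bipartition is trivial: both blocks must contain at least 2 taxa",
        "phylomic_invalid_argument")
  structure(list(block = block, taxa = taxa,
                 key = paste(block, collapse = "\r")),
            class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  other <- setdiff(x$taxa, x$block)
  cat(sprintf("<bipartition on %d taxa> %s | %s\n", length(x$taxa),
              paste(x$block, collapse = ","), paste(other, collapse = ",")))
  invisible(x)
}

#' @export
format.bipartition <- function(x, ...) {
  paste(paste(x$block, collapse = ","), "|",
        paste(setdiff(x$taxa, x$block), collapse = ","))
}

#' Extract all nontrivial bipartitions of a tree
#'
#' One bipartition per internal edge. An unrooted, fully resolved tree on
#' `n` leaves has `n - 3` internal edges and therefore `n - 3` nontrivial
#' bipartitions. Rooted input is unrooted first; trees with fewer than four
#' leaves (or no internal edges, e.g. a star tree) yield an empty list.
#'
#' @param tree an [ape::phylo] tree.
#' @return List of `bipartition` objects, with a character attribute `keys`
#'   giving their canonical keys in the same order.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' bipartitions(tr)
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(structure(list(), keys = character(0)))
  tree <- ape::unroot(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- tree$Nnode
  tipsets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- tree$tip.label[i]
  pe <- po$edge
  for (k in seq_len(nrow(pe))) {
    p <- pe[k, 1L]; ch <- pe[k, 2L]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  root <- ntip + 1L
  taxa <- sort(tree$tip.label)
  internal_children <- pe[, 2L][pe[, 2L] > ntip & pe[, 2L] != root]
  splits <- vector("list", length(internal_children))
  j <- 0L
  for (ch in internal_children) {
    blk <- tipsets[[ch]]
    if (length(blk) < 2L || ntip - length(blk) < 2L) next
    j <- j + 1L
    splits[[j]] <- bipartition(blk, taxa)
  }
  splits <- splits[seq_len(j)]
  structure(splits, keys = vapply(splits, `[[`, character(1), "key"))
}

#' Restrict a bipartition to a taxon subset
#'
#' Intersects both blocks with `taxa`. If either intersected block has fewer
#' than two taxa the bipartition is uninformative on that subset and `NULL`
#' is returned. This is how splits on the full taxon set are matched against
#' partial gene trees.
#'
#' @param bip a [bipartition].
#' @param taxa character vector of taxa to keep.
#' @return A `bipartition` on `intersect(bip$taxa, taxa)`, or `NULL`.
#' @export
restrict_split <- function(bip, taxa) {
  stopifnot(inherits(bip, "bipartition"))
  taxa <- intersect(bip$taxa, taxa)
  a <- intersect(bip$block, taxa)
  if (length(a) < 2L || length(taxa) - length(a) < 2L) return(NULL)
  bipartition(a, taxa)
}

#' Test whether two bipartitions conflict
#'
#' Two splits conflict (are incompatible) when, restricted to their shared
#' taxon set, all four pairwise block intersections are nonempty — i.e. no
#' single tree can display both. Splits that become uninformative on the
#' shared taxa are compatible by convention.
#'
#' @param a,b [bipartition] objects (possibly on different taxon sets).
#' @return Logical scalar.
#' @export
splits_conflict <- function(a, b) {
  shared <- intersect(a$taxa, b$taxa)
  if (length(shared) < 4L) return(FALSE)
  a1 <- intersect(a$block, shared)
  if (length(a1) < 2L || length(shared) - length(a1) < 2L) return(FALSE)
  b1 <- intersect(b$block, shared)
  if (length(b1) < 2L || length(shared) - length(b1) < 2L) return(FALSE)
  a2 <- setdiff(shared, a1)
  b2 <- setdiff(shared, b1)
  length(intersect(a1, b1)) > 0L && length(intersect(a1, b2)) > 0L &&
    length(intersect(a2, b1)) > 0L && length(intersect(a2, b2)) > 0L
}

#' Count topological conflicts between two trees
#'
#' Counts the bipartitions of `tree_a` absent from `tree_b`. For two fully
#' resolved (binary) trees on the same leaf set this is symmetric and equals
#' half the Robinson–Foulds distance; it is the criterion used to report
#' "topological differences" between species trees estimated by different
#' methods or data matrices.
#'
#' @param tree_a,tree_b [ape::phylo] trees on identical leaf sets.
#' @return List with `count` (integer) and `conflicting` (list of
#'   [bipartition]s of `tree_a` absent from `tree_b`).
#' @export
count_conflicts <- function(tree_a, tree_b) {
  stopifnot(inherits(tree_a, "phylo"), inherits(tree_b, "phylo"))
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    err("trees must share an identical leaf set", "phylomic_invalid_argument")
  sa <- bipartitions(tree_a)
  sb <- bipartitions(tree_b)
  missing <- !(attr(sa, "keys") %in% attr(sb, "keys"))
  list(count = sum(missing), conflicting = sa[missing])
}
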