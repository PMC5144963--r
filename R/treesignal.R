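#' Gene-tree signal and incongruence statistics
#'
#' Bipartition-based machinery for quantifying how a collection of
#' (possibly partial) gene trees supports or conflicts with each internal
#' branch of a reference species tree: split frequencies, internode
#' certainty (IC/ICA), average bootstrap support (ABS) and relative tree
#' certainty (RTC) for per-gene signal ranking, multilocus bootstrap
#' resampling, and bootstrap support mapping.
#'
#' @name treesignal
NULL

# cache of per-tree split sets: list(splits=, keys=, taxa=)
tree_split_cache <- function(trees) {
  lapply(trees, function(tr) {
    sp <- bipartitions(tr)
    list(splits = sp, keys = attr(sp, "keys"), taxa = sort(tr$tip.label))
  })
}

# does a cached tree (ts) display bipartition `bip`? NA = uninformative.
# fast path when the tree's taxa all lie inside bip's universe (then the
# restricted reference lives on the tree's own taxon set and key equality
# suffices); otherwise tree splits are restricted to bip's universe first
tree_displays <- function(ts, bip) {
  r <- restrict_split(bip, ts$taxa)
  if (is.null(r)) return(NA)
  if (all(ts$taxa %in% bip$taxa)) return(r$key %in% ts$keys)
  for (s in ts$splits) {
    rs <- restrict_split(s, r$taxa)
    if (!is.null(rs) && rs$key == r$key) return(TRUE)
  }
  FALSE
}

# core tally over cached tree splits; pools conflicting splits from partial
# trees into restriction-compatibility classes (two splits pool when their
# restrictions to shared taxa are equal and nontrivial)
split_frequencies_cached <- function(ref_bip, cache) {
  support <- 0L
  informative <- 0L
  classes <- list() # each: list(rep = bipartition, count = int)
  for (ts in cache) {
    r <- restrict_split(ref_bip, ts$taxa)
    if (is.null(r)) next
    informative <- informative + 1L
    if (isTRUE(tree_displays(ts, ref_bip))) {
      support <- support + 1L
      next
    }
    for (s in ts$splits) {
      if (!splits_conflict(r, s)) next
      placed <- FALSE
      for (j in seq_along(classes)) {
        rep <- classes[[j]]$rep
        if (identical(rep$taxa, s$taxa)) {
          same <- rep$key == s$key
        } else {
          shared <- intersect(rep$taxa, s$taxa)
          r1 <- restrict_split(rep, shared)
          r2 <- restrict_split(s, shared)
          same <- !is.null(r1) && !is.null(r2) && r1$key == r2$key
        }
        if (same) {
          classes[[j]]$count <- classes[[j]]$count + 1L
          if (length(s$taxa) > length(rep$taxa)) classes[[j]]$rep <- s
          placed <- TRUE
          break
        }
      }
      if (!placed) classes[[length(classes) + 1L]] <- list(rep = s, count = 1L)
    }
  }
  counts <- vapply(classes, `[[`, integer(1), "count")
  ord <- order(counts, decreasing = TRUE)
  structure(list(reference = ref_bip,
                 support = support,
                 conflicts = lapply(classes[ord], `[[`, "rep"),
                 conflict_counts = counts[ord],
                 n_informative = informative),
            class = "split_frequencies")
}

#' Split frequencies of a reference bipartition across gene trees
#'
#' A gene tree is *informative* for the reference bipartition when the
#' bipartition restricted to the tree's leaf set is still nontrivial.
#' Among informative trees, those containing the restricted reference count
#' as support; in the remainder, every bipartition incompatible with the
#' restricted reference is tallied. Conflicting splits observed on
#' different taxon subsets are pooled into a class when their restrictions
#' to the shared taxa agree; the class frequency is the number of trees
#' contributing to it. Frequencies are raw tree counts; `n_informative`
#' gives the normaliser for adjusted (per-informative-tree) frequencies.
#'
#' @param ref_bip a [bipartition] on the full taxon universe.
#' @param gene_trees list of [ape::phylo] gene trees (partial trees allowed).
#' @return A `split_frequencies` object: `reference`, `support` (count),
#'   `conflicts` (list of bipartitions, frequency-descending),
#'   `conflict_counts`, `n_informative`.
#' @export
split_frequencies <- function(ref_bip, gene_trees) {
  stopifnot(inherits(ref_bip, "bipartition"))
  split_frequencies_cached(ref_bip, tree_split_cache(gene_trees))
}

#' @export
print.split_frequencies <- function(x, ...) {
  cat(sprintf("<split frequencies> support %d / %d informative trees; %d conflicting class(es)\n",
              x$support, x$n_informative, length(x$conflicts)))
  if (length(x$conflict_counts))
    cat("  top conflict frequency:", x$conflict_counts[1L], "\n")
  invisible(x)
}

#' Internode certainty from split frequencies
#'
#' Entropy-based certainty of one internal branch given how often a set of
#' gene trees contains it versus its most prevalent conflicting
#' bipartition(s).
#'
#' With reference frequency `f0` and most-prevalent conflict `f1`,
#' `p_i = f_i / (f0 + f1)`, IC is `1 + sum(p_i * log2(p_i))`: 1 when all
#' trees agree, 0 when the two resolutions are equally frequent. ICA
#' generalises to the reference plus all retained conflicting bipartitions
#' (`k + 1` frequencies, logarithm base `k + 1`). In both modes the value
#' is negated when the reference is not the most frequent bipartition, so
#' negative values flag internodes where the evaluated tree contradicts the
#' plurality of gene trees. With no conflict observed the value is 1; with
#' no observations at all it is `NA`.
#'
#' @param f a `split_frequencies` object (or a list with `support`,
#'   `conflict_counts` and `n_informative`).
#' @param mode `"IC"` (reference vs top conflict) or `"ICA"` (reference vs
#'   all retained conflicts).
#' @param ica_threshold conflicts with frequency below this fraction of
#'   informative trees are dropped in ICA mode (default 0.05); prevents a
#'   long tail of rare splits from flattening the score.
#' @return Numeric scalar in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' f <- list(support = 30, conflict_counts = 10, n_informative = 40)
#' internode_certainty(f) # 0.1887
#' @export
internode_certainty <- function(f, mode = c("IC", "ICA"), ica_threshold = 0.05) {
  mode <- match.arg(mode)
  f0 <- as.numeric(f$support)
  cf <- as.numeric(f$conflict_counts)
  cf <- cf[cf > 0]
  if (length(cf) == 0L) {
    if (f0 > 0) return(1)
    return(NA_real_)
  }
  if (mode == "IC") {
    f1 <- cf[1L]
    p <- c(f0, f1) / (f0 + f1)
    p <- p[p > 0]
    v <- 1 + sum(p * log2(p))
    if (f1 > f0) v <- -v
    return(v)
  }
  keep <- cf >= ica_threshold * max(1, f$n_informative)
  cf <- cf[keep]
  if (length(cf) == 0L) return(if (f0 > 0) 1 else NA_real_)
  k <- length(cf)
  p <- c(f0, cf) / (f0 + sum(cf))
  p <- p[p > 0]
  v <- 1 + sum(p * log(p, base = k + 1))
  if (max(cf) > f0) v <- -v
  v
}

#' Annotate a reference tree with internode certainty values
#'
#' Computes IC (or ICA) for every internal branch of `ref_tree` from a set
#' of gene trees, and the mean across all internodes — the headline summary
#' of matrix-wide incongruence. An unrooted binary tree on `n` taxa has
#' `n - 3` internal branches.
#'
#' @inheritParams internode_certainty
#' @param ref_tree [ape::phylo], binary, on the full taxon universe.
#' @param gene_trees list of [ape::phylo] (partial trees allowed).
#' @return An `annotated_tree`: list with `tree`, per-internode data frame
#'   `table` (columns `split`, `ic`, `support`, `top_conflict`,
#'   `n_informative`) and `mean_ic` (mean over internodes, `NA`s excluded).
#' @export
annotate_ic <- function(ref_tree, gene_trees, mode = c("IC", "ICA"),
                        ica_threshold = 0.05) {
  mode <- match.arg(mode)
  ref_splits <- bipartitions(ref_tree)
  if (length(ref_splits) == 0L)
    err("reference tree has no internal branches", "phylomic_invalid_argument")
  cache <- tree_split_cache(gene_trees)
  rows <- lapply(ref_splits, function(s) {
    fr <- split_frequencies_cached(s, cache)
    data.frame(split = format(s),
               ic = internode_certainty(fr, mode, ica_threshold),
               support = fr$support,
               top_conflict = if (length(fr$conflict_counts))
                 fr$conflict_counts[1L] else 0L,
               n_informative = fr$n_informative,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(tree = ref_tree, table = tab,
                 mode = mode,
                 mean_ic = mean(tab$ic, na.rm = TRUE)),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat(sprintf("<annotated tree> %d internodes, mean %s = %.3f\n",
              nrow(x$table), x$mode, x$mean_ic))
  invisible(x)
}

#' Average bootstrap support of a gene's ML tree
#'
#' For each internal branch of the gene's ML tree, support is the
#' percentage of bootstrap replicate trees containing that bipartition
#' (restricted to the replicate's taxa when leaf sets differ); ABS is the
#' mean over internal branches. Used to rank genes by phylogenetic signal.
#'
#' @param boot_trees list of [ape::phylo] bootstrap replicates for one gene.
#' @param ml_tree the gene's ML tree ([ape::phylo], at least 4 leaves).
#' @return List with `abs` (mean percent), `per_edge` (numeric vector of
#'   percentages named by split). `abs` is `NA` when the ML tree has no
#'   internal edges.
#' @export
abs_score <- function(boot_trees, ml_tree) {
  if (length(boot_trees) == 0L)
    err("boot_trees must be nonempty", "phylomic_invalid_argument")
  ml_splits <- bipartitions(ml_tree)
  if (length(ml_splits) == 0L)
    return(list(abs = NA_real_, per_edge = numeric(0)))
  cache <- tree_split_cache(boot_trees)
  per_edge <- vapply(ml_splits, function(s) {
    hit <- vapply(cache, function(ts) isTRUE(tree_displays(ts, s)), logical(1))
    100 * sum(hit) / length(cache)
  }, numeric(1))
  names(per_edge) <- vapply(ml_splits, format, character(1))
  list(abs = mean(per_edge), per_edge = per_edge)
}

#' Relative tree certainty of a gene's ML tree
#'
#' IC is computed for every internal branch of the ML tree from the gene's
#' bootstrap replicate trees (via [split_frequencies()] and
#' [internode_certainty()]); RTC is the mean of those IC values.
#'
#' @inheritParams abs_score
#' @param mode,ica_threshold passed to [internode_certainty()].
#' @return List with `rtc` (mean IC) and `per_edge` (named numeric vector).
#' @export
rtc_score <- function(boot_trees, ml_tree, mode = "IC", ica_threshold = 0.05) {
  if (length(boot_trees) == 0L)
    err("boot_trees must be nonempty", "phylomic_invalid_argument")
  ml_splits <- bipartitions(ml_tree)
  if (length(ml_splits) == 0L)
    return(list(rtc = NA_real_, per_edge = numeric(0)))
  cache <- tree_split_cache(boot_trees)
  per_edge <- vapply(ml_splits, function(s) {
    internode_certainty(split_frequencies_cached(s, cache), mode, ica_threshold)
  }, numeric(1))
  names(per_edge) <- vapply(ml_splits, format, character(1))
  list(rtc = mean(per_edge, na.rm = TRUE), per_edge = per_edge)
}

#' Rank genes by a signal score and take the top fraction
#'
#' Genes are sorted by score descending with ties broken by gene name
#' ascending (deterministic across runs); the subset size is
#' `floor(top_frac * n)`.
#'
#' @param scores named numeric vector, one score per gene.
#' @param top_frac fraction of genes to keep, in (0, 1].
#' @return Character vector of gene names, best first.
#' @examples
#' rank_genes(c(a = 1, b = 1, c = 0, d = 0), 0.5) # "a" "b"
#' @export
rank_genes <- function(scores, top_frac) {
  if (length(scores) == 0L)
    err("scores must be nonempty", "phylomic_invalid_argument")
  if (is.null(names(scores)) || anyNA(names(scores)))
    err("scores must be named by gene", "phylomic_invalid_argument")
  if (!is.numeric(top_frac) || top_frac <= 0 || top_frac > 1)
    err("top_frac must be in (0, 1]", "phylomic_invalid_argument")
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(floor(top_frac * length(scores)))]
}

#' Overlap between two gene subsets
#'
#' @param a,b character vectors of gene names.
#' @return List with `jaccard` (`|a n b| / |a u b|`, `NA` if both empty)
#'   and `shared` (intersection size).
#' @export
subset_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  un <- length(union(a, b))
  inter <- length(intersect(a, b))
  list(jaccard = if (un == 0L) NA_real_ else inter / un, shared = inter)
}

#' Multilocus bootstrap resampling of gene trees
#'
#' Each replicate draws, for every gene, one tree uniformly at random from
#' that gene's set of bootstrap trees (with replacement across replicates).
#' This is the resampling scheme used to assess the robustness of
#' coalescence-based species trees.
#'
#' @param boot_sets named list; each element a nonempty list of
#'   [ape::phylo] bootstrap trees for one gene.
#' @param n_reps number of replicates.
#' @param seed integer seed; fixed seed gives identical draws across runs.
#' @return List with `replicates` (list of `n_reps` named gene-tree lists)
#'   and `draws` (`n_reps x n_genes` integer matrix of chosen indices).
#' @export
multilocus_bootstrap <- function(boot_sets, n_reps, seed = NULL) {
  if (length(boot_sets) == 0L || is.null(names(boot_sets)))
    err("boot_sets must be a named nonempty list", "phylomic_invalid_argument")
  sizes <- vapply(boot_sets, length, integer(1))
  if (any(sizes < 1L))
    err(paste0("empty bootstrap set for gene(s): ",
               paste(names(boot_sets)[sizes < 1L], collapse = ", ")),
        "phylomic_invalid_argument")
  draws <- with_seed(seed, {
    m <- vapply(sizes, function(k) sample.int(k, n_reps, replace = TRUE),
                integer(n_reps))
    matrix(m, nrow = n_reps, dimnames = list(NULL, names(boot_sets)))
  })
  replicates <- lapply(seq_len(n_reps), function(r) {
    stats::setNames(lapply(names(boot_sets), function(g)
      boot_sets[[g]][[draws[r, g]]]), names(boot_sets))
  })
  list(replicates = replicates, draws = draws)
}

#' Map bootstrap support onto a reference tree
#'
#' Per internal branch, support is the percentage of replicate trees
#' containing that bipartition, rounded to the nearest integer percent
#' (the convention for tree-figure labels).
#'
#' @param ref_tree [ape::phylo] reference tree.
#' @param replicate_trees list of [ape::phylo] on the same leaf set.
#' @return List with `tree`, and `table` (data frame: `split`, `support`).
#' @export
map_support <- function(ref_tree, replicate_trees) {
  for (tr in replicate_trees)
    if (!setequal(tr$tip.label, ref_tree$tip.label))
      err("replicate trees must share the reference leaf set",
          "phylomic_invalid_argument")
  ref_splits <- bipartitions(ref_tree)
  keysets <- lapply(replicate_trees, function(tr) attr(bipartitions(tr), "keys"))
  support <- vapply(ref_splits, function(s) {
    hits <- sum(vapply(keysets, function(k) s$key %in% k, logical(1)))
    as.integer(round(100 * hits / length(replicate_trees)))
  }, integer(1))
  list(tree = ref_tree,
       table = data.frame(split = vapply(ref_splits, format, character(1)),
                          support = support, stringsAsFactors = FALSE))
}
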