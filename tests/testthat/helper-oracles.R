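# Independent brute-force oracles, deliberately separate from the package's
# postorder/canonical-key machinery.

# All nontrivial splits of a tree by deleting each edge of the adjacency
# graph in turn and flooding one component (graph reachability, no clade
# bookkeeping). Returns a character vector of canonical "a,b,c" strings.
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  nn <- ntip + tree$Nnode
  out <- character(0)
  for (k in seq_len(nrow(edges))) {
    adj <- vector("list", nn)
    for (j in seq_len(nrow(edges))) {
      if (j == k) next
      a <- edges[j, 1L]; b <- edges[j, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    seen <- logical(nn)
    queue <- edges[k, 2L]
    seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    side <- sort(tree$tip.label[which(seen[seq_len(ntip)])])
    if (length(side) < 2L || ntip - length(side) < 2L) next
    if (sort(tree$tip.label)[1L] %in% side)
      side <- sort(setdiff(tree$tip.label, side))
    out <- c(out, paste(side, collapse = ","))
  }
  sort(unique(out))
}

split_key_str <- function(bip) paste(bip$block, collapse = ",")

# 4-taxon test tree with chosen terminal branch lengths
tree_with_terminals <- function(lens) {
  n <- length(lens)
  tips <- paste0("x", seq_len(n))
  tr <- ape::rtree(n, rooted = FALSE)
  tr$tip.label <- tips
  tip_edge <- tr$edge[, 2L] <= n
  tr$edge.length[tip_edge] <- lens[tr$edge[tip_edge, 2L]]
  tr$edge.length[!tip_edge] <- 0.5
  tr
}

# random aa alignment with gaps plus consistent CDS per taxon, built by
# sampling a codon for every residue (reverse of translation; independent
# of thread_codons)
random_threading_case <- function(n_taxa = 4, n_col = 12, cug = character(),
                                  seed = 1) {
  set.seed(seed)
  code_std <- Biostrings::GENETIC_CODE
  code_cug <- code_std; code_cug[["CTG"]] <- "S"
  aas <- setdiff(unique(code_std), "*")
  taxa <- paste0("s", seq_len(n_taxa))
  rows <- character(n_taxa); cds <- character(n_taxa)
  for (i in seq_len(n_taxa)) {
    tab <- if (taxa[i] %in% cug) code_cug else code_std
    res <- sample(aas, n_col, replace = TRUE)
    gap <- runif(n_col) < 0.25
    res[gap] <- "-"
    codons <- vapply(res[!gap], function(a)
      sample(names(tab)[tab == a], 1L), character(1))
    rows[i] <- paste(res, collapse = "")
    cds[i] <- paste(codons, collapse = "")
  }
  list(aa = aa_alignment("g1", stats::setNames(rows, taxa)),
       cds = stats::setNames(cds, taxa),
       codes = stats::setNames(rep("cug_ser", length(cug)), cug))
}

small_codon_aln <- function() {
  codon_alignment("g1", c(
    a = "ATGAAACCCGGG",
    b = "ATGAAA---GGG",
    c = "ATGTTTCCCGGG",
    d = "ATG---CCCGGG"))
}
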