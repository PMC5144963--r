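#' Synthetic phylogenomic data generation
#'
#' Generators that emulate the shape of a yeast phylogenomics study —
#' a 96-taxon species tree, on the order of a thousand single-copy gene
#' families with controlled topological discordance and missing taxa,
#' in-frame codon alignments with CUG-Ser taxa and injected long-branch
#' rogue sequences, bootstrap tree sets, and labelled BUSCO-style hit
#' tables — so every downstream stage (classification, translation,
#' filtering, concatenation, signal statistics) can be tested against
#' known truth without any external data.
#'
#' Sequence evolution is deliberately simple: i.i.d. Jukes–Cantor
#' substitution per nucleotide along branches, with stop codons rejected
#' and resampled. Discordance is a single nearest-neighbour interchange
#' (NNI) at one designated internode, which gives exact control over which
#' branch conflicts. Rogue injection rescales the chosen taxon's terminal
#' branch to `rogue_branch_factor` times the median terminal branch length
#' of the gene tree — recorded in the emitted tree, so the long-branch
#' filter is testable on trees alone.
#'
#' @name synthdata
NULL

#' Synthetic-study configuration
#'
#' Defaults mirror the shape of the study the generator emulates: 96 taxa,
#' 1233 genes, mean per-gene taxon occupancy around 90%
#' (`missing_taxon_rate = 0.1`), roughly 3% of genes carrying one spurious
#' long-branch sequence, rogue branches 40 times the median terminal
#' length, and trimmed alignments of 167–4854 codons (501–14,562 bp).
#'
#' @param n_taxa number of taxa (>= 4).
#' @param n_genes number of gene families.
#' @param discordant_fraction fraction of genes whose tree is rearranged
#'   by one NNI at the designated internode, in `[0, 1]`.
#' @param missing_taxon_rate per-taxon, per-gene drop probability, in
#'   `[0, 1]`; trees never fall below 4 leaves.
#' @param rogue_rate fraction of genes receiving one injected long-branch
#'   rogue sequence, in `[0, 1]`.
#' @param rogue_branch_factor rogue terminal branch length as a multiple
#'   of the gene tree's median terminal branch length.
#' @param codon_length_range integer pair, range of alignment lengths in
#'   codons (uniform draw).
#' @param cug_ser_taxa character vector of taxa translated with the
#'   CUG-Ser code (their alignments are guaranteed to contain a CTG codon).
#' @param seed integer seed; identical config + seed reproduces
#'   byte-identical outputs.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_taxa = 96, n_genes = 1233,
                         discordant_fraction = 0.15,
                         missing_taxon_rate = 0.1,
                         rogue_rate = 0.034,
                         rogue_branch_factor = 40,
                         codon_length_range = c(167, 4854),
                         cug_ser_taxa = character(),
                         seed = 1L) {
  props <- c(discordant_fraction, missing_taxon_rate, rogue_rate)
  if (any(props < 0 | props > 1))
    err("proportions must lie in [0, 1]", "phylomic_invalid_argument")
  if (!is_count(n_taxa) || n_taxa < 4)
    err("n_taxa must be a count >= 4", "phylomic_invalid_argument")
  if (!is_count(n_genes) || n_genes < 1)
    err("n_genes must be a positive count", "phylomic_invalid_argument")
  if (length(codon_length_range) != 2L || codon_length_range[1L] < 1 ||
      diff(codon_length_range) < 0)
    err("codon_length_range must be an increasing pair with min >= 1",
        "phylomic_invalid_argument")
  if (rogue_branch_factor <= 0)
    err("rogue_branch_factor must be positive", "phylomic_invalid_argument")
  structure(list(n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes),
                 discordant_fraction = discordant_fraction,
                 missing_taxon_rate = missing_taxon_rate,
                 rogue_rate = rogue_rate,
                 rogue_branch_factor = rogue_branch_factor,
                 codon_length_range = as.integer(codon_length_range),
                 cug_ser_taxa = as.character(cug_ser_taxa),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a random species tree
#'
#' Unrooted, fully resolved (binary) tree with uniquely named leaves and
#' strictly positive branch lengths (uniform on 0.05–1 substitutions per
#' site). An `n`-leaf unrooted binary tree has `n - 3` internal branches.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param seed integer seed.
#' @return An [ape::phylo] tree.
#' @export
gen_species_tree <- function(n_taxa, seed = 1L) {
  if (!is_count(n_taxa) || n_taxa < 4)
    err("n_taxa must be a count >= 4", "phylomic_invalid_argument")
  with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE)
    tr$tip.label <- seq_names("t", n_taxa)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    tr
  })
}

# --- NNI -------------------------------------------------------------------

# leaf set below every node (indexed by node id)
node_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  tipsets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  tipsets
}

# one NNI across the internal edge whose child-side clade is `block` (or its
# complement); swaps the first child of that clade with its first sibling
nni_at_split <- function(tree, block) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  tipsets <- node_tipsets(tree)
  target <- NA_integer_
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    if (nd == root) next
    ts <- tipsets[[nd]]
    if (setequal(ts, block) || setequal(ts, setdiff(tree$tip.label, block))) {
      target <- nd
      break
    }
  }
  if (is.na(target))
    err("designated split not present in tree", "phylomic_invalid_argument")
  edge <- tree$edge
  row_pc <- which(edge[, 2L] == target)
  p <- edge[row_pc, 1L]
  child_rows <- which(edge[, 1L] == target)
  sib_rows <- setdiff(which(edge[, 1L] == p), row_pc)
  row_y <- child_rows[1L]
  row_s <- sib_rows[1L]
  edge[row_y, 1L] <- p
  edge[row_s, 1L] <- target
  tree$edge <- edge
  # renormalise ape's internal bookkeeping via a newick round trip
  ape::read.tree(text = ape::write.tree(tree))
}

# NNI at a uniformly chosen internal edge (uses the current RNG stream)
nni_random <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  cand <- tree$edge[, 2L][tree$edge[, 2L] > ntip & tree$edge[, 2L] != root]
  if (length(cand) == 0L) return(tree)
  nd <- cand[sample.int(length(cand), 1L)]
  tipsets <- node_tipsets(tree)
  nni_at_split(tree, tipsets[[nd]])
}

#' Generate discordant, possibly partial gene trees
#'
#' A `discordant_fraction` share of genes (Bernoulli per gene) have one
#' internode rearranged by NNI at a single designated edge — chosen as the
#' most balanced internal edge of the species tree, so the conflicting
#' bipartition is identical across discordant genes. Each gene then
#' independently drops each taxon with probability `missing_taxon_rate`;
#' draws leaving fewer than 4 leaves are redone. Per-gene branch lengths
#' get mild lognormal rate jitter.
#'
#' @param species_tree binary unrooted [ape::phylo].
#' @param cfg a [synth_config].
#' @return List with `trees` (named list of [ape::phylo]) and `truth`:
#'   `species_tree`, `focal_split` (the designated [bipartition]),
#'   `discordant` (named logical), `dropped` (named list of dropped taxa).
#' @export
gen_gene_trees <- function(species_tree, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  sp_splits <- bipartitions(species_tree)
  if (length(sp_splits) == 0L)
    err("species tree must have internal branches", "phylomic_invalid_argument")
  balance <- vapply(sp_splits, function(s)
    min(length(s$block), length(s$taxa) - length(s$block)), integer(1))
  focal <- sp_splits[[which.max(balance)]]
  genes <- seq_names("g", cfg$n_genes)
  with_seed(cfg$seed, {
    discordant <- stats::runif(cfg$n_genes) < cfg$discordant_fraction
    names(discordant) <- genes
    alt_tree <- if (any(discordant)) nni_at_split(species_tree, focal$block)
    trees <- vector("list", cfg$n_genes)
    dropped <- vector("list", cfg$n_genes)
    ntip <- length(species_tree$tip.label)
    for (i in seq_len(cfg$n_genes)) {
      tr <- if (discordant[i]) alt_tree else species_tree
      tr$edge.length <- tr$edge.length * exp(stats::rnorm(nrow(tr$edge), 0, 0.25))
      drop <- character(0)
      if (cfg$missing_taxon_rate > 0) {
        repeat {
          mask <- stats::runif(ntip) < cfg$missing_taxon_rate
          if (ntip - sum(mask) >= 4L) break
        }
        drop <- species_tree$tip.label[mask]
        if (length(drop)) tr <- ape::drop.tip(tr, drop)
      }
      trees[[i]] <- tr
      dropped[[i]] <- drop
    }
    names(trees) <- genes
    names(dropped) <- genes
    list(trees = trees,
         truth = list(species_tree = species_tree, focal_split = focal,
                      discordant = discordant, dropped = dropped))
  })
}

# --- sequence simulation ---------------------------------------------------

NUCS <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- {
  all3 <- as.vector(outer(as.vector(outer(NUCS, NUCS, paste0)), NUCS, paste0))
  setdiff(all3, STOPS)
}

is_stop_vec <- function(c1, c2, c3) {
  c1 == "T" & ((c2 == "A" & (c3 == "A" | c3 == "G")) | (c2 == "G" & c3 == "A"))
}

# replace stop codons (positions in `idx`) by random sense codons
fix_stops <- function(nts, idx) {
  if (length(idx) == 0L) return(nts)
  rep_cod <- sample(SENSE_CODONS, length(idx), replace = TRUE)
  pos <- 3L * (idx - 1L)
  nts[pos + 1L] <- substr(rep_cod, 1L, 1L)
  nts[pos + 2L] <- substr(rep_cod, 2L, 2L)
  nts[pos + 3L] <- substr(rep_cod, 3L, 3L)
  nts
}

stop_positions <- function(nts) {
  n <- length(nts)
  which(is_stop_vec(nts[seq(1L, n, 3L)], nts[seq(2L, n, 3L)], nts[seq(3L, n, 3L)]))
}

# Jukes-Cantor evolution of a nucleotide vector over branch length t
jc_mutate <- function(nts, t) {
  p <- 0.75 * (1 - exp(-4 * t / 3))
  hit <- which(stats::runif(length(nts)) < p)
  if (length(hit)) {
    cur <- nts[hit]
    shift <- sample.int(3L, length(hit), replace = TRUE)
    idx <- (match(cur, NUCS) - 1L + shift) %% 4L + 1L
    nts[hit] <- NUCS[idx]
  }
  nts
}

simulate_gene_sequences <- function(tree, n_codons) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge))) # preorder edge traversal
  nsites <- 3L * n_codons
  seqs_at <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  root_cod <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  seqs_at[[root]] <- as.vector(rbind(substr(root_cod, 1, 1),
                                     substr(root_cod, 2, 2),
                                     substr(root_cod, 3, 3)))
  for (k in pre) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    s <- jc_mutate(seqs_at[[p]], po$edge.length[k])
    repeat {
      bad <- stop_positions(s)
      if (length(bad) == 0L) break
      s <- fix_stops(s, bad)
    }
    seqs_at[[ch]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs_at[[i]], collapse = ""),
                character(1))
  stats::setNames(out, tree$tip.label)
}

#' Generate codon alignments (with rogue injection) for gene trees
#'
#' One gapless in-frame alignment per gene tree, with length in codons
#' drawn uniformly from `cfg$codon_length_range` (or given explicitly).
#' A `rogue_rate` share of genes get one rogue: a uniformly chosen taxon
#' whose terminal branch is rescaled to
#' `rogue_branch_factor x median(terminal branch lengths)` *before*
#' simulation, and the rescaled length is recorded in the returned tree.
#' Taxa in `cfg$cug_ser_taxa` are flagged with the CUG-Ser code and
#' guaranteed to contain at least one CTG codon. No sequence contains an
#' in-frame stop codon.
#'
#' @param gene_trees named list of [ape::phylo] gene trees.
#' @param cfg a [synth_config].
#' @param codon_lengths optional integer vector (one per gene) overriding
#'   the uniform length draw — useful for building matrices of an exact
#'   total size.
#' @return List with `alignments` (named list of [codon_alignment]),
#'   `trees` (gene trees with any rogue branch rescaling applied), and
#'   `truth` (`rogues`: named list of rogue taxa per gene, empty when
#'   none; `codes`: per-taxon code map).
#' @export
gen_codon_alignments <- function(gene_trees, cfg, codon_lengths = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(gene_trees) == 0L)
    err("gene_trees must be nonempty", "phylomic_invalid_argument")
  genes <- names(gene_trees)
  if (is.null(genes)) genes <- seq_names("g", length(gene_trees))
  if (!is.null(codon_lengths) && length(codon_lengths) != length(gene_trees))
    err("codon_lengths must have one entry per gene", "phylomic_invalid_argument")
  with_seed(cfg$seed + 1L, {
    lens <- if (is.null(codon_lengths))
      sample(seq(cfg$codon_length_range[1L], cfg$codon_length_range[2L]),
             length(gene_trees), replace = TRUE)
    else as.integer(codon_lengths)
    is_rogue_gene <- stats::runif(length(gene_trees)) < cfg$rogue_rate
    alns <- vector("list", length(gene_trees))
    out_trees <- vector("list", length(gene_trees))
    rogues <- stats::setNames(vector("list", length(gene_trees)), genes)
    for (i in seq_along(gene_trees)) {
      tr <- gene_trees[[i]]
      ntip <- length(tr$tip.label)
      rogues[[i]] <- character(0)
      if (is_rogue_gene[i]) {
        tip_edge <- which(tr$edge[, 2L] <= ntip)
        pick <- tip_edge[sample.int(length(tip_edge), 1L)]
        # the factor is relative to the median of the *emitted* tree's
        # terminal branches (what the long-branch filter sees), so the
        # median is taken with the rogue branch already at the top
        med <- stats::median(c(tr$edge.length[setdiff(tip_edge, pick)], Inf))
        tr$edge.length[pick] <- cfg$rogue_branch_factor * med
        rogues[[i]] <- tr$tip.label[tr$edge[pick, 2L]]
      }
      seqs <- simulate_gene_sequences(tr, lens[i])
      cug_here <- intersect(cfg$cug_ser_taxa, names(seqs))
      for (tx in cug_here) {
        if (!grepl("CTG", seqs[[tx]])) {
          # overwrite the final codon; keeps the row gapless and in-frame
          substr(seqs[[tx]], 3L * lens[i] - 2L, 3L * lens[i]) <- "CTG"
        }
      }
      codes <- stats::setNames(rep("cug_ser", length(cug_here)), cug_here)
      alns[[i]] <- codon_alignment(genes[i], seqs,
                                   if (length(codes)) codes else NULL)
      out_trees[[i]] <- tr
    }
    names(alns) <- genes
    names(out_trees) <- genes
    list(alignments = alns, trees = out_trees,
         truth = list(rogues = rogues,
                      codes = stats::setNames(
                        ifelse(seq_names("t", cfg$n_taxa) %in% cfg$cug_ser_taxa,
                               "cug_ser", "standard"),
                        seq_names("t", cfg$n_taxa))))
  })
}

#' Generate labelled BUSCO-style hit tables
#'
#' For every genome x gene pair a true status is drawn
#' (`complete`/`duplicated`/`fragmented`/`missing`) and candidate hits are
#' constructed so that the classification rules recover exactly that
#' label: complete = one hit above the bit-score cutoff at full length;
#' duplicated = two such; fragmented = above-cutoff hits all shorter than
#' 95% of the reference length; missing = no hit above the cutoff.
#'
#' @param cfg a [synth_config] (`n_taxa` genomes, `n_genes` genes, `seed`).
#' @param ref_stats optional data frame (`busco_gene`, `bitscore_cutoff`,
#'   `ref_aligned_length`); generated when `NULL`.
#' @param status_probs named numeric vector of category probabilities
#'   (defaults approximate a high-quality assembly set: 94% complete).
#' @return List with `hits` (data frame: `genome`, `busco_gene`,
#'   `candidate_id`, `bit_score`, `aligned_length`), `ref_stats`, and
#'   `truth` (data frame: `genome`, `busco_gene`, `status`).
#' @export
gen_busco_hits <- function(cfg, ref_stats = NULL,
                           status_probs = c(complete = 0.94, duplicated = 0.02,
                                            fragmented = 0.02, missing = 0.02)) {
  stopifnot(inherits(cfg, "synth_config"))
  status_probs <- status_probs[status_levels]
  if (anyNA(status_probs) || abs(sum(status_probs) - 1) > 1e-8)
    err("status_probs must cover the four categories and sum to 1",
        "phylomic_invalid_argument")
  genomes <- seq_names("t", cfg$n_taxa)
  genes <- seq_names("g", cfg$n_genes)
  with_seed(cfg$seed + 2L, {
    if (is.null(ref_stats))
      ref_stats <- data.frame(busco_gene = genes,
                              bitscore_cutoff = round(stats::runif(cfg$n_genes, 50, 400), 1),
                              ref_aligned_length = as.integer(round(stats::runif(cfg$n_genes, 100, 800))),
                              stringsAsFactors = FALSE)
    if (!all(genes %in% ref_stats$busco_gene))
      err("ref_stats must cover every gene", "phylomic_invalid_argument")
    truth <- expand.grid(genome = genomes, busco_gene = genes,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$status <- sample(status_levels, nrow(truth), replace = TRUE,
                           prob = status_probs)
    cutoff <- stats::setNames(ref_stats$bitscore_cutoff, ref_stats$busco_gene)
    reflen <- stats::setNames(ref_stats$ref_aligned_length, ref_stats$busco_gene)
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      g <- truth$genome[i]; b <- truth$busco_gene[i]
      co <- cutoff[[b]]; rl <- reflen[[b]]
      full_len <- function(k) as.integer(ceiling(rl * stats::runif(k, 0.96, 1.05)))
      frag_len <- function(k) as.integer(floor(rl * stats::runif(k, 0.30, 0.90)))
      hi <- function(k) round(co * stats::runif(k, 1.1, 2.0), 1)
      lo <- function(k) round(co * stats::runif(k, 0.3, 0.9), 1)
      h <- switch(truth$status[i],
        complete = data.frame(bit_score = hi(1), aligned_length = full_len(1)),
        duplicated = {
          k <- 2L + stats::rbinom(1L, 1L, 0.3)
          data.frame(bit_score = hi(k), aligned_length = full_len(k))
        },
        fragmented = {
          k <- 1L + stats::rbinom(1L, 1L, 0.3)
          data.frame(bit_score = hi(k), aligned_length = frag_len(k))
        },
        missing = {
          k <- stats::rbinom(1L, 2L, 0.3)
          if (k == 0L) NULL
          else data.frame(bit_score = lo(k), aligned_length = full_len(k))
        })
      if (is.null(h)) next
      h$genome <- g; h$busco_gene <- b
      h$candidate_id <- sprintf("%s_%s_c%d", g, b, seq_len(nrow(h)))
      rows[[i]] <- h[, c("genome", "busco_gene", "candidate_id",
                         "bit_score", "aligned_length")]
    }
    hits <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                             list(make.row.names = FALSE)))
    list(hits = hits, ref_stats = ref_stats, truth = truth)
  })
}

#' Generate gene trees with coupled bootstrap tree sets
#'
#' Emulates heterogeneity in per-gene phylogenetic signal: each gene gets
#' a quality draw `q` in `quality_range`; its gene tree is the species
#' tree perturbed by `Poisson(3 (1 - q))` random NNIs, and each of its
#' bootstrap replicates perturbs the gene tree by a further
#' `Poisson(4 (1 - q))` NNIs. High-quality genes therefore have both
#' accurate ML trees and sharp (concordant) bootstrap sets — the coupling
#' that makes ranking genes by average bootstrap support enrich for
#' species-tree signal.
#'
#' @param species_tree binary unrooted [ape::phylo].
#' @param n_genes number of genes.
#' @param n_boot bootstrap replicates per gene.
#' @param seed integer seed.
#' @param quality_range range of the per-gene quality draw.
#' @return List with `gene_trees` (named list), `boot_sets` (named list of
#'   tree lists) and `quality` (named numeric).
#' @export
gen_signal_genes <- function(species_tree, n_genes, n_boot = 100, seed = 1L,
                             quality_range = c(0.2, 1)) {
  genes <- seq_names("g", n_genes)
  with_seed(seed, {
    quality <- stats::setNames(stats::runif(n_genes, quality_range[1L],
                                            quality_range[2L]), genes)
    gene_trees <- vector("list", n_genes)
    boot_sets <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      tr <- species_tree
      for (k in seq_len(stats::rpois(1L, 3 * (1 - quality[i]))))
        tr <- nni_random(tr)
      gene_trees[[i]] <- tr
      boot_sets[[i]] <- lapply(seq_len(n_boot), function(r) {
        bt <- tr
        for (k in seq_len(stats::rpois(1L, 4 * (1 - quality[i]))))
          bt <- nni_random(bt)
        bt
      })
    }
    names(gene_trees) <- genes
    names(boot_sets) <- genes
    list(gene_trees = gene_trees, boot_sets = boot_sets, quality = quality)
  })
}

#' Write a synthetic data set to disk
#'
#' Per-gene FASTA codon alignments (`genes/<gene>.fasta`), Newick gene
#' trees (`trees/<gene>.nwk`), the species tree, hit-table and
#' reference-stats TSVs, taxa and CUG-Ser taxa lists, and a JSON truth
#' file. Identical config + seed reproduces byte-identical files.
#'
#' @param outdir output directory (created if needed).
#' @param cfg a [synth_config].
#' @return Invisibly, a list of the paths written plus the in-memory
#'   objects (`species_tree`, `gene_trees`, `alignments`, `busco`,
#'   `truth`).
#' @export
write_synth_data <- function(outdir, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(file.path(outdir, "genes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "trees"), showWarnings = FALSE)
  sp <- gen_species_tree(cfg$n_taxa, cfg$seed)
  gt <- gen_gene_trees(sp, cfg)
  ca <- gen_codon_alignments(gt$trees, cfg)
  bh <- gen_busco_hits(cfg)
  ape::write.tree(sp, file.path(outdir, "species_tree.nwk"))
  for (g in names(ca$alignments)) {
    write_fasta(ca$alignments[[g]]$seqs, file.path(outdir, "genes", paste0(g, ".fasta")))
    ape::write.tree(ca$trees[[g]], file.path(outdir, "trees", paste0(g, ".nwk")))
  }
  write_tsv_table(bh$hits, file.path(outdir, "busco_hits.tsv"))
  write_tsv_table(bh$ref_stats, file.path(outdir, "busco_ref_stats.tsv"))
  writeLines(sp$tip.label, file.path(outdir, "taxa.txt"))
  writeLines(cfg$cug_ser_taxa, file.path(outdir, "cug_ser_taxa.txt"))
  truth <- list(discordant = as.list(gt$truth$discordant),
                focal_split = gt$truth$focal_split$block,
                dropped = gt$truth$dropped,
                rogues = ca$truth$rogues,
                busco_status = bh$truth)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = outdir, species_tree = sp, gene_trees = ca$trees,
                 alignments = ca$alignments, busco = bh,
                 truth = truth))
}
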