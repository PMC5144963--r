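test_that("long-branch detection flags leaves at >= factor x median", {
  tr <- tree_with_terminals(c(rep(1, 8), 25))
  got <- detect_long_branches(tr, 20)
  expect_identical(as.character(got), "x9")
  expect_equal(attr(got, "median"), 1)
  # all-equal terminals: nothing flagged
  expect_length(detect_long_branches(tree_with_terminals(rep(0.3, 8)), 20), 0L)
  # inclusive boundary: exactly 20 x median is flagged
  tr2 <- tree_with_terminals(c(rep(1, 8), 20))
  expect_identical(as.character(detect_long_branches(tr2, 20)), "x9")
  tr3 <- ape::rtree(5, rooted = FALSE)
  tr3$edge.length <- NULL
  expect_error(detect_long_branches(tr3), "branch lengths")
})

test_that("long-branch detection is scale-invariant", {
  set.seed(17)
  for (rep in 1:10) {
    tr <- ape::rtree(sample(6:20, 1), rooted = FALSE)
    tr$edge.length <- rexp(nrow(tr$edge), 5) + 1e-3
    base <- sort(as.character(detect_long_branches(tr, 8)))
    for (c in c(0.01, 3, 1000)) {
      sc <- tr
      sc$edge.length <- sc$edge.length * c
      expect_identical(sort(as.character(detect_long_branches(sc, 8))), base)
    }
  }
})

test_that("sequence removal drops rows and newly all-gap codon columns", {
  aln <- small_codon_aln()
  expect_identical(apply_sequence_removal(aln, character(0))$seqs, aln$seqs)
  one <- apply_sequence_removal(codon_alignment("g", c(a = "ATGAAA", b = "ATGAAA")),
                                "b")
  expect_identical(names(one$seqs), "a")
  expect_identical(nchar(one$seqs[["a"]]), 6L)
  # the removed row alone had codons in 5 columns: length shrinks by 15 nt
  n_col <- 8L
  solo <- paste0(strrep("ATG", 5), strrep("---", n_col - 5))
  aln2 <- codon_alignment("g", c(
    keep1 = paste0(strrep("---", 5), strrep("AAA", n_col - 5)),
    keep2 = paste0(strrep("---", 5), strrep("AAA", n_col - 5)),
    solo = solo))
  out <- apply_sequence_removal(aln2, "solo")
  expect_identical(nchar(out$seqs[["keep1"]]), 3L * n_col - 15L)
  expect_error(apply_sequence_removal(aln, names(aln$seqs)),
               class = "phylomic_empty_alignment")
  expect_error(apply_sequence_removal(aln, "nope"), "not in alignment")
})

test_that("gene filtering applies length, occupancy and exclusion rules", {
  mk <- function(gene, n_taxa, n_cod) {
    codon_alignment(gene, stats::setNames(rep(strrep("ATG", n_cod), n_taxa),
                                          paste0("t", seq_len(n_taxa))))
  }
  alns <- list(mk("gA", 96, 167), # 501 bp, full occupancy: retained
               mk("gB", 96, 166), # 498 bp: dropped on length
               mk("gC", 47, 200), # 47 of 96 taxa: dropped on occupancy
               mk("gD", 48, 200), # exactly at threshold: retained
               mk("gE", 96, 200)) # excluded by name
  res <- filter_gene_set(alns, min_len_bp = 500, min_taxa_frac = 0.5,
                         total_taxa = 96, excluded_genes = "gE")
  expect_identical(res$report$taxon_threshold, rep(48, 5))
  expect_identical(res$report$retained, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(vapply(res$retained, `[[`, character(1), "gene"),
                   c("gA", "gD"))
})

test_that("filter outcome is independent of gene order", {
  set.seed(19)
  alns <- lapply(1:12, function(i) {
    n_taxa <- sample(3:10, 1) + 1
    n_cod <- sample(100:250, 1)
    codon_alignment(paste0("g", i),
                    stats::setNames(rep(strrep("GAT", n_cod), n_taxa),
                                    paste0("t", seq_len(n_taxa))))
  })
  ref <- filter_gene_set(alns, 500, 0.5, 12)
  kept_ref <- sort(vapply(ref$retained, `[[`, character(1), "gene"))
  for (rep in 1:5) {
    perm <- sample(alns)
    got <- filter_gene_set(perm, 500, 0.5, 12)
    expect_identical(sort(vapply(got$retained, `[[`, character(1), "gene")),
                     kept_ref)
  }
})

test_that("screening clean gene sets removes nothing", {
  sp <- gen_species_tree(10, 71)
  cfg <- synth_config(n_taxa = 10, n_genes = 12, discordant_fraction = 0,
                      missing_taxon_rate = 0, rogue_rate = 0, seed = 71,
                      codon_length_range = c(170, 180))
  gt <- gen_gene_trees(sp, cfg)
  ca <- gen_codon_alignments(gt$trees, cfg)
  sc <- screen_long_branches(ca$alignments, ca$trees)
  expect_identical(nrow(sc$removals), 0L)
  expect_identical(sc$alignments, ca$alignments)
  res <- filter_gene_set(sc$alignments, 500, 0.5, 10)
  expect_length(res$retained, 12L)
})

test_that("injected rogues are recovered exactly from the emitted trees", {
  cfg <- synth_config(n_taxa = 16, n_genes = 60, discordant_fraction = 0,
                      missing_taxon_rate = 0.1, rogue_rate = 0.25,
                      rogue_branch_factor = 40, seed = 23,
                      codon_length_range = c(20, 40))
  sp <- gen_species_tree(16, 23)
  gt <- gen_gene_trees(sp, cfg)
  ca <- gen_codon_alignments(gt$trees, cfg)
  for (g in names(ca$trees)) {
    det <- sort(as.character(detect_long_branches(ca$trees[[g]], 20)))
    expect_identical(det, sort(ca$truth$rogues[[g]]))
  }
  expect_gt(sum(lengths(ca$truth$rogues)), 0L)
})
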