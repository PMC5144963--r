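test_that("species trees are binary, unrooted, positive-length and deterministic", {
  tr <- gen_species_tree(10, 1)
  expect_identical(length(tr$tip.label), 10L)
  expect_identical(tr$Nnode, 8L) # n - 2 internal nodes when unrooted
  expect_true(all(tr$edge.length > 0))
  expect_length(bipartitions(tr), 7L)
  expect_length(bipartitions(gen_species_tree(4, 2)), 1L)
  expect_identical(ape::write.tree(gen_species_tree(10, 1)),
                   ape::write.tree(gen_species_tree(10, 1)))
  expect_false(identical(ape::write.tree(gen_species_tree(10, 1)),
                         ape::write.tree(gen_species_tree(10, 2))))
  expect_error(gen_species_tree(3), class = "phylomic_invalid_argument")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_config(discordant_fraction = 1.2), "proportions")
  expect_error(synth_config(n_taxa = 3), "n_taxa")
  expect_error(synth_config(codon_length_range = c(0, 10)), "codon_length_range")
  expect_error(synth_config(rogue_branch_factor = 0), "positive")
})

test_that("zero discordance reproduces the species tree on every gene's taxa", {
  sp <- gen_species_tree(12, 43)
  cfg <- synth_config(n_taxa = 12, n_genes = 30, discordant_fraction = 0,
                      missing_taxon_rate = 0.2, rogue_rate = 0, seed = 43,
                      codon_length_range = c(10, 20))
  gt <- gen_gene_trees(sp, cfg)
  expect_false(any(gt$truth$discordant))
  for (tr in gt$trees) {
    expect_gte(length(tr$tip.label), 4L)
    pruned <- if (length(tr$tip.label) < 12)
      ape::drop.tip(sp, setdiff(sp$tip.label, tr$tip.label)) else sp
    expect_identical(count_conflicts(tr, pruned)$count, 0L)
  }
})

test_that("discordant genes conflict with the species tree only at the focal edge", {
  sp <- gen_species_tree(10, 47)
  cfg <- synth_config(n_taxa = 10, n_genes = 40, discordant_fraction = 0.5,
                      missing_taxon_rate = 0, rogue_rate = 0, seed = 47,
                      codon_length_range = c(10, 20))
  gt <- gen_gene_trees(sp, cfg)
  for (g in names(gt$trees)) {
    cc <- count_conflicts(gt$trees[[g]], sp)
    if (gt$truth$discordant[[g]]) {
      expect_identical(cc$count, 1L)
      expect_true(splits_conflict(cc$conflicting[[1]], gt$truth$focal_split))
    } else {
      expect_identical(cc$count, 0L)
    }
  }
})

test_that("empirical discordance rate stays within binomial bounds", {
  sp <- gen_species_tree(8, 53)
  n <- 1000
  p <- 0.3
  cfg <- synth_config(n_taxa = 8, n_genes = n, discordant_fraction = p,
                      missing_taxon_rate = 0, rogue_rate = 0, seed = 53,
                      codon_length_range = c(10, 20))
  gt <- gen_gene_trees(sp, cfg)
  k <- sum(gt$truth$discordant)
  ci <- qbinom(c(0.005, 0.995), n, p) # 99% binomial interval around 300
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("taxon dropping hits its expected rate with a floor of four leaves", {
  sp <- gen_species_tree(24, 59)
  cfg <- synth_config(n_taxa = 24, n_genes = 200, discordant_fraction = 0,
                      missing_taxon_rate = 0.5, rogue_rate = 0, seed = 59,
                      codon_length_range = c(10, 20))
  gt <- gen_gene_trees(sp, cfg)
  leaves <- vapply(gt$trees, function(t) length(t$tip.label), integer(1))
  expect_true(all(leaves >= 4L))
  expect_equal(mean(leaves) / 24, 0.5, tolerance = 0.05)
})

test_that("codon alignments are gapless, in-frame, stop-free and CTG-marked", {
  cug <- c("t01", "t03")
  cfg <- synth_config(n_taxa = 8, n_genes = 12, discordant_fraction = 0.2,
                      missing_taxon_rate = 0.2, rogue_rate = 0, seed = 61,
                      codon_length_range = c(15, 40), cug_ser_taxa = cug)
  sp <- gen_species_tree(8, 61)
  gt <- gen_gene_trees(sp, cfg)
  ca <- gen_codon_alignments(gt$trees, cfg)
  expect_length(ca$alignments, 12L)
  expect_true(all(lengths(ca$truth$rogues) == 0L))
  for (aln in ca$alignments) {
    len <- nchar(aln$seqs[[1]])
    expect_identical(len %% 3L, 0L)
    expect_gte(len, 3L * 15L)
    expect_lte(len, 3L * 40L)
    expect_false(any(grepl("-", aln$seqs, fixed = TRUE)))
    for (tx in names(aln$seqs)) {
      expect_false(has_inframe_stop(aln$seqs[[tx]], aln$codes[[tx]]))
      if (tx %in% cug) {
        expect_identical(aln$codes[[tx]], "cug_ser")
        expect_true(grepl("CTG", aln$seqs[[tx]], fixed = TRUE))
      } else {
        expect_identical(aln$codes[[tx]], "standard")
      }
    }
  }
  expect_error(gen_codon_alignments(list(), cfg), "nonempty")
})

test_that("rogue injection rescales the recorded terminal branch", {
  cfg <- synth_config(n_taxa = 10, n_genes = 50, discordant_fraction = 0,
                      missing_taxon_rate = 0, rogue_rate = 0.3,
                      rogue_branch_factor = 35, seed = 67,
                      codon_length_range = c(10, 20))
  sp <- gen_species_tree(10, 67)
  gt <- gen_gene_trees(sp, cfg)
  ca <- gen_codon_alignments(gt$trees, cfg)
  n_rogue <- sum(lengths(ca$truth$rogues))
  expect_gt(n_rogue, 0L)
  for (g in names(ca$trees)) {
    rg <- ca$truth$rogues[[g]]
    expect_true(all(rg %in% names(ca$alignments[[g]]$seqs)))
    if (length(rg)) {
      tr <- ca$trees[[g]]
      ntip <- length(tr$tip.label)
      tip_edge <- tr$edge[, 2L] <= ntip
      lens <- stats::setNames(tr$edge.length[tip_edge],
                              tr$tip.label[tr$edge[tip_edge, 2L]])
      expect_equal(lens[[rg]], 35 * median(lens))
      expect_identical(names(which.max(lens)), rg)
    }
  }
})

test_that("hit tables are reproducible and labelled consistently", {
  cfg <- synth_config(n_taxa = 5, n_genes = 20, seed = 71)
  a <- gen_busco_hits(cfg)
  b <- gen_busco_hits(cfg)
  expect_identical(a, b)
  expect_identical(nrow(a$truth), 100L)
  expect_true(all(a$hits$bit_score >= 0))
  expect_true(all(a$hits$aligned_length >= 0))
})

test_that("written synthetic data sets are byte-identical under a fixed seed", {
  cfg <- synth_config(n_taxa = 6, n_genes = 4, discordant_fraction = 0.3,
                      missing_taxon_rate = 0.1, rogue_rate = 0.2, seed = 73,
                      codon_length_range = c(10, 15), cug_ser_taxa = "t01")
  d1 <- tempfile("synth1_"); d2 <- tempfile("synth2_")
  write_synth_data(d1, cfg)
  write_synth_data(d2, cfg)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("signal-generator quality couples tree accuracy and bootstrap sharpness", {
  sp <- gen_species_tree(12, 79)
  sg <- gen_signal_genes(sp, n_genes = 30, n_boot = 12, seed = 79,
                         quality_range = c(0.1, 1))
  expect_length(sg$gene_trees, 30L)
  expect_true(all(vapply(sg$boot_sets, length, integer(1)) == 12L))
  rf <- vapply(names(sg$gene_trees), function(g)
    count_conflicts(sg$gene_trees[[g]], sp)$count, integer(1))
  # high-quality genes have more accurate trees (negative rank correlation)
  expect_lt(cor(sg$quality, rf, method = "spearman"), 0)
})
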