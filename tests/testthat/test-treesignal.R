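test_that("internode certainty reproduces the two-way entropy closed form", {
  ic <- function(f0, f1) internode_certainty(
    list(support = f0, conflict_counts = f1, n_informative = f0 + f1))
  h2 <- function(q) -q * log2(q) - (1 - q) * log2(1 - q) # binary entropy oracle
  expect_equal(ic(30, 10), 1 - h2(0.75), tolerance = 1e-12)
  for (q in c(0.5, 0.75, 0.9)) {
    n <- 1000
    expect_equal(abs(ic(q * n, (1 - q) * n)), 1 - h2(q), tolerance = 1e-12)
  }
  expect_identical(ic(25, 25), 0)
  expect_identical(internode_certainty(
    list(support = 40, conflict_counts = integer(0), n_informative = 40)), 1)
  # sign convention: negative when the reference loses the plurality
  expect_equal(ic(10, 30), -(1 - h2(0.75)), tolerance = 1e-12)
  expect_true(is.na(internode_certainty(
    list(support = 0, conflict_counts = integer(0), n_informative = 0))))
})

test_that("ICA uses base-(k+1) logs and drops rare conflicts", {
  f <- list(support = 50, conflict_counts = c(25, 25), n_informative = 100)
  p <- c(50, 25, 25) / 100
  expect_equal(internode_certainty(f, "ICA"),
               1 + sum(p * log(p, base = 3)), tolerance = 1e-12)
  # a conflict below 5% of informative trees is ignored
  f2 <- list(support = 96, conflict_counts = 4, n_informative = 100)
  expect_identical(internode_certainty(f2, "ICA"), 1)
  expect_equal(internode_certainty(f2, "ICA", ica_threshold = 0),
               internode_certainty(f2, "IC"), tolerance = 1e-12)
})

test_that("split frequencies separate support from conflict under NNI discordance", {
  sp <- gen_species_tree(12, 21)
  cfg <- synth_config(n_taxa = 12, n_genes = 300, discordant_fraction = 0.3,
                      missing_taxon_rate = 0, rogue_rate = 0, seed = 21,
                      codon_length_range = c(10, 20))
  gt <- gen_gene_trees(sp, cfg)
  fr <- split_frequencies(gt$truth$focal_split, gt$trees)
  n_disc <- sum(gt$truth$discordant)
  expect_identical(fr$n_informative, 300L)
  expect_identical(fr$support, 300L - n_disc)
  expect_length(fr$conflicts, 1L) # a single NNI class
  expect_identical(fr$conflict_counts, n_disc)
  # concordant edges see no conflict at all
  other <- Filter(function(s) s$key != gt$truth$focal_split$key,
                  bipartitions(sp))
  fr2 <- split_frequencies(other[[1]], gt$trees)
  expect_identical(fr2$support, 300L)
  expect_length(fr2$conflicts, 0L)
})

test_that("gene trees unable to express the reference are uninformative", {
  u <- paste0("t", 1:6)
  ref <- bipartition(c("t1", "t2"), u)
  trees <- lapply(1:5, function(i) {
    tr <- ape::rtree(5, rooted = FALSE)
    tr$tip.label <- setdiff(u, "t2") # t2 missing: block shrinks below 2
    tr
  })
  fr <- split_frequencies(ref, trees)
  expect_identical(fr$n_informative, 0L)
  expect_true(is.na(internode_certainty(fr)))
})

test_that("frequencies are invariant to deleting taxa outside the bipartition's universe", {
  set.seed(5)
  sp <- gen_species_tree(10, 5)
  u <- sort(sp$tip.label)[1:7]
  ref <- Find(Negate(is.null),
              lapply(bipartitions(sp), restrict_split, taxa = u))
  expect_false(is.null(ref)) # some species-tree split stays informative on u
  cfg <- synth_config(n_taxa = 10, n_genes = 80, discordant_fraction = 0.4,
                      missing_taxon_rate = 0.15, rogue_rate = 0, seed = 6,
                      codon_length_range = c(10, 20))
  gt <- gen_gene_trees(sp, cfg)
  pruned <- lapply(gt$trees, function(tr) {
    drop <- setdiff(tr$tip.label, u)
    if (length(tr$tip.label) - length(drop) < 4) tr else ape::drop.tip(tr, drop)
  })
  keep <- vapply(pruned, function(tr) all(tr$tip.label %in% u), logical(1))
  fa <- split_frequencies(ref, gt$trees[keep])
  fb <- split_frequencies(ref, pruned[keep])
  expect_identical(fa$support, fb$support)
  expect_identical(fa$n_informative, fb$n_informative)
  expect_identical(fa$conflict_counts, fb$conflict_counts)
})

test_that("annotate_ic labels every internode and averages correctly", {
  sp <- gen_species_tree(10, 31)
  ann <- annotate_ic(sp, rep(list(sp), 100))
  expect_identical(nrow(ann$table), 7L)
  expect_true(all(ann$table$ic == 1))
  expect_equal(ann$mean_ic, 1)

  cfg <- synth_config(n_taxa = 10, n_genes = 400, discordant_fraction = 0.5,
                      missing_taxon_rate = 0, rogue_rate = 0, seed = 31,
                      codon_length_range = c(10, 20))
  gt <- gen_gene_trees(sp, cfg)
  ann2 <- annotate_ic(sp, gt$trees)
  focal_fmt <- format(gt$truth$focal_split)
  at_focal <- ann2$table$ic[ann2$table$split == focal_fmt]
  # rate-0.5 discordance at one edge: IC ~ 1 - H2(0.5) = 0 there, 1 elsewhere
  expect_lt(abs(at_focal), 0.05)
  expect_true(all(ann2$table$ic[ann2$table$split != focal_fmt] == 1))
  expect_true(all(ann2$table$ic >= -1 & ann2$table$ic <= 1))
})

test_that("ABS and RTC summarise bootstrap agreement with the ML tree", {
  sp <- gen_species_tree(8, 41)
  same <- rep(list(sp), 50)
  expect_equal(abs_score(same, sp)$abs, 100)
  expect_equal(rtc_score(same, sp)$rtc, 1)

  # replicates sharing no internal edge with the ML tree
  ml <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  alt <- ape::read.tree(text = "((A,C),(B,E),(D,F));")
  expect_equal(abs_score(rep(list(alt), 10), ml)$abs, 0)

  # per-edge counting oracle: one edge present in 40 of 100 replicates
  tr1 <- ape::read.tree(text = "((A,B),(C,D));")
  tr2 <- ape::read.tree(text = "((A,C),(B,D));")
  boots <- c(rep(list(tr1), 40), rep(list(tr2), 60))
  s <- abs_score(boots, tr1)
  expect_equal(unname(s$per_edge), 40)
  r <- rtc_score(boots, tr1)
  h2 <- function(q) -q * log2(q) - (1 - q) * log2(1 - q)
  expect_equal(unname(r$per_edge), -(1 - h2(0.6)), tolerance = 1e-12)
})

test_that("gene ranking takes floor(frac * n) with deterministic tie-breaks", {
  expect_identical(rank_genes(c(a = 1, b = 1, c = 0, d = 0), 0.5), c("a", "b"))
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(1:200, 1)
    frac <- runif(1, 0.05, 1)
    sc <- stats::setNames(runif(n), paste0("g", seq_len(n)))
    expect_length(rank_genes(sc, frac), floor(frac * n))
  }
  sc <- stats::setNames(rep(1, 4), c("d", "b", "a", "c"))
  expect_identical(rank_genes(sc, 1), c("a", "b", "c", "d"))
  expect_error(rank_genes(numeric(0), 0.5), "nonempty")
})

test_that("subset overlap is Jaccard with shared count", {
  expect_equal(subset_overlap(letters[1:4], letters[1:4]),
               list(jaccard = 1, shared = 4L))
  expect_equal(subset_overlap(letters[1:4], letters[5:8])$jaccard, 0)
  expect_equal(subset_overlap(c("a", "b", "c", "d"), c("c", "d", "e", "f")),
               list(jaccard = 1 / 3, shared = 2L))
  expect_true(is.na(subset_overlap(character(0), character(0))$jaccard))
})

test_that("multilocus bootstrap draws one tree per gene per replicate, reproducibly", {
  sp <- gen_species_tree(6, 51)
  boot_sets <- list(g1 = rep(list(sp), 5), g2 = rep(list(sp), 3),
                    g3 = list(sp))
  mb <- multilocus_bootstrap(boot_sets, n_reps = 20, seed = 4)
  expect_length(mb$replicates, 20L)
  expect_true(all(vapply(mb$replicates, length, integer(1)) == 3L))
  expect_identical(colnames(mb$draws), c("g1", "g2", "g3"))
  expect_true(all(mb$draws[, "g3"] == 1L)) # single tree: always the same draw
  mb2 <- multilocus_bootstrap(boot_sets, n_reps = 20, seed = 4)
  expect_identical(mb$draws, mb2$draws)
  expect_error(multilocus_bootstrap(list(g1 = list()), 5, 1), "empty bootstrap")
})

test_that("support mapping reports integer percentages per internode", {
  sp <- gen_species_tree(7, 61)
  ms <- map_support(sp, rep(list(sp), 10))
  expect_true(all(ms$table$support == 100L))
  tr1 <- ape::read.tree(text = "((A,B),(C,D));")
  tr2 <- ape::read.tree(text = "((A,C),(B,D));")
  ms2 <- map_support(tr1, c(rep(list(tr1), 95), rep(list(tr2), 5)))
  expect_identical(ms2$table$support, 95L)
  ms3 <- map_support(tr1, rep(list(tr2), 8))
  expect_identical(ms3$table$support, 0L)
  expect_error(map_support(tr1, list(ape::rtree(5, rooted = FALSE))),
               "leaf set")
})
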