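#' Run the full matrix-construction and signal pipeline
#'
#' Orchestrates the complete flow from raw inputs to data matrices and
#' signal reports: hit-table classification, in-frame stop screening and
#' genetic-code-aware translation, long-branch sequence removal,
#' length/occupancy gene filtering, AA and C12 supermatrix concatenation,
#' and — when a reference tree is supplied — internode-certainty
#' annotation. Every stage's counts go into a JSON manifest; re-running
#' with identical inputs and seed reproduces identical outputs.
#'
#' @param config a named list, or the path of a YAML file containing one,
#'   with entries:
#'   \describe{
#'     \item{genes_dir}{directory of per-gene FASTA codon alignments}
#'     \item{trees_dir}{directory of per-gene Newick trees (same basenames)}
#'     \item{hits_tsv, ref_stats_tsv}{BUSCO-style hit table and per-gene
#'       reference stats (optional; classification skipped when absent)}
#'     \item{taxa_file}{one taxon per line (the taxon universe)}
#'     \item{cug_ser_taxa_file}{taxa using the CUG-Ser code (optional)}
#'     \item{reference_tree}{Newick species tree for IC annotation (optional)}
#'     \item{out_dir}{output directory}
#'     \item{long_branch_factor}{default 20}
#'     \item{min_len_bp}{default 500}
#'     \item{min_taxa_frac}{default 0.5}
#'     \item{excluded_genes}{default none}
#'     \item{ic_mode}{"IC" or "ICA", default "IC"}
#'     \item{seed}{default 1}
#'   }
#' @return Invisibly, a list with the manifest, the two supermatrices, the
#'   filter reports and (if computed) the annotated reference tree.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  need <- c("genes_dir", "trees_dir", "taxa_file", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    err(paste("config is missing:", paste(miss, collapse = ", ")),
        "phylomic_config_error")
  defaults <- list(long_branch_factor = 20, min_len_bp = 500,
                   min_taxa_frac = 0.5, excluded_genes = character(),
                   ic_mode = "IC", seed = 1L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (p in c("genes_dir", "trees_dir", "taxa_file"))
    if (!file.exists(config[[p]]))
      err(paste("path does not exist:", config[[p]]), "phylomic_config_error")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  taxa <- readLines(config$taxa_file)
  cug_taxa <- if (!is.null(config$cug_ser_taxa_file) &&
                  file.exists(config$cug_ser_taxa_file))
    readLines(config$cug_ser_taxa_file) else character()

  gene_files <- sort(list.files(config$genes_dir, pattern = "\\.fa(sta)?$",
                                full.names = TRUE))
  genes <- sub("\\.fa(sta)?$", "", basename(gene_files))
  manifest <- list(parameters = config[c("long_branch_factor", "min_len_bp",
                                         "min_taxa_frac", "ic_mode", "seed")],
                   taxon_threshold = ceiling(config$min_taxa_frac * length(taxa)),
                   n_taxa = length(taxa),
                   input_hashes = as.list(tools::md5sum(gene_files)))

  # stage 1: genome completeness (optional)
  if (!is.null(config$hits_tsv) && file.exists(config$hits_tsv)) {
    hits <- read_tsv_table(config$hits_tsv)
    ref_stats <- read_tsv_table(config$ref_stats_tsv)
    statuses <- classify_hits(hits, ref_stats, genomes = taxa)
    summaries <- do.call(rbind, lapply(split(statuses, statuses$genome),
                                       summarize_genome,
                                       n_busco = length(unique(ref_stats$busco_gene))))
    write_tsv_table(statuses, file.path(config$out_dir, "busco_status.tsv"))
    write_tsv_table(summaries, file.path(config$out_dir, "genome_summary.tsv"))
    manifest$busco <- list(n_genomes = length(unique(statuses$genome)),
                           n_genes = length(unique(statuses$busco_gene)),
                           n_complete = sum(statuses$status == "complete"))
  }

  # stage 2: load alignments, screen stops, translate
  codes <- stats::setNames(ifelse(taxa %in% cug_taxa, "cug_ser", "standard"), taxa)
  alns <- stats::setNames(lapply(seq_along(gene_files), function(i) {
    seqs <- read_fasta(gene_files[i], "DNA")
    codon_alignment(genes[i], seqs,
                    codes[intersect(names(seqs), names(codes)[codes == "cug_ser"])])
  }), genes)
  stop_flagged <- lapply(alns, function(a) {
    names(a$seqs)[vapply(names(a$seqs), function(tx)
      has_inframe_stop(gsub("-", "", a$seqs[[tx]]), a$codes[[tx]]), logical(1))]
  })
  n_stop <- sum(lengths(stop_flagged))
  for (g in genes)
    if (length(stop_flagged[[g]]))
      alns[[g]] <- apply_sequence_removal(alns[[g]], stop_flagged[[g]])
  manifest$stop_screen <- list(sequences_removed = n_stop)

  # stage 3: long-branch removal
  tree_files <- stats::setNames(file.path(config$trees_dir, paste0(genes, ".nwk")), genes)
  absent <- !file.exists(tree_files)
  if (any(absent))
    err(paste("no tree for gene(s):", paste(genes[absent], collapse = ", ")),
        "phylomic_data_error")
  trees <- lapply(tree_files, ape::read.tree)
  screened <- screen_long_branches(alns, trees, config$long_branch_factor)
  write_tsv_table(screened$removals, file.path(config$out_dir, "long_branch_removals.tsv"))
  manifest$long_branch <- list(sequences_removed = nrow(screened$removals),
                               genes_affected = length(unique(screened$removals$gene)))

  # stage 4: length / occupancy filter
  filt <- filter_gene_set(screened$alignments, config$min_len_bp,
                          config$min_taxa_frac, length(taxa),
                          config$excluded_genes)
  write_tsv_table(filt$report, file.path(config$out_dir, "gene_filter_report.tsv"))
  manifest$filter <- list(genes_in = length(alns),
                          genes_out = length(filt$retained),
                          genes_dropped = length(alns) - length(filt$retained))

  # stage 5: matrices
  aa_alns <- lapply(filt$retained, translate_alignment)
  m_aa <- concatenate_genes(aa_alns, taxa, "AA")
  m_c12 <- concatenate_genes(filt$retained, taxa, "C12")
  write_supermatrix(m_aa, file.path(config$out_dir, "matrix_AA"))
  write_supermatrix(m_c12, file.path(config$out_dir, "matrix_C12"))
  gc <- do.call(rbind, lapply(filt$retained, function(a)
    data.frame(gene = a$gene, t(gc_by_codon_position(a)))))
  write_tsv_table(gc, file.path(config$out_dir, "gc_by_position.tsv"))
  manifest$matrices <- list(aa_columns = m_aa$n_col, c12_columns = m_c12$n_col,
                            n_genes = nrow(m_aa$partitions))

  # stage 6: internode certainty against a reference tree (optional)
  annotated <- NULL
  if (!is.null(config$reference_tree) && file.exists(config$reference_tree)) {
    ref <- ape::read.tree(config$reference_tree)
    kept_trees <- trees[names(filt$retained)]
    annotated <- annotate_ic(ref, kept_trees, config$ic_mode)
    write_tsv_table(annotated$table, file.path(config$out_dir, "internode_ic.tsv"))
    manifest$signal <- list(mean_ic = round(annotated$mean_ic, 3),
                            n_internodes = nrow(annotated$table))
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, matrix_aa = m_aa, matrix_c12 = m_c12,
                 filter_report = filt$report, removals = screened$removals,
                 annotated = annotated))
}
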