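#' Genome-completeness classification from candidate-hit tables
#'
#' Each genome is scanned for a preselected set of near-universal
#' single-copy orthologs (BUSCO genes). The upstream search (tBLASTn +
#' gene prediction + HMM alignment) yields, per genome and gene, zero or
#' more candidate hits with an alignment bit-score and an aligned length;
#' classification into complete / duplicated / fragmented / missing is a
#' pure function of those numbers against per-gene reference standards:
#' a bit-score cutoff (90% of the lowest bit-score among the reference
#' genomes) and a reference aligned length.
#'
#' @name buscoclass
NULL

status_levels <- c("complete", "duplicated", "fragmented", "missing")

#' Classify one gene in one genome
#'
#' Hits with bit-score strictly above the cutoff are retained. No retained
#' hit: `missing`. All retained hits shorter than 95% of the reference
#' aligned length: `fragmented`. Otherwise the full-length retained hits
#' (length at or above the 95% mark) determine the call: one is `complete`,
#' two or more `duplicated`.
#'
#' @param hits data frame with columns `genome`, `busco_gene`,
#'   `candidate_id`, `bit_score`, `aligned_length`; all rows one
#'   genome-gene pair. Zero rows allowed.
#' @param ref single-row data frame (or list) with `busco_gene`,
#'   `bitscore_cutoff`, `ref_aligned_length`.
#' @return Character scalar, one of `"complete"`, `"duplicated"`,
#'   `"fragmented"`, `"missing"`.
#' @export
classify_gene <- function(hits, ref) {
  if (nrow(hits) > 0L) {
    if (length(unique(hits$genome)) > 1L || length(unique(hits$busco_gene)) > 1L)
      err("hits mix genomes or genes", "phylomic_invalid_argument")
    if (!is.null(ref$busco_gene) && hits$busco_gene[1L] != ref$busco_gene)
      err("hits and reference stats are for different genes",
          "phylomic_invalid_argument")
  }
  retained <- hits[hits$bit_score > ref$bitscore_cutoff, , drop = FALSE]
  if (nrow(retained) == 0L) return("missing")
  full <- retained$aligned_length >= 0.95 * ref$ref_aligned_length
  if (!any(full)) return("fragmented")
  if (sum(full) == 1L) "complete" else "duplicated"
}

#' Classify a full hit table
#'
#' Applies [classify_gene()] to every genome-gene pair. Pairs with no hits
#' at all are `missing`, so the output always covers the full
#' `genomes x ref_stats` grid.
#'
#' @param hits data frame of candidate hits (may omit absent pairs).
#' @param ref_stats data frame with one row per gene: `busco_gene`,
#'   `bitscore_cutoff`, `ref_aligned_length`.
#' @param genomes character vector of genomes to classify; defaults to the
#'   genomes present in `hits`.
#' @return Data frame `genome`, `busco_gene`, `status`.
#' @export
classify_hits <- function(hits, ref_stats, genomes = NULL) {
  if (anyDuplicated(ref_stats$busco_gene))
    err("duplicate genes in ref_stats", "phylomic_invalid_argument")
  if (is.null(genomes)) genomes <- sort(unique(hits$genome))
  unknown <- setdiff(unique(hits$busco_gene), ref_stats$busco_gene)
  if (length(unknown))
    err(paste("hits for genes without reference stats:",
              paste(utils::head(unknown, 5), collapse = ", ")),
        "phylomic_invalid_argument")
  key <- paste(hits$genome, hits$busco_gene, sep = "\r")
  by_pair <- split(seq_len(nrow(hits)), key)
  grid <- expand.grid(genome = genomes, busco_gene = ref_stats$busco_gene,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  refs <- split(ref_stats, ref_stats$busco_gene)
  grid$status <- vapply(seq_len(nrow(grid)), function(i) {
    k <- paste(grid$genome[i], grid$busco_gene[i], sep = "\r")
    idx <- by_pair[[k]]
    h <- if (is.null(idx)) hits[0, , drop = FALSE] else hits[idx, , drop = FALSE]
    classify_gene(h, refs[[grid$busco_gene[i]]])
  }, character(1))
  grid
}

#' Summarise completeness for one genome
#'
#' Fractions of the BUSCO set in each category (summing to 1), percentages
#' to one decimal, and the "phylo" count: complete single-copy genes that
#' are additionally free of in-frame stop codons and therefore usable for
#' matrix construction.
#'
#' @param statuses data frame `genome`, `busco_gene`, `status` for one
#'   genome; genes absent from it count as missing.
#' @param n_busco total number of BUSCO genes assessed.
#' @param stop_free optional named logical vector (by gene): `TRUE` when
#'   the gene's sequence in this genome has no in-frame stop codon.
#'   Defaults to all `TRUE`.
#' @return One-row data frame: `genome`, counts `n_complete`,
#'   `n_duplicated`, `n_fragmented`, `n_missing`, `n_phylo`, and
#'   percentages `pct_complete` etc. (one decimal).
#' @export
summarize_genome <- function(statuses, n_busco, stop_free = NULL) {
  if (!is_count(n_busco) || n_busco < 1)
    err("n_busco must be a positive count", "phylomic_invalid_argument")
  if (length(unique(statuses$genome)) != 1L)
    err("statuses must cover exactly one genome", "phylomic_invalid_argument")
  if (anyDuplicated(statuses$busco_gene))
    err("duplicate (genome, gene) entries", "phylomic_invalid_argument")
  counts <- stats::setNames(integer(4), status_levels)
  tab <- table(factor(statuses$status, levels = status_levels))
  counts[names(tab)] <- as.integer(tab)
  counts["missing"] <- counts[["missing"]] + as.integer(n_busco) - nrow(statuses)
  comp_genes <- statuses$busco_gene[statuses$status == "complete"]
  ok <- if (is.null(stop_free)) rep(TRUE, length(comp_genes)) else {
    v <- stop_free[comp_genes]
    v[is.na(v)] <- TRUE
    v
  }
  out <- data.frame(genome = statuses$genome[1L],
                    n_complete = counts[["complete"]],
                    n_duplicated = counts[["duplicated"]],
                    n_fragmented = counts[["fragmented"]],
                    n_missing = counts[["missing"]],
                    n_phylo = sum(ok),
                    stringsAsFactors = FALSE)
  for (s in status_levels)
    out[[paste0("pct_", s)]] <- pct1(counts[[s]] / n_busco)
  out$pct_phylo <- pct1(out$n_phylo / n_busco)
  out
}

#' Write / read hit tables and reference stats as TSV
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_tsv_table` returns a data frame; `write_tsv_table`
#'   invisibly returns `path`.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
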