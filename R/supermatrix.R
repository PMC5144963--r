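#' Supermatrix concatenation and occupancy statistics
#'
#' Per-gene alignments are concatenated (gene order fixed: lexicographic
#' by name) into a single character matrix with per-gene partition
#' coordinates and occupancy metadata. Two matrix kinds are supported:
#' `"AA"` (amino-acid rows) and `"C12"` (first and second codon positions
#' of the codon alignments; always exactly twice the AA column count for
#' the same gene set). Taxa wholly absent from a gene get `"?"` across
#' that gene's partition — distinct from within-alignment `"-"` indels.
#'
#' @name supermatrix
NULL

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param alns list of [aa_alignment]s (`kind = "AA"`) or
#'   [codon_alignment]s (`kind = "C12"`; first and second codon positions
#'   are extracted here). Gene names must be unique.
#' @param taxa_universe character vector of all taxa; every alignment
#'   taxon must belong to it.
#' @param kind `"AA"` or `"C12"`.
#' @return A `supermatrix`: `kind`, `taxa`, `n_col`, `rows` (named
#'   character vector), `partitions` (data frame `gene`, `start`, `end`;
#'   0-based half-open), `gene_occupancy`, `taxon_occupancy` (named
#'   proportions), `presence` (genes x taxa logical matrix).
#' @export
concatenate_genes <- function(alns, taxa_universe, kind = c("AA", "C12")) {
  kind <- match.arg(kind)
  taxa_universe <- as.character(taxa_universe)
  if (anyDuplicated(taxa_universe))
    err("duplicate taxa in universe", "phylomic_invalid_argument")
  genes <- vapply(alns, `[[`, character(1), "gene")
  if (anyDuplicated(genes))
    err("duplicate gene names", "phylomic_invalid_argument")
  alns <- alns[order(genes)]
  genes <- sort(genes)
  chunks <- lapply(alns, function(a) {
    if (kind == "C12") {
      stopifnot(inherits(a, "codon_alignment"))
      extract_c12(a)$seqs
    } else {
      stopifnot(inherits(a, c("aa_alignment", "c12_alignment")) ||
                  is.character(a$seqs))
      a$seqs
    }
  })
  widths <- vapply(chunks, function(s) nchar(s[[1L]]), integer(1))
  for (i in seq_along(chunks)) {
    outside <- setdiff(names(chunks[[i]]), taxa_universe)
    if (length(outside))
      err(sprintf("gene %s has taxa outside the universe: %s", genes[i],
                  paste(outside, collapse = ", ")),
          "phylomic_invalid_argument")
  }
  ends <- cumsum(widths)
  parts <- data.frame(gene = genes, start = ends - widths, end = ends,
                      stringsAsFactors = FALSE)
  presence <- vapply(chunks, function(s) taxa_universe %in% names(s),
                     logical(length(taxa_universe)))
  presence <- matrix(presence, ncol = length(genes),
                     dimnames = list(taxa_universe, genes))
  rows <- vapply(taxa_universe, function(tx) {
    paste(vapply(seq_along(chunks), function(i) {
      s <- chunks[[i]]
      if (tx %in% names(s)) s[[tx]] else strrep("?", widths[i])
    }, character(1)), collapse = "")
  }, character(1))
  structure(list(kind = kind,
                 taxa = taxa_universe,
                 n_col = sum(widths),
                 rows = rows,
                 partitions = parts,
                 gene_occupancy = stats::setNames(colMeans(presence), genes),
                 taxon_occupancy = stats::setNames(rowMeans(presence),
                                                   taxa_universe),
                 presence = t(presence)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix %s> %d taxa x %d sites, %d gene partitions; mean gene occupancy %.1f%%\n",
              x$kind, length(x$taxa), x$n_col, nrow(x$partitions),
              100 * mean(x$gene_occupancy)))
  invisible(x)
}

#' Occupancy report for a supermatrix
#'
#' @param m a `supermatrix`.
#' @return List with `genes` (data frame: `gene`, `n_taxa`, `length`,
#'   `occupancy_pct`), `taxa` (data frame: `taxon`, `n_genes`,
#'   `occupancy_pct`), and `summary` (min / max / mean gene occupancy in
#'   percent to one decimal; gene length min / max / mean). Lengths are in
#'   sites of the matrix kind (residues for AA, nucleotides for C12).
#' @export
occupancy_report <- function(m) {
  stopifnot(inherits(m, "supermatrix"))
  widths <- m$partitions$end - m$partitions$start
  genes <- data.frame(gene = m$partitions$gene,
                      n_taxa = as.integer(rowSums(m$presence)),
                      length = widths,
                      occupancy_pct = pct1(m$gene_occupancy[m$partitions$gene]),
                      stringsAsFactors = FALSE)
  taxa <- data.frame(taxon = m$taxa,
                     n_genes = as.integer(colSums(m$presence)),
                     occupancy_pct = pct1(m$taxon_occupancy[m$taxa]),
                     stringsAsFactors = FALSE)
  list(genes = genes, taxa = taxa,
       summary = list(gene_occupancy_min_pct = min(genes$occupancy_pct),
                      gene_occupancy_max_pct = max(genes$occupancy_pct),
                      gene_occupancy_mean_pct = pct1(mean(m$gene_occupancy)),
                      length_min = min(widths),
                      length_max = max(widths),
                      length_mean = mean(widths)))
}

#' Write a supermatrix (relaxed PHYLIP + partition file)
#'
#' Writes `<prefix>.phy` (relaxed sequential PHYLIP: header
#' `ntaxa ncol`, then one `name  sequence` line per taxon), a RAxML-style
#' partition file `<prefix>.partitions` with 1-based inclusive coordinates
#' (`LG, gene = 1-1484` for AA; `GTR` for C12 — model labels are metadata
#' only, no fitting happens here), and `<prefix>.occupancy.tsv`.
#'
#' @param m a `supermatrix`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_supermatrix <- function(m, prefix) {
  stopifnot(inherits(m, "supermatrix"))
  phy <- paste0(prefix, ".phy")
  con <- file(phy, "w")
  writeLines(sprintf("%d %d", length(m$taxa), m$n_col), con)
  writeLines(sprintf("%s  %s", m$taxa, m$rows[m$taxa]), con)
  close(con)
  model <- if (m$kind == "AA") "LG" else "GTR"
  parts <- paste0(prefix, ".partitions")
  writeLines(sprintf("%s, %s = %d-%d", model, m$partitions$gene,
                     m$partitions$start + 1L, m$partitions$end), parts)
  occ <- paste0(prefix, ".occupancy.tsv")
  write_tsv_table(occupancy_report(m)$genes, occ)
  invisible(c(phylip = phy, partitions = parts, occupancy = occ))
}

#' Read a relaxed-PHYLIP supermatrix and its partition file
#'
#' Round-trip companion to [write_supermatrix()]: reproduces taxa, row
#' order, sequences and partition coordinates exactly.
#'
#' @param prefix path prefix used at write time (or `phy`/`partitions`
#'   paths given explicitly).
#' @param kind matrix kind recorded on the rebuilt object.
#' @param phy,partitions explicit file paths, overriding `prefix`.
#' @return A `supermatrix` (presence inferred: a taxon counts as absent
#'   from a gene when its partition is entirely `"?"`).
#' @export
read_supermatrix <- function(prefix, kind = c("AA", "C12"),
                             phy = paste0(prefix, ".phy"),
                             partitions = paste0(prefix, ".partitions")) {
  kind <- match.arg(kind)
  lines <- readLines(phy)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  body <- body[lengths(body) == 2L]
  if (length(body) != hdr[1L])
    err("PHYLIP header does not match row count", "phylomic_invalid_input")
  taxa <- vapply(body, `[[`, character(1), 1L)
  rows <- stats::setNames(vapply(body, `[[`, character(1), 2L), taxa)
  pl <- readLines(partitions)
  pm <- regmatches(pl, regexec("^\\s*\\S+,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)", pl))
  parts <- data.frame(gene = vapply(pm, `[[`, character(1), 2L),
                      start = as.integer(vapply(pm, `[[`, character(1), 3L)) - 1L,
                      end = as.integer(vapply(pm, `[[`, character(1), 4L)),
                      stringsAsFactors = FALSE)
  presence <- vapply(taxa, function(tx) {
    vapply(seq_len(nrow(parts)), function(i) {
      seg <- substr(rows[[tx]], parts$start[i] + 1L, parts$end[i])
      seg != strrep("?", nchar(seg))
    }, logical(1))
  }, logical(nrow(parts)))
  presence <- matrix(presence, nrow = nrow(parts),
                     dimnames = list(parts$gene, taxa))
  structure(list(kind = kind, taxa = taxa, n_col = hdr[2L], rows = rows,
                 partitions = parts,
                 gene_occupancy = stats::setNames(rowMeans(presence), parts$gene),
                 taxon_occupancy = stats::setNames(colMeans(presence), taxa),
                 presence = presence),
            class = "supermatrix")
}
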