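#' Genetic codes, translation and codon-alignment handling
#'
#' The CUG-Ser clade of budding yeasts has reassigned the CUG (CTG) codon
#' from leucine to serine. All translation in this package is therefore
#' parameterised by a genetic code, and codon alignments carry a per-taxon
#' code assignment so a single ortholog alignment can mix standard-code and
#' CUG-Ser taxa.
#'
#' @name codonkit
NULL

#' Genetic code table
#'
#' `"standard"` is the standard nuclear code (Biostrings' `GENETIC_CODE`);
#' `"cug_ser"` differs at exactly one codon: CTG encodes serine instead of
#' leucine. Stop codons are identical in both.
#'
#' @param name `"standard"` or `"cug_ser"`.
#' @return A `genetic_code` object: `name` plus a 64-entry codon-to-residue
#'   map with stops marked `"*"`.
#' @examples
#' genetic_code("cug_ser")$table[["CTG"]] # "S"
#' @export
genetic_code <- function(name = c("standard", "cug_ser")) {
  name <- match.arg(name)
  tab <- Biostrings::GENETIC_CODE
  if (name == "cug_ser") tab[["CTG"]] <- "S"
  structure(list(name = name, table = tab), class = "genetic_code")
}

as_genetic_code <- function(code) {
  if (inherits(code, "genetic_code")) code else genetic_code(code)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L)
    err(sprintf("sequence length %d is not a multiple of 3", n),
        "phylomic_frame_error")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# residues per codon; gap codon "---" -> "-", ambiguity -> "X"; no stop check
codons_to_aa <- function(codons, tab) {
  aa <- unname(tab[codons])
  gap <- codons == "---"
  aa[gap] <- "-"
  bad <- is.na(aa) & !gap
  if (any(bad)) {
    mixed_gap <- grepl("-", codons[bad], fixed = TRUE)
    if (any(mixed_gap))
      err(sprintf("partial-codon gap in codon(s): %s",
                  paste(utils::head(codons[bad][mixed_gap], 3), collapse = ", ")),
          "phylomic_frame_error")
    aa[bad] <- "X"
  }
  aa
}

#' Translate an in-frame nucleotide sequence
#'
#' One residue per codon. Whole-codon gaps (`"---"`) become `"-"`; codons
#' containing ambiguity characters become `"X"`; any stop codon (terminal
#' included) raises an error of class `phylomic_inframe_stop` — sequences
#' entering the matrices must be stop-free.
#'
#' @param seq character scalar, in-frame nucleotide sequence (length a
#'   multiple of 3).
#' @param code a [genetic_code] or its name.
#' @return Character scalar, the amino-acid sequence.
#' @examples
#' translate_cds("CTG", "standard") # "L"
#' translate_cds("CTG", "cug_ser")  # "S"
#' @export
translate_cds <- function(seq, code = "standard") {
  code <- as_genetic_code(code)
  codons <- split_codons(toupper(seq))
  aa <- codons_to_aa(codons, code$table)
  if (any(aa == "*")) {
    i <- which(aa == "*")[1L]
    err(sprintf("in-frame stop codon %s at codon %d", codons[i], i),
        "phylomic_inframe_stop")
  }
  paste(aa, collapse = "")
}

#' Screen a sequence for in-frame stop codons
#'
#' @inheritParams translate_cds
#' @return `TRUE` iff any codon maps to a stop under `code` (terminal stops
#'   count).
#' @export
has_inframe_stop <- function(seq, code = "standard") {
  code <- as_genetic_code(code)
  codons <- split_codons(toupper(seq))
  any(codons_to_aa(codons, code$table) == "*")
}

#' Codon alignment container
#'
#' An aligned set of in-frame nucleotide sequences for one ortholog group,
#' with a per-taxon genetic-code assignment. All rows must be the same
#' length, a multiple of 3, and gaps may occur only as whole-codon triples
#' (`"---"`) — guaranteed when the alignment is built by threading onto an
#' amino-acid alignment.
#'
#' @param gene gene name.
#' @param seqs named character vector, taxon to aligned sequence.
#' @param codes named character vector of genetic-code names per taxon;
#'   taxa not listed default to `"standard"`.
#' @return A `codon_alignment` object.
#' @export
codon_alignment <- function(gene, seqs, codes = NULL) {
  if (length(seqs) == 0L || is.null(names(seqs)))
    err("seqs must be a named nonempty character vector",
        "phylomic_invalid_argument")
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    err("all rows of a codon alignment must have equal length",
        "phylomic_invalid_argument")
  if (len %% 3L != 0L)
    err("codon alignment length must be a multiple of 3",
        "phylomic_frame_error")
  for (tx in names(seqs)) {
    cods <- split_codons(seqs[[tx]])
    mixed <- grepl("-", cods, fixed = TRUE) & cods != "---"
    if (any(mixed))
      err(sprintf("taxon %s has a partial-codon gap (codon %d)",
                  tx, which(mixed)[1L]), "phylomic_frame_error")
  }
  all_codes <- stats::setNames(rep("standard", length(seqs)), names(seqs))
  if (!is.null(codes)) {
    unknown <- setdiff(names(codes), names(seqs))
    if (length(unknown))
      err(paste("code assignment for taxa absent from alignment:",
                paste(unknown, collapse = ", ")), "phylomic_invalid_argument")
    all_codes[names(codes)] <- codes
  }
  structure(list(gene = gene, seqs = seqs, codes = all_codes),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon alignment> gene %s: %d taxa x %d nt (%d codons)\n",
              x$gene, length(x$seqs), nchar(x$seqs[[1L]]),
              nchar(x$seqs[[1L]]) %/% 3L))
  invisible(x)
}

#' Amino-acid alignment container
#'
#' @param gene gene name.
#' @param seqs named character vector, taxon to aligned residue string.
#' @return An `aa_alignment` object.
#' @export
aa_alignment <- function(gene, seqs) {
  if (length(seqs) == 0L || is.null(names(seqs)))
    err("seqs must be a named nonempty character vector",
        "phylomic_invalid_argument")
  if (length(unique(nchar(seqs))) != 1L)
    err("all rows of an alignment must have equal length",
        "phylomic_invalid_argument")
  structure(list(gene = gene, seqs = toupper(seqs)), class = "aa_alignment")
}

#' Translate a codon alignment row-wise
#'
#' @param codon_aln a [codon_alignment].
#' @return An [aa_alignment] of one residue per codon, using each taxon's
#'   assigned genetic code.
#' @export
translate_alignment <- function(codon_aln) {
  stopifnot(inherits(codon_aln, "codon_alignment"))
  aa <- vapply(names(codon_aln$seqs), function(tx)
    translate_cds(codon_aln$seqs[[tx]], codon_aln$codes[[tx]]),
    character(1))
  aa_alignment(codon_aln$gene, aa)
}

#' Thread coding sequences onto an amino-acid alignment
#'
#' Back-translation: each aligned residue is replaced by the codon it was
#' translated from, each `"-"` by `"---"`, producing the codon-based
#' nucleotide alignment. Every CDS must translate (under its taxon's
#' genetic code) exactly to its alignment row with gaps removed; a mismatch
#' raises a threading error naming the taxon and alignment column, which is
#' how using the wrong code (e.g. standard instead of CUG-Ser) surfaces.
#'
#' @param aa_aln an [aa_alignment].
#' @param cds named character vector of unaligned in-frame nucleotide
#'   sequences, one per alignment taxon.
#' @param codes named character vector of genetic-code names per taxon
#'   (default standard).
#' @return A [codon_alignment]; translating it column-wise reproduces
#'   `aa_aln` exactly.
#' @export
thread_codons <- function(aa_aln, cds, codes = NULL) {
  stopifnot(inherits(aa_aln, "aa_alignment"))
  missing_cds <- setdiff(names(aa_aln$seqs), names(cds))
  if (length(missing_cds))
    err(paste("no CDS supplied for taxa:", paste(missing_cds, collapse = ", ")),
        "phylomic_invalid_argument")
  code_of <- stats::setNames(rep("standard", length(aa_aln$seqs)),
                             names(aa_aln$seqs))
  if (!is.null(codes)) code_of[names(codes)] <- codes
  out <- vapply(names(aa_aln$seqs), function(tx) {
    row <- strsplit(aa_aln$seqs[[tx]], "", fixed = TRUE)[[1L]]
    codons <- split_codons(toupper(cds[[tx]]))
    aa_cds <- codons_to_aa(codons, as_genetic_code(code_of[[tx]])$table)
    pieces <- character(length(row))
    j <- 0L
    for (i in seq_along(row)) {
      if (row[i] == "-") {
        pieces[i] <- "---"
        next
      }
      j <- j + 1L
      if (j > length(codons) || aa_cds[j] != row[i])
        err(sprintf("threading mismatch for taxon %s at alignment column %d: residue %s vs CDS codon %s",
                    tx, i, row[i],
                    if (j <= length(codons)) codons[j] else "<exhausted>"),
            "phylomic_threading_error")
      pieces[i] <- codons[j]
    }
    if (j != length(codons))
      err(sprintf("threading mismatch for taxon %s: %d unused codon(s) in CDS",
                  tx, length(codons) - j), "phylomic_threading_error")
    paste(pieces, collapse = "")
  }, character(1))
  codon_alignment(aa_aln$gene, out,
                  if (is.null(codes)) NULL else
                    codes[intersect(names(codes), names(out))])
}

#' Extract first and second codon positions
#'
#' Drops every third codon position, the usual remedy for compositional
#' heterogeneity: third positions show far higher GC variation across taxa
#' than first and second positions. The output has 2/3 the input length;
#' gap codons yield `"--"`.
#'
#' @param codon_aln a [codon_alignment].
#' @return List of class `c12_alignment` with `gene` and `seqs` (named
#'   character vector of positions 1 and 2 of every codon, in order).
#' @examples
#' aln <- codon_alignment("g", c(a = "ATGAAA"))
#' extract_c12(aln)$seqs[["a"]] # "ATAA"
#' @export
extract_c12 <- function(codon_aln) {
  stopifnot(inherits(codon_aln, "codon_alignment"))
  seqs <- vapply(codon_aln$seqs, function(s) gsub("(..).", "\\1", s),
                 character(1))
  structure(list(gene = codon_aln$gene, seqs = seqs), class = "c12_alignment")
}

#' GC content by codon position
#'
#' Per-position-class GC fraction over unambiguous, non-gap characters.
#' Third-position GC is the saturation/compositional-bias diagnostic that
#' motivates the C12 matrix.
#'
#' @param codon_aln a [codon_alignment].
#' @return Named numeric vector `c(gc1, gc2, gc3)`, each in `[0, 1]`, `NA`
#'   for a position class with no countable characters.
#' @export
gc_by_codon_position <- function(codon_aln) {
  stopifnot(inherits(codon_aln, "codon_alignment"))
  chars <- do.call(rbind, strsplit(unname(codon_aln$seqs), "", fixed = TRUE))
  len <- ncol(chars)
  gc_at <- function(p) {
    v <- as.vector(chars[, seq(p, len, 3L), drop = FALSE])
    v <- v[v %in% c("A", "C", "G", "T")]
    if (length(v) == 0L) return(NA_real_)
    mean(v %in% c("G", "C"))
  }
  c(gc1 = gc_at(1L), gc2 = gc_at(2L), gc3 = gc_at(3L))
}
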