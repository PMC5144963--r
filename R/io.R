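# FASTA IO via Biostrings; trees go through ape's Newick reader/writer

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings with plain named character vectors as
#' the in-memory representation (gaps `-` and ambiguity characters are
#' preserved verbatim).
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @param type `"DNA"` or `"AA"` (read only).
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   invisibly returns `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path)
  else Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
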