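#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings returning/accepting the package's
#' sequence tibble (`seq_id`, `seq`, `length_bp`).  Sequences are wrapped
#' at 60 columns on write; headers are truncated at the first whitespace
#' on read.
#'
#' @param path File path.
#' @return `read_fasta()` returns a sequence tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seq_tbl(ids, toupper(as.character(ss)))
}

#' @rdname read_fasta
#' @param seqs A sequence tibble (see [seq_tbl()]).
#' @export
write_fasta <- function(seqs, path) {
  assert_seq_tbl(seqs)
  ss <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$seq_id))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
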