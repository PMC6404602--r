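# Internal helpers shared across modules.

# All internal intervals are 0-based half-open; CMAP/AGP coordinates are
# 1-based inclusive.  These two converters are the only place the shift
# happens.
to1based <- function(start0) start0 + 1L
to0based <- function(start1) start1 - 1L

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` strings (IUPAC codes
#' are handled by Biostrings).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  out <- character(length(x))
  nz <- !is.na(x) & nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out[!nz] <- x[!nz]
  out
}

# Deterministic per-stage sub-seed: adding a stage never perturbs the
# random stream of an earlier one.
sub_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 131 + stream) %% (2^31 - 1))
}

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(seed, stream))
  force(code)
}

assert_seq_tbl <- function(seqs, need_seq = TRUE, arg = "seqs") {
  if (!is.data.frame(seqs) || !all(c("seq_id", "seq") %in% names(seqs))) {
    abort(sprintf("`%s` must be a data frame with columns seq_id and seq", arg))
  }
  if (anyDuplicated(seqs$seq_id)) {
    abort(sprintf("duplicate seq_id in `%s`: %s", arg,
                  seqs$seq_id[duplicated(seqs$seq_id)][1]))
  }
  if (need_seq && any(is.na(seqs$seq))) {
    abort(sprintf("`%s` contains records without sequence", arg))
  }
  invisible(seqs)
}

#' Build a sequence table
#'
#' The package carries sequence collections as tibbles with columns
#' `seq_id`, `seq` and `length_bp`.  `seq` may be `NA` for a lengths-only
#' ledger (accounting operations work on lengths alone).
#'
#' @param seq_id Character vector of unique identifiers.
#' @param seq Character vector of sequences over `{A,C,G,T,N}` (or `NA`).
#' @param length_bp Lengths; derived from `seq` when omitted.
#' @return A tibble with columns `seq_id`, `seq`, `length_bp`.
#' @export
seq_tbl <- function(seq_id, seq = NA_character_, length_bp = NULL) {
  seq <- unname(toupper(seq))
  if (is.null(length_bp)) {
    if (any(is.na(seq))) abort("length_bp required when seq is NA")
    length_bp <- nchar(seq)
  }
  out <- tibble(seq_id = as.character(seq_id), seq = seq,
                length_bp = as.double(length_bp))
  assert_seq_tbl(out, need_seq = FALSE)
  ok <- !is.na(out$seq)
  if (any(nchar(out$seq[ok]) != out$length_bp[ok])) {
    abort("length_bp disagrees with nchar(seq)")
  }
  out
}

count_n <- function(seq) {
  ifelse(is.na(seq), 0L, stringr::str_count(seq, stringr::fixed("N")))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
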