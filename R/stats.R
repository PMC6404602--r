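#' Locate maximal runs of N in sequences
#'
#' N runs are the only positions where a confirmed chimeric scaffold may
#' be cut, and mark the sized gaps inside scaffolds.
#'
#' @param seqs A sequence tibble.
#' @return Tibble `seq_id`, `start`, `end` with 0-based half-open
#'   intervals, sorted and non-overlapping; runs are maximal (flanked by
#'   non-N bases or the sequence boundary).
#' @examples
#' find_n_runs(seq_tbl("a", "ANNNNA"))
#' @export
find_n_runs <- function(seqs) {
  assert_seq_tbl(seqs)
  res <- purrr::map2(seqs$seq_id, seqs$seq, function(id, s) {
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1L) return(NULL)
    st <- as.integer(m)
    w <- attr(m, "match.length")
    tibble(seq_id = id, start = st - 1L, end = st - 1L + w)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble(seq_id = character(), start = integer(), end = integer())
  }
  out
}

#' Assembly summary statistics
#'
#' Standard assembly accounting: N50 is the length L such that sequences
#' of length >= L sum to at least half of the total; `n_pct` is the
#' percentage of N bases and `effective_bp = total_bp - N count` is the
#' gap-free assembly span.
#'
#' @param seqs A sequence tibble.  A lengths-only ledger (`seq = NA`) is
#'   accepted when it carries an `n_bases` column (N count per record);
#'   otherwise N counts come from the sequences.
#' @return One-row tibble: `n_sequences`, `total_bp`, `max_bp`, `n50_bp`,
#'   `n_pct`, `effective_bp`.
#' @examples
#' assembly_stats(seq_tbl(c("a", "b"), c("ACGTACGT", "ACGNNACG")))
#' @export
assembly_stats <- function(seqs) {
  assert_seq_tbl(seqs, need_seq = FALSE)
  if (nrow(seqs) == 0L) abort("assembly_stats() needs a non-empty collection")
  len <- as.double(seqs$length_bp)
  nb <- if (!all(is.na(seqs$seq))) {
    sum(count_n(seqs$seq))
  } else if ("n_bases" %in% names(seqs)) {
    sum(as.double(seqs$n_bases))
  } else 0
  total <- sum(len)
  tibble(
    n_sequences = nrow(seqs),
    total_bp = total,
    max_bp = max(len),
    n50_bp = n50(len),
    n_pct = 100 * nb / total,
    effective_bp = total - nb
  )
}

#' N50 of a length multiset
#'
#' @param lengths Numeric vector of sequence lengths.
#' @return The N50 length.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) abort("n50() of an empty length set")
  s <- sort(as.double(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}
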