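#' Recognition specifications for labeling enzymes
#'
#' The two chemistries mirror the Bionano kits: `direct` labels the motif
#' without cutting (DLE-1 style), `nick` marks single-strand nicks
#' (Nt.BspQI style) where two opposite-strand sites closer than
#' `fragile_distance_bp` form a fragile site prone to double-strand
#' breaks.  Motifs are shipped as overridable configuration, not
#' hard-coded in any algorithm.
#'
#' @param name Enzyme name.  `"DLE-1"` and `"Nt.BspQI"` have built-in
#'   motifs; any other name requires an explicit `motif`.
#' @param motif Recognition motif over `{A,C,G,T}`, length >= 4.
#' @param chemistry `"direct"` or `"nick"`.
#' @param fragile_distance_bp Opposite-strand site distance that forms a
#'   fragile site (nick chemistry only; must be > 0).
#' @return An object of class `enzyme_spec`.
#' @examples
#' enzyme_spec("DLE-1")
#' enzyme_spec("Nt.BspQI")
#' @export
enzyme_spec <- function(name, motif = NULL, chemistry = NULL,
                        fragile_distance_bp = NULL) {
  builtins <- list(
    "DLE-1"    = list(motif = "CTTAAG", chemistry = "direct"),
    "dle1"     = list(motif = "CTTAAG", chemistry = "direct"),
    "Nt.BspQI" = list(motif = "GCTCTTC", chemistry = "nick",
                      fragile_distance_bp = 1000L),
    "bspqi"    = list(motif = "GCTCTTC", chemistry = "nick",
                      fragile_distance_bp = 1000L)
  )
  if (is.null(motif) && name %in% names(builtins)) {
    b <- builtins[[name]]
    motif <- b$motif
    chemistry <- chemistry %||% b$chemistry
    fragile_distance_bp <- fragile_distance_bp %||% b$fragile_distance_bp
  }
  if (is.null(motif)) abort(sprintf("no built-in motif for enzyme '%s'", name))
  motif <- toupper(motif)
  if (nchar(motif) < 4L) abort("motif length must be >= 4")
  if (grepl("[^ACGT]", motif)) abort("motif may contain only A, C, G, T")
  chemistry <- match.arg(chemistry, c("direct", "nick"))
  if (chemistry == "nick") {
    fragile_distance_bp <- fragile_distance_bp %||% 1000L
    if (fragile_distance_bp <= 0) abort("fragile_distance_bp must be > 0")
  } else {
    fragile_distance_bp <- NA_integer_
  }
  structure(
    list(name = name, motif = motif, chemistry = chemistry,
         fragile_distance_bp = as.integer(fragile_distance_bp),
         palindromic = identical(motif, revcomp(motif))),
    class = "enzyme_spec"
  )
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s  motif %s  chemistry %s%s\n", x$name, x$motif,
              x$chemistry,
              if (x$chemistry == "nick")
                sprintf("  fragile_distance %d bp", x$fragile_distance_bp)
              else ""))
  invisible(x)
}

# 1-based starts of fixed-string matches; labels never arise from N runs
# because N does not literally match any motif base.
motif_starts <- function(seq, motif) {
  m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Collapse label clusters closer than min_dist to the rounded midpoint of
# the cluster extent (optical resolution model).
merge_close_labels <- function(pos, min_dist) {
  if (length(pos) < 2L || min_dist <= 0) return(pos)
  grp <- cumsum(c(1L, as.integer(diff(pos) >= min_dist)))
  as.numeric(tapply(pos, grp, function(p) round((min(p) + max(p)) / 2)))
}

#' In-silico digestion of sequences into label maps
#'
#' Finds every motif occurrence on either strand (label position = 1-based
#' start of the match on the forward strand; palindromic motifs are
#' reported once), then merges labels closer than
#' `min_label_distance_bp` to their midpoint, mimicking the optical
#' resolution limit.  Matches overlapping N runs yield no label because
#' the base content is unknown.
#'
#' @param seqs A sequence tibble.
#' @param enzyme An [enzyme_spec()].
#' @param min_label_distance_bp Labels closer than this are collapsed
#'   (default 1000 bp); 0 disables merging.
#' @return A label-map tibble (CMAP-style): `map_id`, `length_bp`,
#'   `site_id`, `position`, `channel`.  Sequences without any label
#'   contribute no rows.
#' @examples
#' s <- seq_tbl("x", paste0(strrep("A", 10), "CTTAAG", strrep("A", 14),
#'                          "CTTAAG", strrep("A", 14)))
#' digest_sequences(s, enzyme_spec("DLE-1"), min_label_distance_bp = 0)
#' @export
digest_sequences <- function(seqs, enzyme = enzyme_spec("DLE-1"),
                             min_label_distance_bp = 1000) {
  assert_seq_tbl(seqs)
  stopifnot(inherits(enzyme, "enzyme_spec"))
  rcm <- revcomp(enzyme$motif)
  res <- purrr::pmap(list(seqs$seq_id, seqs$seq, seqs$length_bp),
    function(id, s, len) {
      pos <- motif_starts(s, enzyme$motif)
      if (!enzyme$palindromic) {
        pos <- sort(unique(c(pos, motif_starts(s, rcm))))
      }
      pos <- merge_close_labels(pos, min_label_distance_bp)
      if (length(pos) == 0L) return(NULL)
      tibble(map_id = id, length_bp = as.double(len),
             site_id = seq_along(pos), position = as.double(pos),
             channel = 1L)
    })
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble(map_id = character(), length_bp = double(),
                  site_id = integer(), position = double(), channel = integer())
  }
  out
}

#' Fragile sites of a nicking chemistry
#'
#' Pairs of opposite-strand recognition sites closer than the enzyme's
#' `fragile_distance_bp` create fragile sites where labeled molecules
#' tend to suffer double-strand breaks.  Used by the optical-map
#' simulator to reproduce the fragmentation of nick-labeled maps.
#'
#' @inheritParams digest_sequences
#' @return Tibble `seq_id`, `pos_fwd`, `pos_rev`, `site` (midpoint, bp).
#' @export
fragile_sites <- function(seqs, enzyme) {
  assert_seq_tbl(seqs)
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (enzyme$chemistry != "nick") {
    return(tibble(seq_id = character(), pos_fwd = double(),
                  pos_rev = double(), site = double()))
  }
  rcm <- revcomp(enzyme$motif)
  d <- enzyme$fragile_distance_bp
  res <- purrr::map2(seqs$seq_id, seqs$seq, function(id, s) {
    fw <- motif_starts(s, enzyme$motif)
    rv <- motif_starts(s, rcm)
    if (length(fw) == 0L || length(rv) == 0L) return(NULL)
    pairs <- expand.grid(pos_fwd = fw, pos_rev = rv)
    pairs <- pairs[abs(pairs$pos_fwd - pairs$pos_rev) <= d, , drop = FALSE]
    if (nrow(pairs) == 0L) return(NULL)
    tibble(seq_id = id, pos_fwd = as.double(pairs$pos_fwd),
           pos_rev = as.double(pairs$pos_rev),
           site = round((pairs$pos_fwd + pairs$pos_rev) / 2))
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(seq_id = character(), pos_fwd = double(),
                  pos_rev = double(), site = double()))
  }
  arrange(out, .data$seq_id, .data$site)
}
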