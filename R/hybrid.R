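#' Place validated scaffolds on optical map contigs
#'
#' Each scaffold receives at most one placement: its highest-confidence
#' alignment, provided any runner-up on a different locus trails by more
#' than `margin` confidence units; otherwise the scaffold is ambiguous
#' and left unplaced.  Placements on one map may not overlap by more
#' than `overlap_tol` bp — the lower-confidence overlapper is demoted.
#'
#' @param alignments Alignment tibble from [align_maps()]
#'   (chimera-resolved inputs).
#' @param margin Ambiguity margin in confidence units.
#' @param overlap_tol Tolerated projected-extent overlap in bp.
#' @param min_confidence Optional extra confidence filter.
#' @return Placement tibble: `seq_id`, `map_id`, `map_start`, `map_end`
#'   (projected scaffold extent on the map), `orientation`,
#'   `confidence`, plus the flanking aligned-label coordinates used for
#'   gap estimation (`q_first_or`, `q_last_or`, `r_first`, `r_last`,
#'   `seq_len_bp`).  Unplaced scaffolds and their reasons are in
#'   `attr(, "unplaced")`.
#' @export
place_sequences <- function(alignments, margin = 3, overlap_tol = 20000,
                            min_confidence = NULL) {
  if (!is.null(min_confidence)) {
    alignments <- filter(alignments, .data$confidence >= min_confidence)
  }
  unplaced <- list()
  rows <- list()
  for (sid in unique(alignments$query_id)) {
    al <- alignments[alignments$query_id == sid, ]
    al <- al[order(-al$confidence), ]
    best <- al[1, ]
    alt_conf <- -Inf
    if (nrow(al) >= 2L) {
      other <- al[-1, ]
      off_locus <- other$ref_id != best$ref_id |
        other$ref_start_bp > best$ref_end_bp |
        other$ref_end_bp < best$ref_start_bp
      if (any(off_locus)) alt_conf <- max(other$confidence[off_locus])
    }
    # the competing chain on another contig at extraction time also
    # measures ambiguity (e.g. a repeat locus present on two contigs)
    if ("runner_up_conf" %in% names(al) && !is.na(best$runner_up_conf)) {
      alt_conf <- max(alt_conf, best$runner_up_conf)
    }
    if (alt_conf > best$confidence - margin) {
      unplaced[[length(unplaced) + 1L]] <-
        tibble(seq_id = sid, reason = "ambiguous")
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      seq_id = sid, map_id = best$ref_id,
      map_start = best$ref_start_bp - (best$qry_start_or - 1),
      map_end = best$ref_end_bp + (best$query_len_bp - best$qry_end_or),
      orientation = best$orientation, confidence = best$confidence,
      q_first_or = best$qry_start_or, q_last_or = best$qry_end_or,
      r_first = best$ref_start_bp, r_last = best$ref_end_bp,
      seq_len_bp = best$query_len_bp)
  }
  pl <- bind_rows(rows)
  if (nrow(pl) == 0L) {
    pl <- tibble(seq_id = character(), map_id = character(),
                 map_start = double(), map_end = double(),
                 orientation = character(), confidence = double(),
                 q_first_or = double(), q_last_or = double(),
                 r_first = double(), r_last = double(), seq_len_bp = double())
  }
  # resolve overlapping placements per map, higher confidence wins
  keep <- rep(TRUE, nrow(pl))
  for (mid in unique(pl$map_id)) {
    idx <- which(pl$map_id == mid)
    idx <- idx[order(-pl$confidence[idx])]
    kept <- integer(0)
    for (i in idx) {
      ov <- FALSE
      for (j in kept) {
        overlap <- min(pl$map_end[i], pl$map_end[j]) -
          max(pl$map_start[i], pl$map_start[j])
        if (overlap > overlap_tol) { ov <- TRUE; break }
      }
      if (ov) {
        keep[i] <- FALSE
        unplaced[[length(unplaced) + 1L]] <-
          tibble(seq_id = pl$seq_id[i], reason = "overlap")
      } else {
        kept <- c(kept, i)
      }
    }
  }
  pl <- pl[keep, , drop = FALSE]
  pl <- arrange(pl, .data$map_id, .data$map_start)
  attr(pl, "unplaced") <- bind_rows(unplaced) %||%
    tibble(seq_id = character(), reason = character())
  pl
}

#' Estimate the gap between two adjacent placements
#'
#' The gap is the map distance between the last aligned label of the
#' left scaffold and the first aligned label of the right scaffold,
#' minus the unaligned sequence tail of the left scaffold beyond its
#' last aligned label and the unaligned head of the right scaffold
#' before its first aligned label, floored at `min_gap`.
#'
#' @param left,right Single placement rows, adjacent on one map.
#' @param min_gap Floor for the reported gap (bp).
#' @param overlap_tol Allowed violation of `left` ending before `right`.
#' @return Gap size in bp (integer scalar).
#' @export
estimate_gap <- function(left, right, min_gap = 13, overlap_tol = 20000) {
  if (left$map_id != right$map_id) abort("placements on different maps")
  if (left$map_end > right$map_start + overlap_tol ||
      right$map_start < left$map_start) {
    abort("placements are not adjacent")
  }
  raw <- (right$r_first - left$r_last) -
    (left$seq_len_bp - left$q_last_or) - right$q_first_or
  max(round(raw), min_gap)
}

#' Estimate every inter-scaffold gap on every map
#'
#' @param placements Placement tibble from [place_sequences()].
#' @inheritParams estimate_gap
#' @return Tibble `map_id`, `left_id`, `right_id`, `raw_gap_bp`,
#'   `gap_bp`.
#' @export
estimate_gaps <- function(placements, min_gap = 13) {
  pl <- arrange(placements, .data$map_id, .data$map_start)
  out <- pl |>
    group_by(.data$map_id) |>
    mutate(
      left_id = .data$seq_id,
      right_id = lead(.data$seq_id),
      raw_gap_bp = (lead(.data$r_first) - .data$r_last) -
        (.data$seq_len_bp - .data$q_last_or) - lead(.data$q_first_or)
    ) |>
    ungroup() |>
    filter(!is.na(.data$right_id)) |>
    mutate(gap_bp = pmax(round(.data$raw_gap_bp), min_gap)) |>
    select("map_id", "left_id", "right_id", "raw_gap_bp", "gap_bp")
  out
}

superscaffold_empty <- function() {
  tibble(super_id = character(), member_index = integer(),
         seq_id = character(), orientation = character(),
         gap_after_bp = double(), length_bp = double(), map_id = character())
}

#' Build super-scaffolds from placements and gap estimates
#'
#' Per map contig, placed scaffolds are sorted by projected start and
#' joined with their estimated gaps; scaffolds unplaced on any map pass
#' through as singletons retaining their original identifiers (a contig
#' hosting a single scaffold likewise stays a singleton).  Every input
#' scaffold appears in exactly one super-scaffold.
#'
#' @param placements Placement tibble (non-overlapping per map).
#' @param gaps Gap tibble from [estimate_gaps()].
#' @param scaffolds Sequence tibble of all scaffolds (placed or not).
#' @param prefix Identifier prefix for multi-member super-scaffolds.
#' @return A long-format super-scaffold tibble of class
#'   `optscaf_superscaffolds`: one row per member with `super_id`,
#'   `member_index`, `seq_id`, `orientation`, `gap_after_bp` (`NA` for
#'   the last member; `-1` marks a gap of unknown size), `length_bp`,
#'   `map_id`.
#' @export
build_superscaffolds <- function(placements, gaps, scaffolds,
                                 prefix = "super") {
  assert_seq_tbl(scaffolds, need_seq = FALSE)
  rows <- list()
  pl <- arrange(placements, .data$map_id, .data$map_start)
  for (mid in unique(pl$map_id)) {
    mpl <- pl[pl$map_id == mid, ]
    if (nrow(mpl) == 1L) {
      rows[[length(rows) + 1L]] <- tibble(
        super_id = mpl$seq_id, member_index = 1L, seq_id = mpl$seq_id,
        orientation = mpl$orientation, gap_after_bp = NA_real_,
        map_id = mid)
      next
    }
    g <- gaps[gaps$map_id == mid, ]
    gap_after <- g$gap_bp[match(mpl$seq_id, g$left_id)]
    gap_after[nrow(mpl)] <- NA_real_
    rows[[length(rows) + 1L]] <- tibble(
      super_id = paste0(prefix, "_", mid),
      member_index = seq_len(nrow(mpl)), seq_id = mpl$seq_id,
      orientation = mpl$orientation, gap_after_bp = gap_after, map_id = mid)
  }
  placed_ids <- if (length(rows)) unique(bind_rows(rows)$seq_id) else character()
  singles <- setdiff(scaffolds$seq_id, placed_ids)
  if (length(singles)) {
    rows[[length(rows) + 1L]] <- tibble(
      super_id = singles, member_index = 1L, seq_id = singles,
      orientation = "+", gap_after_bp = NA_real_, map_id = NA_character_)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) out <- superscaffold_empty()
  out$length_bp <- scaffolds$length_bp[match(out$seq_id, scaffolds$seq_id)]
  if (anyNA(out$length_bp)) abort("placement refers to an unknown scaffold")
  out <- select(out, "super_id", "member_index", "seq_id", "orientation",
                "gap_after_bp", "length_bp", "map_id")
  class(out) <- c("optscaf_superscaffolds", class(out))
  out
}

super_lengths <- function(supers, unknown_gap_n = 100) {
  supers |>
    group_by(.data$super_id) |>
    summarise(length_bp = sum(.data$length_bp) +
                sum(if_else(is.na(.data$gap_after_bp), 0,
                            if_else(.data$gap_after_bp < 0,
                                    as.double(unknown_gap_n),
                                    .data$gap_after_bp))),
              n_members = n(), .groups = "drop")
}

#' Emit super-scaffold sequences and their AGP
#'
#' Members are concatenated in order and orientation (`-` members
#' reverse-complemented) with `gap_after_bp` Ns between; gaps of unknown
#' size are written as 100 Ns and AGP `U 100` rows, estimated gaps as
#' `N` rows with their length.  Rebuilding from the AGP plus the member
#' FASTA reproduces the emitted sequences bit-exactly.
#'
#' @param supers Super-scaffold tibble from [build_superscaffolds()].
#' @param scaffolds Sequence tibble holding every member sequence.
#' @param unknown_gap_n N count used for gaps of unknown size.
#' @return List with `sequences` (sequence tibble) and `agp`.
#' @export
emit_sequences <- function(supers, scaffolds, unknown_gap_n = 100) {
  assert_seq_tbl(scaffolds)
  missing <- setdiff(supers$seq_id, scaffolds$seq_id)
  if (length(missing)) {
    abort(sprintf("member missing from FASTA: %s", missing[1]))
  }
  seq_rows <- list(); agp_rows <- list()
  for (sid in unique(supers$super_id)) {
    mem <- supers[supers$super_id == sid, ]
    mem <- mem[order(mem$member_index), ]
    pos <- 0; part <- 0L; pieces <- character(0)
    for (i in seq_len(nrow(mem))) {
      s <- scaffolds$seq[match(mem$seq_id[i], scaffolds$seq_id)]
      if (mem$orientation[i] == "-") s <- revcomp(s)
      len <- nchar(s)
      part <- part + 1L
      agp_rows[[length(agp_rows) + 1L]] <- tibble(
        object = sid, object_beg = pos + 1, object_end = pos + len,
        part_number = part, component_type = "W",
        component_id = mem$seq_id[i], component_beg = "1",
        component_end = as.character(len), orientation = mem$orientation[i])
      pieces <- c(pieces, s)
      pos <- pos + len
      g <- mem$gap_after_bp[i]
      if (i < nrow(mem)) {
        unknown <- is.na(g) || g < 0
        glen <- if (unknown) unknown_gap_n else g
        part <- part + 1L
        agp_rows[[length(agp_rows) + 1L]] <- tibble(
          object = sid, object_beg = pos + 1, object_end = pos + glen,
          part_number = part,
          component_type = if (unknown) "U" else "N",
          component_id = as.character(glen), component_beg = "scaffold",
          component_end = "yes", orientation = "map")
        pieces <- c(pieces, strrep("N", glen))
        pos <- pos + glen
      }
    }
    seq_rows[[length(seq_rows) + 1L]] <-
      tibble(seq_id = sid, seq = paste(pieces, collapse = ""))
  }
  sq <- bind_rows(seq_rows)
  list(sequences = seq_tbl(sq$seq_id, sq$seq), agp = bind_rows(agp_rows))
}

#' Validate and extend super-scaffolds with a second optical map
#'
#' Super-scaffold sequences are re-digested (gap Ns carry no labels),
#' aligned to the second map, and super-scaffolds linked by concordant
#' placements are merged with optically estimated gaps.  Conflicts
#' against the second map are detected (and arbitrated against the
#' first-round alignments when supplied, with the roles of the maps
#' swapped); conflicting super-scaffolds are reported and excluded from
#' merging rather than cut, so N50 never decreases.  Conflict reports
#' are attached as `attr(, "conflicts")`.
#'
#' @param supers Round-one super-scaffold tibble.
#' @param scaffolds Member sequence tibble.
#' @param second_map Label-map tibble of the second-chemistry map.
#' @param enzyme [enzyme_spec()] of the second chemistry.
#' @param params [align_params()] for the second round (the merge rung
#'   of the confidence ladder).
#' @param tol [conflict_tol()].
#' @param first_alignments Optional alignment tibble of the same
#'   super-scaffold digests against the first map, used to arbitrate.
#' @param min_label_distance_bp Label-merge distance for re-digestion.
#' @param min_gap Gap floor (bp).
#' @return A super-scaffold tibble over the original scaffold members.
#' @export
second_round <- function(supers, scaffolds, second_map,
                         enzyme = enzyme_spec("Nt.BspQI"),
                         params = align_params(min_confidence = 15,
                                               label_footprint_bp = 7L),
                         tol = conflict_tol(), first_alignments = NULL,
                         min_label_distance_bp = 1000, min_gap = 13) {
  em <- emit_sequences(supers, scaffolds)
  dig <- digest_sequences(em$sequences, enzyme, min_label_distance_bp)
  aln <- align_maps(dig, second_map, params)
  conf <- detect_conflicts(aln, tol)
  if (nrow(conf) > 0L && !is.null(first_alignments)) {
    conf <- arbitrate_conflicts(conf, first_alignments, tol)
  }
  bad <- unique(conf$scaffold_id[is.na(conf$verdict) |
                                   conf$verdict != "map_error"])
  pl <- place_sequences(aln[!aln$query_id %in% bad, , drop = FALSE])
  gaps <- estimate_gaps(pl, min_gap = min_gap)
  lens <- super_lengths(supers)
  super_seqs <- seq_tbl(em$sequences$seq_id, em$sequences$seq)
  merged <- build_superscaffolds(pl, gaps, super_seqs, prefix = "super2")
  # flatten: second-round members are first-round super-scaffolds
  out <- list()
  for (sid in unique(merged$super_id)) {
    mem <- merged[merged$super_id == sid, ]
    mem <- mem[order(mem$member_index), ]
    flat <- list()
    for (i in seq_len(nrow(mem))) {
      sub <- supers[supers$super_id == mem$seq_id[i], ]
      sub <- sub[order(sub$member_index), ]
      if (mem$orientation[i] == "-") {
        sub <- sub[rev(seq_len(nrow(sub))), ]
        sub$orientation <- if_else(sub$orientation == "+", "-", "+")
        # after row reversal the gap vector is (NA, g_{k-1}, ..., g_1);
        # the reversed member j is now followed by gap g_{j-1}
        sub$gap_after_bp <- c(sub$gap_after_bp[-1], NA_real_)
      }
      sub$gap_after_bp[nrow(sub)] <-
        if (i < nrow(mem)) mem$gap_after_bp[i] else NA_real_
      flat[[length(flat) + 1L]] <- sub
    }
    flat <- bind_rows(flat)
    n_first <- length(unique(flat$super_id))
    flat$super_id <- if (n_first > 1L) sid else flat$super_id[1]
    flat$member_index <- seq_len(nrow(flat))
    out[[length(out) + 1L]] <- flat
  }
  res <- bind_rows(out)
  class(res) <- c("optscaf_superscaffolds", setdiff(class(res),
                                                    "optscaf_superscaffolds"))
  attr(res, "conflicts") <- conf
  res
}
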