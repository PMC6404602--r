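#' Tolerances for conflict detection and arbitration
#'
#' Defaults sit comfortably above the default optical sizing noise; none
#' of them is dictated by the mapping chemistry and all are configurable.
#'
#' @param junction_bp Minimum gap between two alignment spans of one
#'   scaffold for them to count as disjoint.
#' @param distance_bp Allowed difference between map distance and
#'   scaffold distance for two placements on one contig to be compatible.
#' @param min_unaligned Minimum run of consecutive unaligned labels (on
#'   one side, inside an alignment) to flag an internal discordance.
#' @param span_bp Minimum bp extent of such a run.
#' @param min_confirm Labels required on each side of a conflict interval
#'   for the second map to confirm the scaffold.
#' @param boundary_bp A scaffold reaching two different map contigs is a
#'   bridge, not a conflict, when each alignment ends within this
#'   distance of its contig boundary on the junction side; a larger
#'   interior overhang means the contig contradicts the scaffold.
#' @return A list of class `conflict_tol`.
#' @export
conflict_tol <- function(junction_bp = 50000, distance_bp = 100000,
                         min_unaligned = 5L, span_bp = 100000,
                         min_confirm = 5L, boundary_bp = 50000) {
  structure(list(junction_bp = junction_bp, distance_bp = distance_bp,
                 min_unaligned = as.integer(min_unaligned), span_bp = span_bp,
                 min_confirm = as.integer(min_confirm),
                 boundary_bp = boundary_bp),
            class = "conflict_tol")
}

conflict_empty <- function() {
  tibble(conflict_id = integer(), scaffold_id = character(),
         map_id = character(), kind = character(),
         scaffold_start = double(), scaffold_end = double(),
         ext_start = double(), ext_end = double(),
         map_start = double(), map_end = double(), verdict = character())
}

#' Detect scaffold-versus-map conflicts
#'
#' Two signals mark a putative mis-join: a *split alignment* (one
#' scaffold holds two retained alignments whose scaffold spans are
#' disjoint by more than `junction_bp` and whose map placements are
#' incompatible: different contigs, discordant orientations, or a
#' map-versus-scaffold distance mismatch above `distance_bp`), and an
#' *internal discordance* (inside one alignment, a run of at least
#' `min_unaligned` consecutive unaligned labels on one side spanning
#' more than `span_bp`, e.g. a repeat copy-number disagreement).  The
#' breakpoint interval is the scaffold interval between the flanking
#' aligned labels.
#'
#' @param alignments Alignment tibble from [align_maps()].
#' @param tol A [conflict_tol()].
#' @return A conflict tibble with `verdict = NA` (set by
#'   [arbitrate_conflicts()]).
#' @export
detect_conflicts <- function(alignments, tol = conflict_tol()) {
  if (nrow(alignments) == 0L) return(conflict_empty())
  out <- list()
  for (sid in unique(alignments$query_id)) {
    al <- alignments[alignments$query_id == sid, ]
    al <- al[order(al$qry_start_bp), ]
    # split alignments
    if (nrow(al) >= 2L) {
      for (a in seq_len(nrow(al) - 1L)) {
        for (b in seq((a + 1L), nrow(al))) {
          # spans must be essentially disjoint: an overlap beyond
          # junction_bp means the two alignments describe one locus
          gap <- al$qry_start_bp[b] - al$qry_end_bp[a]
          if (gap <= -tol$junction_bp) next
          incompatible <- if (al$ref_id[a] != al$ref_id[b]) {
            # a scaffold may genuinely bridge two map contigs; that is a
            # conflict only when a contig continues past the junction
            ja <- if (al$orientation[a] == "+") {
              al$ref_len_bp[a] - al$ref_end_bp[a]
            } else {
              al$ref_start_bp[a] - 1
            }
            jb <- if (al$orientation[b] == "+") {
              al$ref_start_bp[b] - 1
            } else {
              al$ref_len_bp[b] - al$ref_end_bp[b]
            }
            ja > tol$boundary_bp || jb > tol$boundary_bp
          } else {
            al$orientation[a] != al$orientation[b] ||
              {
                map_d <- if (al$orientation[a] == "+") {
                  al$ref_start_bp[b] - al$ref_end_bp[a]
                } else {
                  al$ref_start_bp[a] - al$ref_end_bp[b]
                }
                abs(map_d - gap) > tol$distance_bp
              }
          }
          if (!incompatible) next
          # flanking labels exclusive to each side: a stray label just
          # past the junction that one chain appropriated must not
          # shift the breakpoint bracket off the junction
          pa <- al$pairs[[a]]$q_pos
          pb <- al$pairs[[b]]$q_pos
          left_flank <- if (any(pa < al$qry_start_bp[b])) {
            max(pa[pa < al$qry_start_bp[b]])
          } else al$qry_end_bp[a]
          right_flank <- if (any(pb > al$qry_end_bp[a])) {
            min(pb[pb > al$qry_end_bp[a]])
          } else al$qry_start_bp[b]
          # a chain occasionally appropriates a few stray labels past
          # the true junction when their intervals happen to match, so
          # the breakpoint is localized only to a few label intervals;
          # the extended bracket (up to min_unaligned labels outward)
          # supports arbitration and the split planner
          k_out <- tol$min_unaligned
          ext_left <- if (any(pa < left_flank)) {
            lower <- sort(pa[pa < left_flank], decreasing = TRUE)
            lower[min(k_out, length(lower))]
          } else left_flank
          ext_right <- if (any(pb > right_flank)) {
            upper <- sort(pb[pb > right_flank])
            upper[min(k_out, length(upper))]
          } else right_flank
          out[[length(out) + 1L]] <- tibble(
            scaffold_id = sid, map_id = al$ref_id[a],
            kind = "split_alignment",
            scaffold_start = left_flank,
            scaffold_end = right_flank,
            ext_start = ext_left, ext_end = ext_right,
            map_start = al$ref_end_bp[a], map_end = al$ref_end_bp[a],
            verdict = NA_character_)
        }
      }
    }
    # internal discordances
    for (i in seq_len(nrow(al))) {
      p <- al$pairs[[i]]
      if (is.null(p) || nrow(p) < 2L) next
      r_skip <- diff(p$r_idx) - 1L
      q_skip <- abs(diff(p$q_idx)) - 1L
      r_gap <- diff(p$r_pos)
      q_gap <- abs(diff(p$q_pos))
      bad <- (r_skip >= tol$min_unaligned & r_gap > tol$span_bp) |
             (q_skip >= tol$min_unaligned & q_gap > tol$span_bp)
      for (t in which(bad)) {
        lo <- min(p$q_pos[t], p$q_pos[t + 1L])
        hi <- max(p$q_pos[t], p$q_pos[t + 1L])
        qp <- sort(p$q_pos)
        out[[length(out) + 1L]] <- tibble(
          scaffold_id = sid, map_id = al$ref_id[i],
          kind = "internal_discordance",
          scaffold_start = lo, scaffold_end = hi,
          ext_start = if (any(qp < lo)) max(qp[qp < lo]) else lo,
          ext_end = if (any(qp > hi)) min(qp[qp > hi]) else hi,
          map_start = p$r_pos[t], map_end = p$r_pos[t + 1L],
          verdict = NA_character_)
      }
    }
  }
  if (length(out) == 0L) return(conflict_empty())
  res <- bind_rows(out)
  res <- distinct(res, .data$scaffold_id, .data$kind, .data$scaffold_start,
                  .data$scaffold_end, .keep_all = TRUE)
  mutate(res, conflict_id = row_number(), .before = 1L)
}

#' Arbitrate conflicts with the second, independent optical map
#'
#' A conflict is called a `sequence_error` when the second map also
#' conflicts with the scaffold over an overlapping interval, a
#' `map_error` when the scaffold's second-map alignments run
#' concordantly across the whole conflict interval with at least
#' `min_confirm` aligned labels on each side (one spanning alignment,
#' or a clean bridge over a second-map contig boundary — bridges are
#' not conflicts, so any retained alignment set without an overlapping
#' conflict is concordant), and `unresolved` when the second map lacks
#' the labels to judge.
#'
#' @param conflicts Conflict tibble from [detect_conflicts()] (first map).
#' @param second_alignments Alignment tibble of the same scaffolds
#'   against the second map.
#' @param tol A [conflict_tol()].
#' @return The conflict tibble with `verdict` filled.
#' @export
arbitrate_conflicts <- function(conflicts, second_alignments,
                                tol = conflict_tol()) {
  if (nrow(conflicts) == 0L) return(conflicts)
  second_conf <- detect_conflicts(second_alignments, tol)
  verdict <- character(nrow(conflicts))
  for (i in seq_len(nrow(conflicts))) {
    cf <- conflicts[i, ]
    sc <- second_conf[second_conf$scaffold_id == cf$scaffold_id, ]
    # each bracket is localized only to one label interval per side, so
    # agreement between the two maps is judged on the extended brackets
    cf_lo <- cf$ext_start %||% cf$scaffold_start
    cf_hi <- cf$ext_end %||% cf$scaffold_end
    overlaps <- nrow(sc) > 0L &&
      any(sc$ext_start <= cf_hi & sc$ext_end >= cf_lo)
    if (overlaps) {
      verdict[i] <- "sequence_error"
      next
    }
    al <- second_alignments[second_alignments$query_id == cf$scaffold_id, ]
    q_pos <- unlist(purrr::map(al$pairs, function(p) p$q_pos))
    n_left <- sum(q_pos < cf$scaffold_start)
    n_right <- sum(q_pos > cf$scaffold_end)
    confirmed <- n_left >= tol$min_confirm && n_right >= tol$min_confirm
    verdict[i] <- if (confirmed) "map_error" else "unresolved"
  }
  conflicts$verdict <- verdict
  conflicts
}

#' Plan chimera splits at N runs
#'
#' For each confirmed sequence error the cut goes to the midpoint of the
#' N run nearest to the center of the conflict interval and lying inside
#' it; equidistant runs break toward the lower coordinate.  Overlapping
#' conflict intervals on one scaffold are merged first so a single event
#' never yields two cuts.  A conflict whose interval contains no N run
#' yields no cut (the sequence is never broken blind) and is reported
#' with `cut_pos = NA`.
#'
#' @param conflicts Arbitrated conflict tibble; only rows with verdict
#'   `sequence_error` are acted on.
#' @param n_runs N-run tibble from [find_n_runs()].
#' @return Tibble `scaffold_id`, `cut_pos` (1-based bp; the cut ends the
#'   left piece), `scaffold_start`, `scaffold_end`, `resolved`,
#'   `conflict_ids`.
#' @export
plan_splits <- function(conflicts, n_runs) {
  seq_err <- conflicts[!is.na(conflicts$verdict) &
                         conflicts$verdict == "sequence_error", ]
  if (nrow(seq_err) == 0L) {
    return(tibble(scaffold_id = character(), cut_pos = double(),
                  scaffold_start = double(), scaffold_end = double(),
                  resolved = logical(), conflict_ids = character()))
  }
  out <- list()
  for (sid in unique(seq_err$scaffold_id)) {
    cf <- seq_err[seq_err$scaffold_id == sid, ]
    cf <- cf[order(cf$scaffold_start), ]
    # merge overlapping intervals
    grp <- cumsum(c(1, as.integer(
      cf$scaffold_start[-1] > cummax(cf$scaffold_end)[-nrow(cf)])))
    if (!"ext_start" %in% names(cf)) {
      cf$ext_start <- cf$scaffold_start
      cf$ext_end <- cf$scaffold_end
    }
    merged <- cf |>
      mutate(.grp = grp) |>
      group_by(.data$.grp) |>
      summarise(scaffold_start = min(.data$scaffold_start),
                scaffold_end = max(.data$scaffold_end),
                ext_start = min(.data$ext_start),
                ext_end = max(.data$ext_end),
                conflict_ids = paste(.data$conflict_id, collapse = ","),
                .groups = "drop")
    nr <- n_runs[n_runs$seq_id == sid, ]
    for (i in seq_len(nrow(merged))) {
      lo <- merged$scaffold_start[i]; hi <- merged$scaffold_end[i]
      # runs intersecting the conflict interval (N runs are 0-based)
      cand <- nr[to1based(nr$start) <= hi & nr$end >= lo, ]
      if (nrow(cand) == 0L) {
        # the breakpoint is localized only to +- one label interval:
        # fall back to the extended bracket before giving up
        lo <- merged$ext_start[i]; hi <- merged$ext_end[i]
        cand <- nr[to1based(nr$start) <= hi & nr$end >= lo, ]
      }
      if (nrow(cand) == 0L) {
        out[[length(out) + 1L]] <- tibble(
          scaffold_id = sid, cut_pos = NA_real_, scaffold_start = lo,
          scaffold_end = hi, resolved = FALSE,
          conflict_ids = merged$conflict_ids[i])
        next
      }
      mid <- (cand$start + cand$end + 1) / 2   # midpoint, 1-based bp
      center <- (lo + hi) / 2
      pick <- order(abs(mid - center), mid)[1]  # tie -> lower coordinate
      out[[length(out) + 1L]] <- tibble(
        scaffold_id = sid, cut_pos = floor(mid[pick]), scaffold_start = lo,
        scaffold_end = hi, resolved = TRUE,
        conflict_ids = merged$conflict_ids[i])
    }
  }
  bind_rows(out)
}

#' Split scaffolds at planned cut positions
#'
#' A cut at position `p` ends the left piece at base `p` (N bases at the
#' cut are apportioned to the left piece up to the cut position); `k`
#' cuts in one record yield `k + 1` pieces named `<id>_1 ... <id>_k+1`.
#' The record count grows by exactly the number of cuts and the multiset
#' of non-N bases is conserved.
#'
#' @param scaffolds A sequence tibble (the assembly ledger).  A
#'   lengths-only ledger is accepted; pieces then carry `NA` sequence.
#' @param plans Tibble from [plan_splits()]; rows with `NA` `cut_pos`
#'   are ignored.
#' @return List with `scaffolds` (new ledger) and `provenance` (tibble
#'   `old_id`, `new_id`, `piece`, `start`, `end`, 1-based inclusive on
#'   the old record).
#' @export
apply_splits <- function(scaffolds, plans) {
  assert_seq_tbl(scaffolds, need_seq = FALSE)
  plans <- plans[!is.na(plans$cut_pos), , drop = FALSE]
  if (nrow(plans) > 0L) {
    len <- scaffolds$length_bp[match(plans$scaffold_id, scaffolds$seq_id)]
    if (anyNA(len)) {
      abort(sprintf("split plan for unknown scaffold %s",
                    plans$scaffold_id[which(is.na(len))[1]]))
    }
    if (any(plans$cut_pos < 1 | plans$cut_pos >= len)) {
      abort("cut position outside sequence")
    }
  }
  cut_ids <- unique(plans$scaffold_id)
  keep <- scaffolds[!scaffolds$seq_id %in% cut_ids, , drop = FALSE]
  prov_keep <- tibble(old_id = keep$seq_id, new_id = keep$seq_id,
                      piece = 1L, start = 1, end = keep$length_bp)
  pieces <- purrr::map(cut_ids, function(sid) {
    rec <- scaffolds[scaffolds$seq_id == sid, ]
    cuts <- sort(unique(plans$cut_pos[plans$scaffold_id == sid]))
    bounds <- c(0, cuts, rec$length_bp)
    starts <- bounds[-length(bounds)] + 1
    ends <- bounds[-1]
    segs <- if (is.na(rec$seq)) rep(NA_character_, length(starts)) else
      substring(rec$seq, starts, ends)
    tibble(old_id = sid,
           new_id = paste0(sid, "_", seq_along(starts)),
           piece = seq_along(starts), start = starts, end = ends,
           seq = segs)
  })
  pieces <- bind_rows(pieces)
  if (nrow(pieces) == 0L) {
    pieces <- tibble(old_id = character(), new_id = character(),
                     piece = integer(), start = double(), end = double(),
                     seq = character())
  }
  new_sc <- bind_rows(
    keep,
    if (nrow(pieces) > 0L) {
      seq_tbl(pieces$new_id, pieces$seq, pieces$end - pieces$start + 1)
    }
  )
  prov <- bind_rows(prov_keep,
                    select(pieces, "old_id", "new_id", "piece", "start", "end"))
  list(scaffolds = new_sc, provenance = prov)
}

#' Lift marker hits through split provenance
#'
#' Rewrites `scaffold_id`/`pos` of a marker table onto the post-split
#' record containing each position.
#'
#' @param markers Tibble with columns `scaffold_id` and `pos`.
#' @param provenance Provenance tibble from [apply_splits()].
#' @return The marker tibble with updated coordinates.
#' @export
lift_markers <- function(markers, provenance) {
  j <- inner_join(markers, provenance,
                  by = c(scaffold_id = "old_id"),
                  relationship = "many-to-many") |>
    filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    mutate(scaffold_id = .data$new_id, pos = .data$pos - .data$start + 1) |>
    select(-"new_id", -"piece", -"start", -"end")
  j
}
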