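# Scoring a pipeline run against simulator ground truth.

# map each original scaffold id to the final (post-split) record that
# contains its starting base
final_id_map <- function(hosts, provenance) {
  j <- inner_join(hosts, provenance, by = c(host_id = "old_id"),
                  relationship = "many-to-many")
  j <- j[j$offset_bp + 1 >= j$start & j$offset_bp + 1 <= j$end, ]
  tibble(orig_id = j$orig_id, final_id = j$new_id,
         # base shift of the original scaffold inside the final record
         shift = j$offset_bp - (j$start - 1))
}

edge_n <- function(seq, side = c("left", "right")) {
  side <- match.arg(side)
  pat <- if (side == "left") "^N+" else "N+$"
  m <- regmatches(seq, regexpr(pat, seq))
  if (length(m) == 0L) 0L else nchar(m)
}

#' Score a pipeline run against simulation ground truth
#'
#' Compares the output of [run_pipeline()] (run on simulated inputs, so
#' `$sim` carries ground truth) with the injected truth: chimera
#' detection recall and false positives, placement/order/orientation
#' recovery of the super-scaffold layout, gap-size accuracy, and
#' pseudomolecule length recovery.
#'
#' @param res Result of [run_pipeline()] with a non-`NULL` `$sim`.
#' @return One-row tibble of recovery metrics.
#' @export
evaluate_recovery <- function(res) {
  sim <- res$sim
  if (is.null(sim)) abort("evaluate_recovery() needs a simulated run")
  truth <- sim$truth
  chim <- truth$chimeras$seq_id

  conf <- res$conflicts
  detected <- unique(conf$scaffold_id[is.na(conf$verdict) |
                                        conf$verdict != "map_error"])
  chimera_recall <- if (length(chim)) mean(chim %in% detected) else NA_real_
  false_conflicts <- sum(!detected %in% chim)

  idmap <- final_id_map(truth$hosts, res$provenance)
  tr <- truth$placements
  tr$final_id <- idmap$final_id[match(tr$seq_id, idmap$orig_id)]

  # flatten the final super-scaffolds and judge them against the truth
  ss <- as_tibble(res$supers)
  multi <- ss |>
    group_by(.data$super_id) |>
    filter(n() > 1L) |>
    arrange(.data$member_index, .by_group = TRUE) |>
    ungroup()
  j <- inner_join(multi, tr, by = c(seq_id = "final_id"),
                  suffix = c("", ".tr"))
  placement_rate <- nrow(j) / nrow(tr)
  orientation_accuracy <- mean(j$orientation == j$orientation.tr)
  # order: longest increasing run of true chromosome positions per super
  order_accuracy <- if (nrow(j)) {
    ok <- 0L
    for (sid in unique(j$super_id)) {
      m <- j[j$super_id == sid, ]
      x <- m$start
      if (nrow(m) >= 2L && stats::cor(seq_len(nrow(m)), x,
                                      method = "spearman") < 0) {
        x <- rev(x)   # a super-scaffold may legitimately be mirrored
      }
      ok <- ok + length(lis_members(x))
    }
    ok / nrow(j)
  } else NA_real_

  # gap accuracy on round-one estimates: expected gap = true gap minus
  # the N overhangs that splitting apportioned to the piece edges
  tr_adj <- tr |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(right_final = lead(.data$final_id)) |>
    ungroup() |>
    filter(!is.na(.data$right_final))
  g <- inner_join(res$gaps, tr_adj,
                  by = c(left_id = "final_id", right_id = "right_final"))
  gap_err <- if (nrow(g)) {
    sc <- res$scaffolds
    left_seq <- sc$seq[match(g$left_id, sc$seq_id)]
    right_seq <- sc$seq[match(g$right_id, sc$seq_id)]
    left_or <- res$placements$orientation[match(g$left_id,
                                                res$placements$seq_id)]
    # overhang at the junction-facing end, in oriented coordinates
    tailN <- purrr::map2_int(left_seq, left_or, function(s, o) {
      edge_n(s, if (o == "+") "right" else "left")
    })
    headN <- purrr::map2_int(right_seq,
                             res$placements$orientation[
                               match(g$right_id, res$placements$seq_id)],
                             function(s, o) {
                               edge_n(s, if (o == "+") "left" else "right")
                             })
    abs(g$gap_bp - (g$gap_after_bp - tailN - headN))
  } else NA_real_

  # the recoverable extent of a chromosome is the span its scaffolds
  # cover (terminal fragments below the minimum scaffold size are not
  # sequenced and no method can restore them)
  span <- truth$placements |>
    group_by(.data$chrom) |>
    summarise(span_bp = max(.data$end) - min(.data$start) + 1,
              .groups = "drop")
  ps_len <- res$pseudo$sequences$length_bp
  true_len <- span$span_bp[
    match(sub("^Chr", "", res$pseudo$sequences$seq_id), span$chrom)]

  tibble(
    chimera_recall = chimera_recall,
    false_conflicts = as.double(false_conflicts),
    placement_rate = placement_rate,
    order_accuracy = order_accuracy,
    orientation_accuracy = orientation_accuracy,
    n_gaps_scored = nrow(g),
    gap_exact_rate = mean(gap_err == 0),
    gap_mean_abs_err = mean(gap_err),
    pseudo_length_max_rel_err =
      max(abs(ps_len - true_len) / true_len)
  )
}
#' Flatten an anchored assembly to the original scaffold level
#'
#' Expands each anchored super-scaffold of a pipeline run into its
#' member scaffolds (applying the super-scaffold's own orientation) and
#' maps split pieces back to the original scaffold identifiers, giving
#' a per-scaffold placement table directly comparable with a prior
#' assembly via [compare_assemblies()].
#'
#' @param res Result of [run_pipeline()] with a non-`NULL` `$sim`.
#' @return An ordered placement tibble (`chrom`, `position_index`,
#'   `super_id` holding the original scaffold id, `orientation`,
#'   `length_bp`, ...).
#' @export
scaffold_level_layout <- function(res) {
  idmap <- final_id_map(res$sim$truth$hosts, res$provenance)
  anch <- res$pseudo$anchored
  ss <- as_tibble(res$supers)
  rows <- list()
  for (i in seq_len(nrow(anch))) {
    mem <- ss[ss$super_id == anch$super_id[i], ]
    mem <- mem[order(mem$member_index), ]
    if (anch$orientation[i] == "-") {
      mem <- mem[rev(seq_len(nrow(mem))), ]
      mem$orientation <- if_else(mem$orientation == "+", "-", "+")
    }
    rows[[length(rows) + 1L]] <- tibble(
      chrom = anch$chrom[i], seq_id = mem$seq_id,
      orientation = mem$orientation, length_bp = mem$length_bp)
  }
  flat <- bind_rows(rows)
  flat$orig_id <- idmap$orig_id[match(flat$seq_id, idmap$final_id)]
  flat <- flat[!is.na(flat$orig_id), ]
  flat |>
    group_by(.data$chrom) |>
    mutate(position_index = row_number()) |>
    ungroup() |>
    mutate(super_id = .data$orig_id, orientation_determined = TRUE,
           mean_cm = as.double(.data$position_index), n_markers = 2L) |>
    select("chrom", "position_index", "super_id", "orientation",
           "orientation_determined", "mean_cm", "n_markers", "length_bp")
}
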