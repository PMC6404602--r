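# Chromosome anchoring with genetic-map markers, pseudomolecule
# construction, and the accounting tables.

#' Canonical chromosome order
#'
#' Chromosomes are reported in the fixed order 1A..7A, 1B..7B; simulated
#' genomes with fewer chromosomes use a prefix of this list.
#'
#' @param n Number of chromosomes (defaults to all 14).
#' @return Character vector of chromosome names.
#' @export
chromosome_levels <- function(n = 14L) {
  lv <- c(paste0(1:7, "A"), paste0(1:7, "B"))
  lv[seq_len(n)]
}

#' Merge marker tables from multiple linkage maps
#'
#' Markers are combined by union; a marker claiming two different
#' chromosomes across maps is dropped (conservative).
#'
#' @param ... Marker tibbles (`marker_id`, `chrom`, `cm`, `scaffold_id`,
#'   `pos`).
#' @return A single marker tibble.
#' @export
merge_marker_maps <- function(...) {
  mk <- bind_rows(...)
  bad <- mk |>
    distinct(.data$marker_id, .data$chrom) |>
    count(.data$marker_id) |>
    filter(.data$n > 1L) |>
    pull(.data$marker_id)
  filter(mk, !.data$marker_id %in% bad)
}

#' Assign super-scaffolds to chromosomes by marker majority
#'
#' A super-scaffold is assigned to the chromosome contributing the
#' majority of its markers, provided that chromosome supplies at least
#' `min_markers` (default 2, the two-or-more-SNP rule); majority ties go
#' unassigned.  Minority markers are logged as discordant.
#'
#' @param markers Marker tibble with `scaffold_id` resolvable against
#'   the super-scaffold members (lift split markers with
#'   [lift_markers()] first).
#' @param supers Super-scaffold tibble from [build_superscaffolds()].
#' @param min_markers Markers required on the winning chromosome.
#' @return Tibble `super_id`, `chrom` (`NA` when unassigned),
#'   `n_markers`, `n_discordant`, `mean_cm`.
#' @export
assign_chromosomes <- function(markers, supers, min_markers = 2L) {
  mem <- select(as_tibble(supers), "super_id", "seq_id")
  mk <- inner_join(markers, mem, by = c(scaffold_id = "seq_id"))
  per <- mk |>
    count(.data$super_id, .data$chrom, name = "n_chr")
  out <- purrr::map(unique(per$super_id), function(sid) {
    p <- per[per$super_id == sid, ]
    tot <- sum(p$n_chr)
    top <- max(p$n_chr)
    winners <- p$chrom[p$n_chr == top]
    ok <- length(winners) == 1L && top >= min_markers
    chrom <- if (ok) winners else NA_character_
    mean_cm <- if (ok) {
      mean(mk$cm[mk$super_id == sid & mk$chrom == chrom])
    } else NA_real_
    tibble(super_id = sid, chrom = chrom,
           n_markers = if (ok) top else 0L,
           n_discordant = if (ok) tot - top else tot,
           mean_cm = mean_cm)
  })
  res <- bind_rows(out)
  all_supers <- unique(supers$super_id)
  missing <- setdiff(all_supers, res$super_id)
  if (length(missing)) {
    res <- bind_rows(res, tibble(super_id = missing, chrom = NA_character_,
                                 n_markers = 0L, n_discordant = 0L,
                                 mean_cm = NA_real_))
  }
  arrange(res, .data$super_id)
}

# marker position within the emitted super-scaffold sequence
marker_super_positions <- function(markers, supers, unknown_gap_n = 100) {
  mem <- as_tibble(supers) |>
    group_by(.data$super_id) |>
    arrange(.data$member_index, .by_group = TRUE) |>
    mutate(gap_len = if_else(is.na(.data$gap_after_bp), 0,
                             if_else(.data$gap_after_bp < 0,
                                     as.double(unknown_gap_n),
                                     .data$gap_after_bp)),
           offset = cumsum(lag(.data$length_bp + .data$gap_len,
                               default = 0))) |>
    ungroup() |>
    select("super_id", "seq_id", "orientation", "length_bp", "offset")
  inner_join(markers, mem, by = c(scaffold_id = "seq_id")) |>
    mutate(pos_super = if_else(.data$orientation == "+",
                               .data$offset + .data$pos,
                               .data$offset + .data$length_bp - .data$pos + 1))
}

#' Order and orient anchored super-scaffolds along each chromosome
#'
#' Order is by mean centimorgan of each super-scaffold's concordant
#' markers (ties broken by length, longer first, then lexicographic id).
#' Orientation is the sign of the rank correlation between marker cM and
#' bp position, computed only when at least two distinct cM values
#' exist; degenerate cases are recorded as `+` with
#' `orientation_determined = FALSE`.
#'
#' @param assignments Tibble from [assign_chromosomes()].
#' @param markers Marker tibble.
#' @param supers Super-scaffold tibble (for marker coordinates and
#'   lengths).
#' @return Tibble `chrom`, `position_index`, `super_id`, `orientation`,
#'   `orientation_determined`, `mean_cm`, `n_markers`, `length_bp`.
#' @export
order_and_orient <- function(assignments, markers, supers) {
  lens <- super_lengths(supers)
  mk <- marker_super_positions(markers, supers)
  anchored <- filter(assignments, !is.na(.data$chrom))
  rows <- purrr::map(seq_len(nrow(anchored)), function(i) {
    a <- anchored[i, ]
    m <- mk[mk$super_id == a$super_id & mk$chrom == a$chrom, ]
    orient <- "+"; determined <- FALSE
    if (nrow(m) >= 2L && length(unique(m$cm)) >= 2L &&
        length(unique(m$pos_super)) >= 2L) {
      rho <- suppressWarnings(cor(m$cm, m$pos_super, method = "spearman"))
      if (!is.na(rho) && rho != 0) {
        orient <- if (rho > 0) "+" else "-"
        determined <- TRUE
      }
    }
    tibble(chrom = a$chrom, super_id = a$super_id, orientation = orient,
           orientation_determined = determined, mean_cm = a$mean_cm,
           n_markers = a$n_markers,
           length_bp = lens$length_bp[match(a$super_id, lens$super_id)])
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0L) {
    return(tibble(chrom = character(), position_index = integer(),
                  super_id = character(), orientation = character(),
                  orientation_determined = logical(), mean_cm = double(),
                  n_markers = integer(), length_bp = double()))
  }
  res |>
    mutate(chrom = factor(.data$chrom, levels = chromosome_levels())) |>
    arrange(.data$chrom, .data$mean_cm, desc(.data$length_bp),
            .data$super_id) |>
    group_by(.data$chrom) |>
    mutate(position_index = row_number()) |>
    ungroup() |>
    mutate(chrom = as.character(.data$chrom)) |>
    select("chrom", "position_index", "super_id", "orientation",
           "orientation_determined", "mean_cm", "n_markers", "length_bp")
}

#' Build chromosome pseudomolecules
#'
#' Anchored super-scaffolds are concatenated in order and orientation,
#' linked with `gap_n` Ns (gaps of unknown length, AGP `U` rows with
#' linkage evidence `map`).  With S anchored scaffolds over C
#' chromosomes the unknown-length joins total S - C.  Unanchored
#' scaffolds stay separate records in ChrUn (never concatenated).
#'
#' @param ordered Tibble from [order_and_orient()].
#' @param sequences Sequence tibble of the super-scaffolds (lengths-only
#'   accepted: length arithmetic and AGP are still produced, sequences
#'   are `NA`).
#' @param gap_n Number of Ns in each inter-scaffold join.
#' @return A `pseudomolecule_set`: list with `sequences` (chromosome
#'   records named `Chr<chrom>`), `agp`, `anchored`, `chrun`, `ledger`.
#' @export
build_pseudomolecules <- function(ordered, sequences, gap_n = 1000) {
  assert_seq_tbl(sequences, need_seq = FALSE)
  has_seq <- !any(is.na(sequences$seq))
  chroms <- unique(ordered$chrom)
  chroms <- chroms[order(match(chroms, chromosome_levels()))]
  seq_rows <- list(); agp_rows <- list()
  for (ch in chroms) {
    mem <- ordered[ordered$chrom == ch, ]
    mem <- mem[order(mem$position_index), ]
    obj <- paste0("Chr", ch)
    idx <- match(mem$super_id, sequences$seq_id)
    if (anyNA(idx)) {
      abort(sprintf("anchored scaffold %s has no sequence record",
                    mem$super_id[which(is.na(idx))[1]]))
    }
    k <- nrow(mem)
    len <- sequences$length_bp[idx]
    w_beg <- cumsum(c(0, head(len, -1) + gap_n)) + 1
    w_end <- w_beg + len - 1
    w_rows <- tibble(object = obj, object_beg = w_beg, object_end = w_end,
                     part_number = 2L * seq_len(k) - 1L,
                     component_type = "W", component_id = mem$super_id,
                     component_beg = "1", component_end = as.character(len),
                     orientation = mem$orientation)
    u_rows <- if (k > 1L) {
      tibble(object = obj, object_beg = w_end[-k] + 1,
             object_end = w_end[-k] + gap_n,
             part_number = 2L * seq_len(k - 1L),
             component_type = "U", component_id = as.character(gap_n),
             component_beg = "contig", component_end = "yes",
             orientation = "map")
    }
    agp_rows[[length(agp_rows) + 1L]] <-
      arrange(bind_rows(w_rows, u_rows), .data$part_number)
    total <- w_end[k]
    s <- NA_character_
    if (has_seq) {
      pieces <- sequences$seq[idx]
      flip <- mem$orientation == "-"
      pieces[flip] <- revcomp(pieces[flip])
      joiner <- strrep("N", gap_n)
      s <- paste(pieces, collapse = joiner)
    }
    seq_rows[[length(seq_rows) + 1L]] <- tibble(
      seq_id = obj, seq = s, length_bp = total)
  }
  sq <- bind_rows(seq_rows)
  chrun <- sequences[!sequences$seq_id %in% ordered$super_id, c("seq_id", "length_bp")]
  structure(
    list(sequences = seq_tbl(sq$seq_id, sq$seq, sq$length_bp),
         agp = bind_rows(agp_rows),
         anchored = ordered,
         chrun = as_tibble(chrun),
         ledger = NULL,
         gap_n = gap_n),
    class = "pseudomolecule_set")
}

#' @export
print.pseudomolecule_set <- function(x, ...) {
  cat(sprintf("<pseudomolecule_set> %d chromosomes, %d anchored scaffolds, %d ChrUn\n",
              nrow(x$sequences), nrow(x$anchored), nrow(x$chrun)))
  cat(sprintf("  total length %.0f bp; %d gaps of unknown length\n",
              sum(x$sequences$length_bp),
              nrow(x$anchored) - length(unique(x$anchored$chrom))))
  invisible(x)
}

#' Count annotated genes per chromosome
#'
#' Counts the genes whose host scaffold landed on each chromosome; genes
#' on ChrUn scaffolds are counted separately and totals are additive.
#'
#' @param genes Tibble `gene_id`, `scaffold_id` (one row per gene).
#' @param pseudo A `pseudomolecule_set`.
#' @return Tibble `chrom`, `n_genes` with a `ChrUn` row and an attached
#'   `total` attribute (genes on pseudomolecules, ChrUn excluded).
#' @export
gene_accounting <- function(genes, pseudo) {
  stopifnot(inherits(pseudo, "pseudomolecule_set"))
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("duplicate gene id: %s",
                  genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  host <- bind_rows(
    tibble(scaffold_id = pseudo$anchored$super_id,
           chrom = paste0("Chr", pseudo$anchored$chrom)),
    tibble(scaffold_id = pseudo$chrun$seq_id, chrom = "ChrUn"))
  unknown <- setdiff(genes$scaffold_id, host$scaffold_id)
  if (length(unknown)) {
    abort(sprintf("gene mapped to unknown scaffold: %s", unknown[1]))
  }
  lv <- c(paste0("Chr", chromosome_levels()), "ChrUn")
  counts <- genes |>
    inner_join(host, by = "scaffold_id") |>
    count(.data$chrom, name = "n_genes")
  out <- tibble(chrom = lv) |>
    left_join(counts, by = "chrom") |>
    mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L)) |>
    filter(.data$chrom %in% c(counts$chrom, paste0("Chr", unique(pseudo$anchored$chrom)), "ChrUn"))
  attr(out, "total") <- sum(out$n_genes[out$chrom != "ChrUn"])
  out
}

# indices of a longest strictly increasing subsequence (O(n^2); the
# per-chromosome scaffold counts here are small)
lis_members <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  out <- integer(0)
  while (i > 0L) {
    out <- c(i, out)
    i <- prev[i]
  }
  out
}

#' Compare a pseudomolecule set against a prior placement table
#'
#' Classifies every scaffold relative to the old assembly: `rescued`
#' (previously ChrUn, now anchored), `relocated` (different chromosome,
#' or out of order relative to the scaffolds around it), `reoriented`
#' (same location, flipped), `unchanged`.  "Out of order" means not on
#' the longest increasing subsequence of the old-versus-new order
#' mapping, so a scaffold that merely lost a moved neighbor is not
#' itself flagged.  A scaffold anchored before but unplaced now counts
#' as `relocated`.
#'
#' @param pseudo A `pseudomolecule_set`.
#' @param old Tibble `seq_id`, `chrom` (`"ChrUn"` for unplaced),
#'   `position_index`, `orientation`.
#' @return List with `per_scaffold` (tibble `seq_id`, `class`,
#'   `length_bp`) and `summary` (class counts and total bp).
#' @export
compare_assemblies <- function(pseudo, old) {
  stopifnot(inherits(pseudo, "pseudomolecule_set"))
  new_tbl <- bind_rows(
    tibble(seq_id = pseudo$anchored$super_id, chrom = pseudo$anchored$chrom,
           position_index = pseudo$anchored$position_index,
           orientation = pseudo$anchored$orientation,
           length_bp = pseudo$anchored$length_bp),
    tibble(seq_id = pseudo$chrun$seq_id, chrom = "ChrUn",
           position_index = NA_integer_, orientation = "+",
           length_bp = pseudo$chrun$length_bp))
  old <- mutate(old, seq_id = as.character(.data$seq_id))
  shared <- intersect(new_tbl$seq_id, old$seq_id)
  nw <- new_tbl[match(shared, new_tbl$seq_id), ]
  ol <- old[match(shared, old$seq_id), ]
  cls <- rep("relocated", length(shared))
  same_chrom <- nw$chrom == ol$chrom
  cls[ol$chrom == "ChrUn" & nw$chrom != "ChrUn"] <- "rescued"
  cls[same_chrom & nw$chrom == "ChrUn"] <- "unchanged"
  # per chromosome, scaffolds on the LIS of the order mapping kept place
  for (ch in setdiff(unique(nw$chrom[same_chrom]), "ChrUn")) {
    idx <- which(same_chrom & nw$chrom == ch)
    idx <- idx[order(ol$position_index[idx])]
    on_lis <- idx[lis_members(nw$position_index[idx])]
    cls[on_lis] <- if_else(nw$orientation[on_lis] == ol$orientation[on_lis],
                           "unchanged", "reoriented")
  }
  per <- tibble(seq_id = shared, class = cls, length_bp = nw$length_bp)
  summary <- per |>
    group_by(.data$class) |>
    summarise(n = n(), total_bp = sum(.data$length_bp), .groups = "drop")
  list(per_scaffold = per, summary = summary)
}

#' Per-chromosome length, effective length, N% and unknown-gap report
#'
#' `N%` is `100 * (length - effective) / length` rounded to two
#' decimals; the totals row is recomputed from the column sums.
#'
#' @param x A `pseudomolecule_set`, or a data frame with columns
#'   `chrom`, `length_bp` and `effective_bp`.
#' @param ... Unused.
#' @return Tibble `chrom`, `length_bp`, `effective_bp`, `n_pct` (and
#'   `n_unknown_gaps` for a pseudomolecule set) with a final `Total`
#'   row.
#' @export
report_tables <- function(x, ...) UseMethod("report_tables")

#' @export
report_tables.pseudomolecule_set <- function(x, ...) {
  seqs <- x$sequences
  n_known <- if (!any(is.na(seqs$seq))) {
    count_n(seqs$seq)
  } else {
    # lengths-only mode: joins contribute gap_n Ns each
    joins <- x$agp |>
      filter(.data$component_type %in% c("N", "U")) |>
      group_by(.data$object) |>
      summarise(nb = sum(as.double(.data$component_id)), .groups = "drop")
    dplyr::coalesce(joins$nb[match(seqs$seq_id, joins$object)], 0)
  }
  gaps <- x$agp |>
    filter(.data$component_type == "U") |>
    count(.data$object, name = "n_unknown_gaps")
  tab <- tibble(chrom = seqs$seq_id, length_bp = seqs$length_bp,
                effective_bp = seqs$length_bp - n_known,
                n_unknown_gaps = dplyr::coalesce(
                  gaps$n_unknown_gaps[match(seqs$seq_id, gaps$object)], 0L))
  finish_report(tab)
}

#' @export
report_tables.data.frame <- function(x, ...) {
  stopifnot(all(c("chrom", "length_bp", "effective_bp") %in% names(x)))
  finish_report(as_tibble(x))
}

finish_report <- function(tab) {
  tab$n_pct <- round(100 * (tab$length_bp - tab$effective_bp) / tab$length_bp, 2)
  tot <- tibble(chrom = "Total", length_bp = sum(tab$length_bp),
                effective_bp = sum(tab$effective_bp))
  tot$n_pct <- round(100 * (tot$length_bp - tot$effective_bp) / tot$length_bp, 2)
  if ("n_unknown_gaps" %in% names(tab)) {
    tot$n_unknown_gaps <- sum(tab$n_unknown_gaps)
  }
  bind_rows(tab, tot)
}
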