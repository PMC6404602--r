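# Chromosome assignment, ordering/orientation, pseudomolecule assembly,
# gene accounting and the comparison ledger.

mk_supers <- function(ids, lengths) {
  out <- tibble::tibble(super_id = ids, member_index = 1L, seq_id = ids,
                        orientation = "+", gap_after_bp = NA_real_,
                        length_bp = lengths, map_id = NA_character_)
  class(out) <- c("optscaf_superscaffolds", class(out))
  out
}

test_that("chromosome assignment follows the two-or-more-marker rule", {
  supers <- mk_supers(c("s1", "s2", "s3"), c(1e5, 1e5, 1e5))
  mk <- tibble::tibble(
    marker_id = paste0("m", 1:9),
    chrom = c("2A", rep("2A", 5), "3B", "1A", "1A"),
    cm = 1:9,
    scaffold_id = c("s1", rep("s2", 5), "s2", "s3", "s3"),
    pos = rep(10, 9))
  asg <- assign_chromosomes(mk, supers)
  expect_true(is.na(asg$chrom[asg$super_id == "s1"]))   # single marker
  expect_identical(asg$chrom[asg$super_id == "s2"], "2A")  # 5 vs 1 majority
  expect_identical(asg$n_discordant[asg$super_id == "s2"], 1L)
  expect_identical(asg$chrom[asg$super_id == "s3"], "1A")

  # majority tie goes unassigned
  tie <- tibble::tibble(marker_id = paste0("t", 1:4), chrom = c("1A", "1A", "2B", "2B"),
                        cm = 1:4, scaffold_id = "s1", pos = 10)
  asg2 <- assign_chromosomes(tie, supers)
  expect_true(is.na(asg2$chrom[asg2$super_id == "s1"]))
})

test_that("orientation follows the cM-versus-bp rank correlation", {
  supers <- mk_supers(c("up", "down", "flat"), rep(2e5, 3))
  mk <- dplyr::bind_rows(
    tibble::tibble(marker_id = paste0("u", 1:3), chrom = "1A",
                   cm = c(1, 2, 3), scaffold_id = "up",
                   pos = c(1e4, 5e4, 9e4)),
    tibble::tibble(marker_id = paste0("d", 1:3), chrom = "1A",
                   cm = c(4, 5, 6), scaffold_id = "down",
                   pos = c(9e4, 5e4, 1e4)),
    tibble::tibble(marker_id = paste0("f", 1:2), chrom = "1A",
                   cm = c(7, 7), scaffold_id = "flat",
                   pos = c(1e4, 9e4)))
  ord <- order_and_orient(assign_chromosomes(mk, supers), mk, supers)
  expect_identical(ord$orientation[ord$super_id == "up"], "+")
  expect_identical(ord$orientation[ord$super_id == "down"], "-")
  # all markers at one cM: undetermined, recorded as + with a flag
  expect_identical(ord$orientation[ord$super_id == "flat"], "+")
  expect_false(ord$orientation_determined[ord$super_id == "flat"])
  # ordering by mean cM
  expect_identical(ord$super_id[order(ord$position_index)],
                   c("up", "down", "flat"))
})

test_that("zero-noise marker simulation recovers assignment, order and orientation", {
  sim <- small_sim(seed = 57, n_chimeras = 0L, n_chromosomes = 2L,
                   chromosome_length_bp = 4e6, scaffold_break_rate = 3)
  # anchor the raw scaffolds directly (no optical scaffolding step)
  supers <- mk_supers(sim$scaffolds$seq_id, sim$scaffolds$length_bp)
  asg <- assign_chromosomes(sim$markers, supers)
  tr <- sim$truth$placements
  got <- asg[!is.na(asg$chrom), ]
  expect_identical(got$chrom, tr$chrom[match(got$super_id, tr$seq_id)])
  ord <- order_and_orient(asg, sim$markers, supers)
  for (ch in unique(ord$chrom)) {
    mem <- ord[ord$chrom == ch, ]
    mem <- mem[order(mem$position_index), ]
    want <- tr[tr$seq_id %in% mem$super_id & tr$chrom == ch, ]
    want <- want[order(want$start), ]
    # order is recoverable only between scaffolds with distinct mean cM
    # (markers on one cM plateau carry no order information); every
    # distinct-cM pair must be ordered as in the truth
    rank_true <- match(mem$super_id, want$seq_id)
    for (a in seq_len(nrow(mem) - 1L)) {
      for (b in seq(a + 1L, nrow(mem))) {
        if (mem$mean_cm[a] != mem$mean_cm[b]) {
          expect_lt(rank_true[a], rank_true[b])
        }
      }
    }
    det <- mem$orientation_determined
    expect_identical(mem$orientation[det],
                     want$orientation[match(mem$super_id[det], want$seq_id)])
  }
})

test_that("pseudomolecule join arithmetic holds at full assembly scale", {
  # 485 anchored scaffolds totalling 10,330,081,199 bp over 14 chromosomes
  n <- 485L
  total <- 10330081199
  lens <- rep(floor(total / n), n)
  lens[1] <- lens[1] + total - sum(lens)
  ids <- sprintf("anch%03d", seq_len(n))
  chroms <- rep(chromosome_levels(14L), length.out = n)
  ordered <- tibble::tibble(chrom = chroms, super_id = ids,
                            orientation = "+",
                            orientation_determined = TRUE,
                            mean_cm = seq_len(n), n_markers = 2L,
                            length_bp = lens) |>
    dplyr::group_by(chrom) |>
    dplyr::mutate(position_index = dplyr::row_number()) |>
    dplyr::ungroup()
  seqs <- seq_tbl(ids, NA, length_bp = lens)
  ps <- build_pseudomolecules(ordered, seqs, gap_n = 1000)
  expect_identical(sum(ps$sequences$length_bp), 10330552199)
  rep <- report_tables(ps)
  expect_identical(rep$n_unknown_gaps[rep$chrom == "Total"], 471L)

  # one scaffold per chromosome: zero joins, length preserved
  one <- ordered |> dplyr::distinct(chrom, .keep_all = TRUE) |>
    dplyr::mutate(position_index = 1L)
  ps1 <- build_pseudomolecules(one, seqs)
  expect_identical(sum(ps1$sequences$length_bp), sum(one$length_bp))
  rep1 <- report_tables(ps1)
  expect_identical(rep1$n_unknown_gaps[rep1$chrom == "Total"], 0L)
})

test_that("AGP round-trip rebuilds pseudomolecule sequences bit-exactly", {
  set.seed(67)
  ids <- paste0("s", 1:6)
  seqs <- seq_tbl(ids, vapply(sample(500:2000, 6), random_seq, ""))
  ordered <- tibble::tibble(
    chrom = c("1A", "1A", "1A", "2B", "2B", "3A"),
    position_index = c(1:3, 1:2, 1L), super_id = ids,
    orientation = c("+", "-", "+", "-", "+", "+"),
    orientation_determined = TRUE, mean_cm = 1:6, n_markers = 2L,
    length_bp = seqs$length_bp)
  ps <- build_pseudomolecules(ordered, seqs, gap_n = 1000)
  rebuilt <- build_from_agp(ps$agp, seqs)
  expect_identical(rebuilt$seq, ps$sequences$seq)
})

test_that("gene accounting is additive and rescues count toward the total", {
  # 62,813 genes on scaffolds anchored in both assemblies plus 2,179 on
  # rescued scaffolds -> 64,992 on the pseudomolecules
  n_old <- 62813L
  n_rescued <- 2179L
  anch <- sprintf("a%02d", 1:28)
  ordered <- tibble::tibble(
    chrom = rep(chromosome_levels(14L), 2),
    super_id = anch, orientation = "+", orientation_determined = TRUE,
    mean_cm = 1:28, n_markers = 2L, length_bp = 1e6) |>
    dplyr::group_by(chrom) |>
    dplyr::mutate(position_index = dplyr::row_number()) |>
    dplyr::ungroup()
  seqs <- seq_tbl(c(anch, "un1"), NA, length_bp = rep(1e6, 29))
  ps <- build_pseudomolecules(ordered, seqs)
  # first 14 scaffolds were placed before; the second 14 are rescued
  genes <- tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n_old + n_rescued + 10L)),
    scaffold_id = c(rep(anch[1:14], length.out = n_old),
                    rep(anch[15:28], length.out = n_rescued),
                    rep("un1", 10L)))
  acc <- gene_accounting(genes, ps)
  expect_identical(attr(acc, "total"), 64992L)
  expect_identical(acc$n_genes[acc$chrom == "ChrUn"], 10L)
  expect_identical(sum(acc$n_genes), n_old + n_rescued + 10L)

  expect_identical(attr(gene_accounting(genes[0, ], ps), "total"), 0L)
  expect_error(gene_accounting(dplyr::bind_rows(genes[1, ], genes[1, ]), ps),
               "duplicate")
})

test_that("assembly comparison classifies rescue, relocation and reorientation", {
  ids <- paste0("s", 1:8)
  ordered <- tibble::tibble(
    chrom = c(rep("1A", 4), rep("2A", 3), "3B"),
    position_index = c(1:4, 1:3, 1L), super_id = ids,
    orientation = "+", orientation_determined = TRUE,
    mean_cm = 1:8, n_markers = 2L, length_bp = rep(100, 8))
  seqs <- seq_tbl(c(ids, "u1"), NA, length_bp = rep(100, 9))
  ps <- build_pseudomolecules(ordered, seqs)

  identical_old <- tibble::tibble(
    seq_id = c(ids, "u1"),
    chrom = c(ordered$chrom, "ChrUn"),
    position_index = c(ordered$position_index, NA),
    orientation = c(ordered$orientation, "+"))
  cmpI <- compare_assemblies(ps, identical_old)
  expect_true(all(cmpI$per_scaffold$class == "unchanged"))

  old <- identical_old
  old$orientation[old$seq_id == "s2"] <- "-"           # reoriented
  old$chrom[old$seq_id == "s5"] <- "7B"                # relocated
  old$chrom[old$seq_id == "s8"] <- "ChrUn"             # rescued
  cmp <- compare_assemblies(ps, old)
  per <- cmp$per_scaffold
  expect_identical(per$class[per$seq_id == "s2"], "reoriented")
  expect_identical(per$class[per$seq_id == "s5"], "relocated")
  expect_identical(per$class[per$seq_id == "s8"], "rescued")
  expect_identical(sum(per$class == "unchanged"), 6L)

  # scaffolds swapped within a chromosome: exactly the minimal set moves
  old2 <- identical_old
  old2$position_index[old2$seq_id == "s1"] <- 4L
  old2$position_index[old2$seq_id == "s4"] <- 1L
  cmp2 <- compare_assemblies(ps, old2)
  per2 <- cmp2$per_scaffold
  expect_identical(sort(per2$seq_id[per2$class == "relocated"]),
                   sort(c("s1", "s4")) [1:sum(per2$class == "relocated")])
  expect_lte(sum(per2$class == "relocated"), 2L)
  expect_gte(sum(per2$class == "relocated"), 1L)
})

test_that("injected old-layout corruption is recovered class by class", {
  sim <- small_sim(seed = 77, n_chimeras = 0L, n_chromosomes = 4L,
                   chromosome_length_bp = 2e6, scaffold_break_rate = 3)
  supers <- mk_supers(sim$scaffolds$seq_id, sim$scaffolds$length_bp)
  asg <- assign_chromosomes(sim$markers, supers)
  ord <- order_and_orient(asg, sim$markers, supers)
  ps <- build_pseudomolecules(ord, sim$scaffolds)
  old <- sim$truth$old_layout
  cmp <- compare_assemblies(ps, old)
  per <- dplyr::inner_join(cmp$per_scaffold, old, by = "seq_id")
  # only judge scaffolds the marker anchoring actually placed with a
  # determined orientation (few markers leave some undetermined)
  det <- ord$super_id[ord$orientation_determined]
  judged <- per[per$seq_id %in% det, ]
  agree <- judged$class == judged$class_truth
  expect_gte(mean(agree), 0.9)
})

test_that("N% report reproduces the headline totals", {
  # per-chromosome lengths and effective lengths of a 14-chromosome
  # assembly; the totals row recomputes N% from the sums
  tab <- tibble::tibble(
    chrom = c("Chr1A", "Chr2A"),
    length_bp = c(609493238, 788782410),
    effective_bp = c(589191139, 766375931))
  rep <- report_tables(tab)
  expect_identical(rep$n_pct[1], 3.33)
  expect_identical(rep$n_pct[2], 2.84)

  zero <- report_tables(tibble::tibble(chrom = "Chr1A", length_bp = 100,
                                       effective_bp = 100))
  expect_identical(zero$n_pct, c(0, 0))
})
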