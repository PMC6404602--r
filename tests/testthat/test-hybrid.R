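# Placement, gap estimation, super-scaffold construction, the second
# scaffolding round, and sequence/AGP emission.

# one shared zero-noise scaffolding run (chimera-free, so placements are
# directly comparable to truth)
hybrid_fix <- local({
  sim <- small_sim(seed = 31, n_chimeras = 0L, n_chromosomes = 2L,
                   chromosome_length_bp = 4e6, scaffold_break_rate = 3)
  aln <- align_sim(sim)
  pl <- place_sequences(aln)
  gaps <- estimate_gaps(pl)
  list(sim = sim, aln = aln, pl = pl, gaps = gaps)
})

test_that("zero-noise placements equal the ground-truth layout exactly", {
  sim <- hybrid_fix$sim
  pl <- hybrid_fix$pl
  tr <- sim$truth$placements
  expect_identical(nrow(pl), nrow(tr))
  j <- dplyr::inner_join(pl, tr, by = "seq_id")
  mt <- sim$truth$map1
  expect_true(all(mt$chrom[match(j$map_id, mt$map_id)] == j$chrom))
  expect_identical(j$orientation.x, j$orientation.y)
  # projected extents equal the true chromosome intervals
  expect_equal(j$map_start, j$start)
  expect_equal(j$map_end, j$end)
  # member order along each map follows the truth
  ord <- pl |> dplyr::arrange(.data$map_id, .data$map_start)
  want <- tr |> dplyr::arrange(.data$chrom, .data$start)
  expect_identical(ord$seq_id, want$seq_id)
})

test_that("ambiguous and overlapping placements are demoted", {
  set.seed(41)
  ref1 <- lmap("c1", sort(sample(5000:995000, 50)), 1e6)
  # second contig shares the same label pattern: ambiguous placement
  ref2 <- ref1
  ref2$map_id <- "c2"
  q <- lmap("q", ref1$position[10:25] - ref1$position[10] + 1,
            ref1$position[25] - ref1$position[10] + 100)
  aln <- align_maps(q, dplyr::bind_rows(ref1, ref2), align_params())
  pl <- place_sequences(aln)
  expect_identical(nrow(pl), 0L)
  expect_identical(attr(pl, "unplaced")$reason, "ambiguous")

  # two queries over the same interval: higher confidence wins
  q2 <- lmap("q2", ref1$position[12:20] - ref1$position[12] + 1,
             ref1$position[20] - ref1$position[12] + 100)
  aln2 <- align_maps(dplyr::bind_rows(q, q2), ref1, align_params())
  pl2 <- place_sequences(aln2)
  expect_identical(pl2$seq_id, "q")
  expect_identical(attr(pl2, "unplaced")$seq_id, "q2")
})

test_that("zero-noise gap estimates equal the true inter-scaffold distances", {
  sim <- hybrid_fix$sim
  gaps <- hybrid_fix$gaps
  tr <- sim$truth$placements |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(right = dplyr::lead(.data$seq_id)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$right))
  cmp <- dplyr::inner_join(gaps, tr, by = c(left_id = "seq_id",
                                            right_id = "right"))
  expect_identical(nrow(cmp), nrow(gaps))
  expect_equal(cmp$gap_bp, cmp$gap_after_bp)
})

test_that("touching scaffolds floor at min_gap and adjacency is enforced", {
  pl <- hybrid_fix$pl
  left <- pl[1, ]; right <- pl[2, ]
  # force a negative raw estimate by pretending right starts at left
  fake <- right
  fake$r_first <- left$r_last + 5
  fake$map_start <- left$map_end - 10
  fake$q_first_or <- 200
  expect_identical(estimate_gap(left, fake), 13)
  other_map <- dplyr::mutate(right, map_id = "elsewhere")
  expect_error(estimate_gap(left, other_map), "different maps")
  expect_error(estimate_gap(right, left), "not adjacent")
})

test_that("super-scaffold membership partitions the scaffold set", {
  sim <- hybrid_fix$sim
  ss <- build_superscaffolds(hybrid_fix$pl, hybrid_fix$gaps, sim$scaffolds)
  expect_setequal(ss$seq_id, sim$scaffolds$seq_id)
  expect_identical(anyDuplicated(ss$seq_id), 0L)
  # zero-noise recovery: per map contig, order and orientation = truth
  tr <- sim$truth$placements |> dplyr::arrange(.data$chrom, .data$start)
  mt <- sim$truth$map1
  for (sid in unique(ss$super_id[!is.na(ss$map_id)])) {
    mem <- ss[ss$super_id == sid, ]
    mem <- mem[order(mem$member_index), ]
    chr <- mt$chrom[match(mem$map_id[1], mt$map_id)]
    want <- tr[tr$chrom == chr, ]
    expect_identical(mem$seq_id, want$seq_id)
    expect_identical(mem$orientation, want$orientation)
  }

  # no placements: every scaffold passes through as a singleton
  empty_pl <- hybrid_fix$pl[0, ]
  solo <- build_superscaffolds(empty_pl, hybrid_fix$gaps[0, ], sim$scaffolds)
  expect_identical(solo$super_id, sim$scaffolds$seq_id)
  expect_true(all(solo$member_index == 1L))
})

test_that("emitted sequences conserve non-N bases and honor orientation", {
  set.seed(47)
  sc <- seq_tbl(c("a", "b"), c(random_seq(100), random_seq(100)))
  supers <- tibble::tibble(super_id = "ss", member_index = 1:2,
                           seq_id = c("a", "b"), orientation = c("+", "-"),
                           gap_after_bp = c(50, NA), length_bp = c(100, 100),
                           map_id = "m")
  em <- emit_sequences(supers, sc)
  expect_identical(em$sequences$length_bp, 250)
  expect_identical(nrow(em$agp), 3L)
  expect_identical(
    em$sequences$seq,
    paste0(sc$seq[1], strrep("N", 50), revcomp(sc$seq[2])))
  expect_error(emit_sequences(supers, sc[1, ]), "missing")

  non_n <- function(x) sum(nchar(gsub("N", "", x)))
  sim <- hybrid_fix$sim
  ss <- build_superscaffolds(hybrid_fix$pl, hybrid_fix$gaps, sim$scaffolds)
  em2 <- emit_sequences(ss, sim$scaffolds)
  expect_identical(non_n(em2$sequences$seq), non_n(sim$scaffolds$seq))
})

test_that("the second round merges map-A fragments that map B spans", {
  sim <- hybrid_fix$sim
  # fragment map 1 artificially: split each contig at its midpoint so
  # round one yields two super-scaffolds per chromosome
  frag <- sim$map1 |>
    dplyr::group_by(.data$map_id) |>
    dplyr::group_modify(function(m, key) {
      mid <- m$length_bp[1] / 2
      dplyr::bind_rows(
        lmap("left", m$position[m$position <= mid], mid) |>
          dplyr::select(-"map_id"),
        lmap("right", m$position[m$position > mid] - mid,
             m$length_bp[1] - mid) |> dplyr::select(-"map_id")) |>
        dplyr::mutate(part = rep(c("a", "b"),
                                 c(sum(m$position <= mid),
                                   sum(m$position > mid))))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(map_id = paste0(.data$map_id, "_", .data$part)) |>
    dplyr::select(-"part")
  aln <- align_sim(sim, map = frag)
  pl <- place_sequences(aln)
  ss1 <- build_superscaffolds(pl, estimate_gaps(pl), sim$scaffolds)
  n1 <- length(unique(ss1$super_id))
  st1 <- assembly_stats(emit_sequences(ss1, sim$scaffolds)$sequences)
  # second map is unfragmented and spans the artificial breaks
  ss2 <- second_round(ss1, sim$scaffolds, sim$map2,
                      params = align_params(min_confidence = 15,
                                            label_footprint_bp = 7L),
                      min_label_distance_bp = 0)
  n2 <- length(unique(ss2$super_id))
  expect_lt(n2, n1)
  st2 <- assembly_stats(emit_sequences(ss2, sim$scaffolds)$sequences)
  expect_gte(st2$n50_bp, st1$n50_bp)
  # membership is preserved through merging
  expect_setequal(ss2$seq_id, sim$scaffolds$seq_id)
})

test_that("a second map with identical information adds no joins", {
  sim <- hybrid_fix$sim
  ss1 <- build_superscaffolds(hybrid_fix$pl, hybrid_fix$gaps, sim$scaffolds)
  # identical information: the second round sees the first map again
  ss2 <- second_round(ss1, sim$scaffolds, sim$map1,
                      enzyme = sim$config$enzyme,
                      params = align_params(min_confidence = 15,
                                            label_footprint_bp = 6L),
                      min_label_distance_bp = 0)
  expect_identical(length(unique(ss2$super_id)),
                   length(unique(ss1$super_id)))
  expect_identical(sort(table(ss1$super_id)), sort(table(ss2$super_id)))
})
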