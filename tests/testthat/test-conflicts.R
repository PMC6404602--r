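# Conflict detection, arbitration with the second map, split planning
# and application.

test_that("a scaffold contained in one alignment yields no conflict", {
  set.seed(61)
  ref <- lmap("r", sort(sample(5000:995000, 60)), 1e6)
  q <- lmap("q", ref$position[10:30] - ref$position[10] + 1,
            ref$position[30] - ref$position[10] + 200)
  aln <- align_maps(q, ref, align_params())
  expect_identical(nrow(detect_conflicts(aln)), 0L)
})

test_that("zero-noise chimeras produce one split conflict bracketing the junction", {
  sim <- small_sim(seed = 7)
  aln <- align_sim(sim)
  conf <- detect_conflicts(aln)
  expect_identical(sort(unique(conf$scaffold_id)),
                   sort(sim$truth$chimeras$seq_id))
  expect_true(all(conf$kind == "split_alignment"))
  for (i in seq_len(nrow(sim$truth$chimeras))) {
    ch <- sim$truth$chimeras[i, ]
    cf <- conf[conf$scaffold_id == ch$seq_id, ]
    expect_identical(nrow(cf), 1L)
    # the bracket contains the junction up to one label interval
    expect_lte(cf$ext_start, ch$junction_start)
    expect_gte(cf$ext_end, ch$junction_end)
  }
})

test_that("chimera-free zero-noise simulations yield zero conflicts", {
  sim <- small_sim(seed = 12, n_chimeras = 0L)
  expect_identical(nrow(detect_conflicts(align_sim(sim))), 0L)
})

test_that("a repeat copy-number disagreement is flagged as internal discordance", {
  # map contig carries 3 tandem copies of repeat 1 and 2 of repeat 2;
  # the scaffold carries only 2 copies of repeat 1
  set.seed(71)
  unit1 <- cumsum(c(0, 9000, 14000, 11000, 17000, 12000, 15000, 13000))
  unit1_len <- 110000
  unit2 <- cumsum(c(0, 12000, 9000, 16000))
  unit2_len <- 50000
  flank1 <- sort(sample(2000:140000, 20))
  flank2 <- sort(sample(2000:140000, 20))
  block <- function(copies1) {
    pos <- flank1
    base <- 150000
    for (k in seq_len(copies1)) {
      pos <- c(pos, base + unit1)
      base <- base + unit1_len
    }
    for (k in 1:2) {
      pos <- c(pos, base + unit2)
      base <- base + unit2_len
    }
    c(pos, base + 10000 + flank2)
  }
  rpos <- block(3)
  qpos <- block(2)
  ref <- lmap("map", rpos, max(rpos) + 2000)
  q <- lmap("scf", qpos, max(qpos) + 2000)
  aln <- align_maps(q, ref, align_params())
  conf <- detect_conflicts(aln)
  expect_true("internal_discordance" %in% conf$kind)
})

test_that("arbitration separates sequence errors from map errors at zero noise", {
  # sequence errors: injected chimeras over several seeds
  n_seq_ok <- 0L; n_seq <- 0L
  for (seed in c(7, 8, 9, 10, 11)) {
    sim <- small_sim(seed = seed, n_chimeras = 4L,
                     n_chromosomes = 2L, chromosome_length_bp = 3e6)
    conf <- detect_conflicts(align_sim(sim))
    conf <- conf[conf$scaffold_id %in% sim$truth$chimeras$seq_id, ]
    aln2 <- align_sim(sim, map = sim$map2, enzyme = enzyme_spec("Nt.BspQI"))
    conf <- arbitrate_conflicts(conf, aln2)
    n_seq <- n_seq + nrow(conf)
    n_seq_ok <- n_seq_ok + sum(conf$verdict == "sequence_error")
  }
  expect_gte(n_seq, 20L)
  expect_identical(n_seq_ok, n_seq)

  # map errors: duplicate a label block inside scaffold spans of map 1
  sim <- small_sim(seed = 13, n_chimeras = 0L,
                   n_chromosomes = 2L, chromosome_length_bp = 12e6,
                   scaffold_break_rate = 2)
  corrupted <- corrupt_map_blocks(sim, n = 20L)
  expect_gte(length(corrupted$scaffolds), 15L)
  aln1 <- align_sim(sim, map = corrupted$map)
  conf <- detect_conflicts(aln1)
  conf <- conf[conf$scaffold_id %in% corrupted$scaffolds, ]
  expect_gte(length(unique(conf$scaffold_id)),
             length(corrupted$scaffolds) - 2L)
  aln2 <- align_sim(sim, map = sim$map2, enzyme = enzyme_spec("Nt.BspQI"))
  conf <- arbitrate_conflicts(conf, aln2)
  expect_true(all(conf$verdict == "map_error"))
})

test_that("split planning picks the N run nearest the conflict center", {
  n_runs <- tibble::tibble(seq_id = "s",
                           start = c(99L, 300L, 600L),
                           end = c(120L, 320L, 640L))
  conf <- tibble::tibble(conflict_id = 1L, scaffold_id = "s", map_id = "m",
                         kind = "split_alignment", scaffold_start = 90,
                         scaffold_end = 650, map_start = 0, map_end = 0,
                         verdict = "sequence_error")
  pl <- plan_splits(conf, n_runs)
  expect_identical(pl$cut_pos, floor((300 + 320 + 1) / 2))

  # no N run inside the interval -> unresolved, no blind cut
  conf2 <- dplyr::mutate(conf, scaffold_start = 400, scaffold_end = 500)
  pl2 <- plan_splits(conf2, n_runs)
  expect_false(pl2$resolved)
  expect_true(is.na(pl2$cut_pos))

  # equidistant runs break toward the lower coordinate
  n_eq <- tibble::tibble(seq_id = "s", start = c(100L, 300L),
                         end = c(120L, 320L))
  conf3 <- dplyr::mutate(conf, scaffold_start = 110, scaffold_end = 311)
  pl3 <- plan_splits(conf3, n_eq)
  expect_identical(pl3$cut_pos, floor((100 + 120 + 1) / 2))

  # overlapping conflicts on one scaffold merge into a single cut
  conf4 <- dplyr::bind_rows(conf, dplyr::mutate(conf, conflict_id = 2L,
                                                scaffold_start = 200,
                                                scaffold_end = 700))
  expect_identical(nrow(plan_splits(conf4, n_runs)), 1L)
})

test_that("applying splits conserves non-N bases and adds one record per cut", {
  set.seed(91)
  base <- random_seq(5000)
  substr(base, 2001, 2100) <- strrep("N", 100)
  substr(base, 4001, 4050) <- strrep("N", 50)
  sc <- seq_tbl(c("a", "b"), c(base, random_seq(1000)))
  plans <- tibble::tibble(scaffold_id = c("a", "a"),
                          cut_pos = c(2050, 4025))
  out <- apply_splits(sc, plans)
  expect_identical(nrow(out$scaffolds), nrow(sc) + 2L)
  expect_identical(sort(out$scaffolds$seq_id), c("a_1", "a_2", "a_3", "b"))
  non_n <- function(x) sum(nchar(gsub("N", "", x)))
  expect_identical(non_n(out$scaffolds$seq), non_n(sc$seq))
  # pieces concatenate to the original record
  pieces <- out$scaffolds$seq[match(c("a_1", "a_2", "a_3"),
                                    out$scaffolds$seq_id)]
  expect_identical(paste(pieces, collapse = ""), base)

  expect_identical(apply_splits(sc, plans[0, ])$scaffolds, sc)
  expect_error(apply_splits(sc, tibble::tibble(scaffold_id = "b",
                                               cut_pos = 5000)),
               "outside")
})

test_that("split-ledger arithmetic matches at the full assembly scale", {
  # 151,912 records, 56 cuts across 47 of them -> 151,968 records
  n_rec <- 151912L
  ledger <- seq_tbl(sprintf("scf%06d", seq_len(n_rec)), NA,
                    length_bp = rep(1000, n_rec))
  set.seed(5)
  hit <- sample(ledger$seq_id, 47L)
  extra <- sample(hit, 9L)   # 47 + 9 = 56 cuts
  plans <- tibble::tibble(scaffold_id = c(hit, extra),
                          cut_pos = c(rep(400, 47), rep(700, 9)))
  out <- apply_splits(ledger, plans)
  expect_identical(nrow(out$scaffolds), 151968L)
})

test_that("markers lift through split provenance", {
  sc <- seq_tbl("a", paste0(random_seq(100, seed = 2), strrep("N", 20),
                            random_seq(80)))
  plans <- tibble::tibble(scaffold_id = "a", cut_pos = 110)
  sp <- apply_splits(sc, plans)
  mk <- tibble::tibble(marker_id = c("m1", "m2"), chrom = "1A",
                       cm = c(1, 2), scaffold_id = "a", pos = c(50, 150))
  lifted <- lift_markers(mk, sp$provenance)
  expect_identical(lifted$scaffold_id, c("a_1", "a_2"))
  expect_identical(lifted$pos, c(50, 40))
})
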