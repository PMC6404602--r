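# The simulator: determinism, planted structure, fragmentation truth,
# injected errors, chemistry-specific map behaviour, genetic maps.

tiny_cfg <- function(seed = 3, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2L,
                   chromosome_length_bp = 1.5e6, scaffold_break_rate = 3,
                   n_chimeras = 1L, n_misplacements = 2L,
                   n_misorientations = 2L, n_old_unplaced = 1L,
                   marker_density = 10)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("generation is byte-identical under one seed", {
  g1 <- simulate_genome(tiny_cfg())
  g2 <- simulate_genome(tiny_cfg())
  expect_identical(g1, g2)
  s1 <- simulate_dataset(tiny_cfg())
  s2 <- simulate_dataset(tiny_cfg())
  expect_identical(s1$scaffolds, s2$scaffolds)
  expect_identical(s1$map1, s2$map1)
  expect_identical(s1$map2, s2$map2)
  expect_identical(s1$markers, s2$markers)
})

test_that("planted tandem arrays match their annotation; none by default", {
  cfg <- tiny_cfg(repeat_families = list(
    list(unit_bp = 5000, copies = 3, n_insertions = 2)))
  g <- simulate_genome(cfg)
  expect_identical(nrow(g$repeats), 4L)   # 2 insertions x 2 chromosomes
  for (i in seq_len(nrow(g$repeats))) {
    r <- g$repeats[i, ]
    s <- g$sequences$seq[match(r$chrom, g$sequences$seq_id)]
    arr <- substring(s, r$start, r$end)
    unit <- substring(arr, 1, r$unit_bp)
    expect_identical(arr, strrep(unit, r$copies))
  }
  g0 <- simulate_genome(tiny_cfg())
  expect_identical(nrow(g0$repeats), 0L)
  cfg_big <- tiny_cfg(repeat_families = list(
    list(unit_bp = 1e6, copies = 3, n_insertions = 1)))
  expect_error(simulate_genome(cfg_big), "exceeds")
})

test_that("label density lands near its configured target", {
  cfg <- tiny_cfg()
  g <- simulate_genome(cfg)
  dig <- digest_sequences(g$sequences, cfg$enzyme, 0)
  dens <- nrow(dig) / (2 * 1.5e6) * 1e5
  expect_lt(abs(dens - cfg$label_density), 1.5)
})

test_that("fragmentation truth reconstitutes the chromosomes", {
  cfg <- tiny_cfg()
  g <- simulate_genome(cfg)
  fr <- fragment_genome(g, cfg)
  tr <- fr$truth
  # non-N scaffold bases equal the chromosome bases at the true interval
  for (i in seq_len(nrow(tr))) {
    p <- tr[i, ]
    seg <- substring(g$sequences$seq[match(p$chrom, g$sequences$seq_id)],
                     p$start, p$end)
    s <- fr$scaffolds$seq[match(p$seq_id, fr$scaffolds$seq_id)]
    if (p$orientation == "-") s <- revcomp(s)
    expect_identical(nchar(s), nchar(seg))
    keep <- strsplit(s, "")[[1]] != "N"
    expect_identical(strsplit(s, "")[[1]][keep], strsplit(seg, "")[[1]][keep])
  }
  # truth intervals tile each chromosome with the recorded gaps between
  by_ch <- split(tr, tr$chrom)
  for (ch in by_ch) {
    ch <- ch[order(ch$start), ]
    expect_true(all(diff(ch$start) > 0))
    expect_identical(ch$start[-1] - ch$end[-nrow(ch)] - 1,
                     ch$gap_after_bp[-nrow(ch)])
  }
})

test_that("break counts follow the Poisson model and rate zero means no breaks", {
  counts <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, n_chromosomes = 1L,
                      chromosome_length_bp = 1e6, scaffold_break_rate = 5,
                      label_density = 2, min_scaffold_bp = 1)
    g <- list(sequences = seq_tbl("1A", random_seq(1e6, seed = s)))
    nrow(fragment_genome(g, cfg)$truth) - 1L
  }, integer(1))
  lambda <- 5
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 50))

  cfg0 <- tiny_cfg(scaffold_break_rate = 0)
  g <- simulate_genome(cfg0)
  fr <- fragment_genome(g, cfg0)
  expect_identical(nrow(fr$truth), 2L)   # one scaffold per chromosome
})

test_that("chimera injection matches its configuration exactly", {
  cfg <- tiny_cfg(n_chimeras = 2L)
  g <- simulate_genome(cfg)
  fr <- fragment_genome(g, cfg)
  err <- inject_errors(fr$scaffolds, fr$truth, cfg)
  expect_identical(nrow(err$chimeras), 2L)
  for (i in 1:2) {
    ch <- err$chimeras[i, ]
    expect_false(ch$left_chrom == ch$right_chrom)
    s <- err$scaffolds$seq[match(ch$seq_id, err$scaffolds$seq_id)]
    expect_identical(substring(s, ch$junction_start, ch$junction_end),
                     strrep("N", 100))
  }
  err0 <- inject_errors(fr$scaffolds, fr$truth, tiny_cfg(n_chimeras = 0L))
  expect_identical(err0$scaffolds, fr$scaffolds)
})

test_that("a zero-noise direct-chemistry map equals the in-silico digest", {
  cfg <- zero_noise(tiny_cfg())
  g <- simulate_genome(cfg)
  m <- simulate_optical_map(g, cfg)
  dig <- digest_sequences(g$sequences, cfg$enzyme,
                          cfg$min_label_distance_bp)
  for (ch in g$sequences$seq_id) {
    mid <- m$truth$map_id[m$truth$chrom == ch]
    expect_identical(m$cmap$position[m$cmap$map_id == mid],
                     dig$position[dig$map_id == ch])
  }
})

test_that("certain fragile breakage cuts at every fragile site", {
  cfg <- zero_noise(tiny_cfg())
  cfg$enzyme <- enzyme_spec("Nt.BspQI")
  cfg$fragile_break_prob <- 1
  cfg$min_molecule_kb <- 0L
  g <- simulate_genome(cfg)
  m <- simulate_optical_map(g, cfg)
  fs <- fragile_sites(g$sequences, cfg$enzyme)
  # every distinct fragile site adds one cut per chromosome
  expected <- nrow(g$sequences) + nrow(dplyr::distinct(fs, seq_id, site))
  # contigs that end up without labels are not emitted
  expect_lte(length(unique(m$cmap$map_id)), expected)
  expect_gte(length(unique(m$cmap$map_id)), expected - 6L)
})

test_that("sizing residuals match the declared Gaussian model", {
  # 10,000 simulated intervals; Kolmogorov-Smirnov against N(0, c*sqrt(d))
  cfg <- sim_config(seed = 9, n_chromosomes = 1L,
                    chromosome_length_bp = 4e6,
                    noise = list(miss_rate = 0, false_rate = 0,
                                 sizing_sd_coeff = 1.0))
  g <- simulate_genome(cfg)
  truth <- digest_sequences(g$sequences, cfg$enzyme,
                            cfg$min_label_distance_bp)$position
  iv_t <- diff(truth)
  resid <- c()
  s <- 0L
  while (length(resid) < 10000) {
    m <- simulate_optical_map(g, cfg, stream = s)
    # miss/false are off, so label k corresponds to truth label k
    iv_o <- diff(m$cmap$position)
    resid <- c(resid, (iv_o - iv_t) / sqrt(iv_t))
    s <- s + 1L
  }
  # rounding to integer bp creates ties; the test is still valid
  ks <- suppressWarnings(
    stats::ks.test(resid, "pnorm", 0, cfg$noise$sizing_sd_coeff))
  expect_gt(ks$p.value, 0.01)
})

test_that("genetic maps are monotone and resolve through chimera hosts", {
  cfg <- tiny_cfg()
  sim <- simulate_dataset(cfg)
  mk <- sim$markers
  for (ch in unique(mk$chrom)) {
    m <- mk[mk$chrom == ch, ]
    expect_true(all(diff(m$cm) >= -1e-9))
  }
  expect_true(all(mk$scaffold_id %in% sim$scaffolds$seq_id))
  pos_ok <- mk$pos >= 1 &
    mk$pos <= sim$scaffolds$length_bp[match(mk$scaffold_id,
                                            sim$scaffolds$seq_id)]
  expect_true(all(pos_ok))

  cfg0 <- tiny_cfg(marker_density = 1e-9)
  g <- simulate_genome(cfg0)
  fr <- fragment_genome(g, cfg0)
  expect_identical(nrow(simulate_genetic_map(g, fr$truth, cfg0)), 0L)
})
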