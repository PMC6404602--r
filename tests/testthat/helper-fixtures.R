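# Fixture builders shared across the suite.  Everything is generated in
# code under fixed seeds; no data files.

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a sequence with the motif planted at given 0-based offsets (and nowhere
# else, with high probability: the background avoids the motif by rejection)
seq_with_motifs <- function(len, motif, offsets0, seed = 1) {
  set.seed(seed)
  repeat {
    s <- random_seq(len)
    if (!grepl(motif, s, fixed = TRUE) &&
        !grepl(optscaf::revcomp(motif), s, fixed = TRUE)) break
  }
  for (p in offsets0) {
    substr(s, p + 1, p + nchar(motif)) <- motif
  }
  s
}

# label-map tibble from a bare position vector
lmap <- function(id, positions, length_bp = max(positions) + 1000) {
  tibble::tibble(map_id = id, length_bp = as.double(length_bp),
                 site_id = seq_along(positions),
                 position = as.double(positions), channel = 1L)
}

# exhaustive best score over all monotone pairings (independent oracle
# for the DP; feasible for maps of <= 8 labels)
brute_force_best <- function(qpos, rpos, params) {
  n <- length(qpos); m <- length(rpos)
  best <- -Inf
  for (k in 2:min(n, m)) {
    qs <- utils::combn(n, k, simplify = FALSE)
    rs <- utils::combn(m, k, simplify = FALSE)
    for (qi in qs) {
      for (ri in rs) {
        s <- optscaf::score_alignment(data.frame(q = qi, r = ri),
                                      qpos, rpos, params)
        if (s > best) best <- s
      }
    }
  }
  best
}

# small zero-noise simulated dataset used by several conflict/scaffold
# tests (kept modest so the whole suite stays fast)
small_sim <- function(seed = 7, n_chimeras = 2L, noise = FALSE,
                      n_chromosomes = 2L, chromosome_length_bp = 3e6,
                      scaffold_break_rate = 2.5, ...) {
  cfg <- sim_config(seed = seed, n_chromosomes = n_chromosomes,
                    chromosome_length_bp = chromosome_length_bp,
                    scaffold_break_rate = scaffold_break_rate,
                    n_chimeras = n_chimeras, n_misplacements = 2L,
                    n_misorientations = 2L, n_old_unplaced = 1L,
                    marker_density = 10, ...)
  if (!noise) cfg <- zero_noise(cfg)
  simulate_dataset(cfg)
}

# digest scaffolds and align on a simulated map, mirroring the pipeline
align_sim <- function(sim, map = sim$map1, enzyme = sim$config$enzyme,
                      params = align_params()) {
  params$label_footprint_bp <- nchar(enzyme$motif)
  dig <- digest_sequences(sim$scaffolds, enzyme,
                          sim$config$min_label_distance_bp)
  align_maps(dig, map, params)
}

# Corrupt an optical map by duplicating a label block inside the spans
# of up to n scaffolds (a synthetic map-assembly error: the map shows
# two copies of a region the genome holds once).  Works on zero-noise
# maps, whose coordinates equal chromosome coordinates.
corrupt_map_blocks <- function(sim, n, map = sim$map1, blk = 110000) {
  pl <- sim$truth$placements
  host <- sim$truth$hosts
  own <- host$orig_id[host$orig_id == host$host_id]
  # ample flanks: even if the aligner matches the other repeat copy
  # (register shift of one block), >= min_confirm labels remain per side
  pl <- pl[pl$seq_id %in% own & (pl$end - pl$start) >= 4 * blk, ]
  pl <- pl[order(-(pl$end - pl$start)), ]
  pl <- utils::head(pl, n)
  mt <- sim$truth$map1
  out <- map
  affected <- character(0)
  for (ch in unique(pl$chrom)) {
    rows <- pl[pl$chrom == ch, ]
    rows <- rows[order(-rows$start), ]     # descending: no coordinate shifts
    mid <- mt$map_id[match(ch, mt$chrom)]
    for (i in seq_len(nrow(rows))) {
      center <- (rows$start[i] + rows$end[i]) / 2
      p <- center - blk / 2
      m <- out[out$map_id == mid, ]
      block <- m$position[m$position > p & m$position <= p + blk]
      if (length(block) < 6L) next
      newpos <- sort(c(m$position[m$position <= p + blk], block + blk,
                       m$position[m$position > p + blk] + blk))
      out <- dplyr::bind_rows(
        out[out$map_id != mid, ],
        lmap(mid, newpos, m$length_bp[1] + blk))
      affected <- c(affected, rows$seq_id[i])
    }
  }
  list(map = dplyr::arrange(out, map_id, position), scaffolds = affected)
}
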