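# Synthetic genomes, scaffold sets, optical maps under both labeling
# chemistries, genetic maps, and injected assembly errors -- with
# machine-readable ground truth.

#' Simulation configuration
#'
#' The default preset is a desk-scale study: 4 chromosomes of 12.5 Mb
#' (a 50-Mb genome), 15 labels per 100 kb, roughly 120 scaffolds and 8
#' injected chimeras.  Every random draw derives from `seed` through
#' fixed per-stage sub-streams, so adding a stage never perturbs an
#' earlier one and outputs are byte-identical under one seed.
#'
#' @param seed Integer seed (mandatory; all randomness derives from it).
#' @param n_chromosomes,chromosome_length_bp Genome shape.
#' @param label_density Expected labels per 100 kb.
#' @param repeat_families List of `list(unit_bp=, copies=, n_insertions=)`
#'   tandem-array specs.
#' @param scaffold_break_rate Poisson break rate per Mb.
#' @param n_chimeras,n_misplacements,n_misorientations,n_old_unplaced
#'   Injected assembly errors (chimeric joins; and, for the simulated
#'   "old" layout, wrong placements, flipped orientations, and scaffolds
#'   demoted to ChrUn so rescue can be tested).
#' @param noise List `miss_rate` (per label), `false_rate` (per 100 kb),
#'   `sizing_sd_coeff` (bp^(1/2)).
#' @param enzyme An [enzyme_spec()] (the map chemistry).
#' @param fragile_break_prob Per-fragile-site break probability (nick
#'   chemistry).
#' @param marker_density Markers per Mb.
#' @param min_molecule_kb Map contigs shorter than this are dropped.
#' @param min_label_distance_bp Imaging resolution: labels closer than
#'   this merge to their midpoint in the simulated maps (and in the
#'   matching in-silico digests).
#' @param n_run_rate_per_bp Internal sized-gap (N run) rate.
#' @param min_scaffold_bp Fragments shorter than this are not emitted as
#'   scaffolds (their bases join the flanking gap).  Scaffolds below the
#'   optical resolution limit carry too few labels to be alignable and
#'   are outside this simulator's scope.
#' @param n_run_len_range,gap_len_range Length ranges (bp) of internal N
#'   runs and of the dropped inter-scaffold gap segments.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 4L,
                       chromosome_length_bp = 12.5e6, label_density = 15,
                       repeat_families = list(), scaffold_break_rate = 3,
                       n_chimeras = 8L, n_misplacements = 10L,
                       n_misorientations = 10L, n_old_unplaced = 5L,
                       noise = list(miss_rate = 0.08, false_rate = 0.8,
                                    sizing_sd_coeff = 1.0),
                       enzyme = enzyme_spec("DLE-1"),
                       fragile_break_prob = 0.5, marker_density = 2,
                       min_molecule_kb = 150L, min_label_distance_bp = 1000,
                       n_run_rate_per_bp = 1 / 5e5,
                       n_run_len_range = c(100, 5000),
                       gap_len_range = c(500, 20000),
                       min_scaffold_bp = 1e5) {
  stopifnot(noise$miss_rate >= 0, noise$miss_rate <= 1,
            fragile_break_prob >= 0, fragile_break_prob <= 1,
            label_density > 0, n_chromosomes >= 1,
            n_chromosomes <= 14, !is.null(seed))
  structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = chromosome_length_bp,
                 label_density = label_density,
                 repeat_families = repeat_families,
                 scaffold_break_rate = scaffold_break_rate,
                 n_chimeras = as.integer(n_chimeras),
                 n_misplacements = as.integer(n_misplacements),
                 n_misorientations = as.integer(n_misorientations),
                 n_old_unplaced = as.integer(n_old_unplaced),
                 noise = noise, enzyme = enzyme,
                 fragile_break_prob = fragile_break_prob,
                 marker_density = marker_density,
                 min_molecule_kb = as.integer(min_molecule_kb),
                 min_label_distance_bp = min_label_distance_bp,
                 n_run_rate_per_bp = n_run_rate_per_bp,
                 n_run_len_range = n_run_len_range,
                 gap_len_range = gap_len_range,
                 min_scaffold_bp = min_scaffold_bp),
            class = "sim_config")
}

#' Noise-free variant of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return The configuration with all map noise and fragile breaking off.
#' @export
zero_noise <- function(config) {
  config$noise <- list(miss_rate = 0, false_rate = 0, sizing_sd_coeff = 0)
  config$fragile_break_prob <- 0
  # perfect imaging resolution: label collapse off, so in-silico and
  # optical label coordinates agree exactly
  config$min_label_distance_bp <- 0
  config
}

# sample() guard against the length-one numeric pitfall
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

# per-stage sub-streams
.str_genome <- 1L; .str_fragment <- 2L; .str_errors <- 3L
.str_map <- 10L; .str_markers <- 5L

#' Simulate a genome with planted tandem repeat arrays
#'
#' Bases are i.i.d. uniform outside planted arrays; arrays (identical
#' tandem copies of a random unit) are placed uniformly without overlap.
#' The recognition-motif occurrence count is then adjusted to the
#' configured label density by mutating surplus occurrences or planting
#' extra motifs at uniform positions outside the arrays, so that label
#' density is a controlled study condition rather than an accident of
#' motif length.  Deterministic under the seed.
#'
#' @param config A [sim_config()].
#' @return List with `sequences` (chromosome tibble; ids are chromosome
#'   names) and `repeats` (planted-array annotation: `chrom`, `start`,
#'   `end` 1-based inclusive, `family`, `unit_bp`, `copies`).
#' @export
simulate_genome <- function(config) {
  L <- as.integer(config$chromosome_length_bp)
  chroms <- chromosome_levels(config$n_chromosomes)
  with_stream(config$seed, .str_genome, {
    rep_rows <- list()
    seqs <- purrr::map_chr(seq_along(chroms), function(ci) {
      s <- random_dna(L)
      # plant tandem arrays
      occupied <- matrix(numeric(0), ncol = 2)
      for (fi in seq_along(config$repeat_families)) {
        fam <- config$repeat_families[[fi]]
        arr_len <- fam$unit_bp * fam$copies
        if (arr_len > L) abort("repeat array exceeds chromosome length")
        for (k in seq_len(fam$n_insertions %||% 1L)) {
          for (try in 1:100) {
            st <- sample.int(L - arr_len, 1L)
            if (nrow(occupied) == 0L ||
                all(st > occupied[, 2] | st + arr_len - 1 < occupied[, 1])) break
          }
          unit <- random_dna(fam$unit_bp)
          arr <- strrep(unit, fam$copies)
          substr(s, st, st + arr_len - 1L) <- arr
          occupied <- rbind(occupied, c(st, st + arr_len - 1))
          rep_rows[[length(rep_rows) + 1L]] <<- tibble(
            chrom = chroms[ci], family = fi, start = st,
            end = st + arr_len - 1L, unit_bp = fam$unit_bp,
            copies = fam$copies)
        }
      }
      tune_label_density(s, config$enzyme, config$label_density, occupied)
    })
    list(sequences = seq_tbl(chroms, seqs),
         repeats = bind_rows(rep_rows) %||%
           tibble(chrom = character(), family = integer(), start = integer(),
                  end = integer(), unit_bp = integer(), copies = integer()))
  })
}

# adjust motif occurrences toward the target density (per 100 kb),
# leaving planted arrays untouched
tune_label_density <- function(s, enzyme, density, occupied) {
  L <- nchar(s)
  mlen <- nchar(enzyme$motif)
  rcm <- revcomp(enzyme$motif)
  in_array <- function(p) {
    nrow(occupied) > 0L &&
      any(p <= occupied[, 2] & p + mlen - 1 >= occupied[, 1])
  }
  find_all <- function(s) {
    p <- motif_starts(s, enzyme$motif)
    if (!enzyme$palindromic) {
      p <- sort(unique(c(p, motif_starts(s, rcm))))
    }
    p
  }
  target <- round(density * L / 1e5)
  pos <- find_all(s)
  chars <- NULL   # edit a char vector: substr<- on a Mb string is O(L) per call
  if (length(pos) > target) {
    free <- pos[!purrr::map_lgl(pos, in_array)]
    kill <- resample(free, min(length(free), length(pos) - target))
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in kill) {
      # mutate the middle base of the occurrence
      mid <- p + mlen %/% 2
      chars[mid] <- resample(setdiff(c("A", "C", "G", "T"), chars[mid]), 1L)
    }
  } else if (length(pos) < target) {
    need <- target - length(pos)
    cand <- sort(sample.int(L - mlen, min(L - mlen, 2L * need + 10L)))
    cand <- cand[!purrr::map_lgl(cand, in_array)]
    cand <- cand[c(TRUE, diff(cand) > 2 * mlen)]   # keep plant sites apart
    cand <- utils::head(cand, need)
    strands <- if (enzyme$palindromic) rep("+", length(cand)) else
      sample(c("+", "-"), length(cand), replace = TRUE)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in seq_along(cand)) {
      motif <- if (strands[i] == "+") enzyme$motif else rcm
      chars[cand[i]:(cand[i] + mlen - 1L)] <- strsplit(motif, "")[[1]]
    }
  }
  if (!is.null(chars)) s <- paste(chars, collapse = "")
  s
}

#' Fragment a genome into a scaffold set with ground truth
#'
#' Breakpoints follow a Poisson process at `scaffold_break_rate` per Mb;
#' at each break a gap segment (`gap_len_range`) of chromosome sequence
#' is dropped (unsequenced), and its true length recorded.  Each
#' scaffold is independently flipped with probability 0.5, and internal
#' sized gaps (N runs replacing equal-length sequence) are planted at
#' `n_run_rate_per_bp` so that split sites exist.
#'
#' @param genome Result of [simulate_genome()].
#' @param config A [sim_config()].
#' @return List with `scaffolds` (sequence tibble) and `truth`
#'   (placements tibble: `seq_id`, `chrom`, `start`, `end` 1-based
#'   inclusive chromosome interval, `orientation`, `gap_after_bp` true
#'   gap to the next scaffold, `NA` for the last).
#' @export
fragment_genome <- function(genome, config) {
  with_stream(config$seed, .str_fragment, {
    sc_rows <- list(); tr_rows <- list()
    counter <- 0L
    for (ci in seq_len(nrow(genome$sequences))) {
      chrom <- genome$sequences$seq_id[ci]
      s <- genome$sequences$seq[ci]
      L <- nchar(s)
      n_breaks <- rpois(1L, config$scaffold_break_rate * L / 1e6)
      bp <- sort(sample.int(L - 1L, n_breaks))
      gaps <- round(runif(n_breaks, config$gap_len_range[1],
                          config$gap_len_range[2]))
      # scaffold i spans (bound[i], bound2[i]] on the chromosome
      starts <- c(1, pmin(bp + gaps + 1, L))
      ends <- c(bp, L)
      keep <- ends - starts + 1 >= config$min_scaffold_bp
      starts <- starts[keep]; ends <- ends[keep]
      for (i in seq_along(starts)) {
        counter <- counter + 1L
        id <- sprintf("scaffold%04d", counter)
        seg <- substring(s, starts[i], ends[i])
        slen <- nchar(seg)
        # internal N runs replacing sequence
        n_runs <- rpois(1L, slen * config$n_run_rate_per_bp)
        max_rl <- config$n_run_len_range[2]
        if (n_runs > 0L && slen > 2 * 10000 + max_rl + 1000) {
          rl <- round(runif(n_runs, config$n_run_len_range[1],
                            config$n_run_len_range[2]))
          rs <- sort(round(runif(n_runs, 10000, slen - 10000 - max(rl))))
          ok <- c(TRUE, diff(rs) > max(rl) + 1000)
          rs <- rs[ok]; rl <- rl[ok]
          for (k in seq_along(rs)) {
            substr(seg, rs[k], rs[k] + rl[k] - 1L) <- strrep("N", rl[k])
          }
        }
        orient <- sample(c("+", "-"), 1L)
        if (orient == "-") seg <- revcomp(seg)
        gap_after <- if (i < length(starts)) starts[i + 1] - ends[i] - 1
                     else NA_real_
        sc_rows[[length(sc_rows) + 1L]] <- tibble(seq_id = id, seq = seg)
        tr_rows[[length(tr_rows) + 1L]] <- tibble(
          seq_id = id, chrom = chrom, start = starts[i], end = ends[i],
          orientation = orient, gap_after_bp = gap_after)
      }
    }
    sc <- bind_rows(sc_rows)
    list(scaffolds = seq_tbl(sc$seq_id, sc$seq), truth = bind_rows(tr_rows))
  })
}

#' Inject assembly errors with recorded ground truth
#'
#' Chimeras join two scaffolds from different chromosomes through a
#' 100-N spacer (so a break-at-N fix exists).  For testing assembly
#' comparison, a corrupted "old" layout is also generated in which
#' configured numbers of scaffolds are misplaced, misoriented, or
#' demoted to ChrUn.
#'
#' @param scaffolds Scaffold tibble from [fragment_genome()].
#' @param truth Truth placements from [fragment_genome()].
#' @param config A [sim_config()].
#' @return List with `scaffolds` (corrupted set), `chimeras` (tibble
#'   `seq_id`, `left_id`, `right_id`, `junction_start`, `junction_end`
#'   1-based N-spacer interval, `left_chrom`, `right_chrom`), `hosts`
#'   (original scaffold -> host record mapping: `orig_id`, `host_id`,
#'   `offset_bp`), and `old_layout` (tibble `seq_id`, `chrom`,
#'   `position_index`, `orientation`, `class_truth`).
#' @export
inject_errors <- function(scaffolds, truth, config) {
  with_stream(config$seed, .str_errors, {
    hosts <- tibble(orig_id = scaffolds$seq_id, host_id = scaffolds$seq_id,
                    offset_bp = 0)
    chim_rows <- list()
    sc <- scaffolds
    if (config$n_chimeras > 0L) {
      big <- truth$seq_id[truth$end - truth$start + 1 >= 2e5]
      pool <- sample(big)
      used <- character(0)
      for (k in seq_len(config$n_chimeras)) {
        cand <- setdiff(pool, used)
        found <- FALSE
        for (a in cand) {
          partner_ok <- cand[truth$chrom[match(cand, truth$seq_id)] !=
                               truth$chrom[match(a, truth$seq_id)]]
          partner_ok <- setdiff(partner_ok, a)
          if (length(partner_ok)) {
            b <- partner_ok[1]
            found <- TRUE
            break
          }
        }
        if (!found) break
        used <- c(used, a, b)
        ia <- match(a, sc$seq_id); ib <- match(b, sc$seq_id)
        la <- sc$length_bp[ia]
        id <- sprintf("chimera%02d", k)
        joined <- paste0(sc$seq[ia], strrep("N", 100L), sc$seq[ib])
        chim_rows[[length(chim_rows) + 1L]] <- tibble(
          seq_id = id, left_id = a, right_id = b,
          junction_start = la + 1, junction_end = la + 100,
          left_chrom = truth$chrom[match(a, truth$seq_id)],
          right_chrom = truth$chrom[match(b, truth$seq_id)])
        hosts$host_id[hosts$orig_id == a] <- id
        hosts$host_id[hosts$orig_id == b] <- id
        hosts$offset_bp[hosts$orig_id == b] <- la + 100
        sc <- sc[-c(ia, ib), ]
        sc <- bind_rows(sc, seq_tbl(id, joined))
      }
    }
    chimeras <- bind_rows(chim_rows) %||%
      tibble(seq_id = character(), left_id = character(),
             right_id = character(), junction_start = double(),
             junction_end = double(), left_chrom = character(),
             right_chrom = character())
    old_layout <- corrupt_layout(truth, config)
    list(scaffolds = sc, chimeras = chimeras, hosts = hosts,
         old_layout = old_layout)
  })
}

# Build the "old assembly" layout: the true layout with injected
# misplacements, misorientations and ChrUn demotions.
corrupt_layout <- function(truth, config) {
  base <- truth |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(position_index = row_number()) |>
    ungroup() |>
    select("seq_id", "chrom", "position_index", "orientation") |>
    mutate(class_truth = "unchanged")
  ids <- sample(base$seq_id)
  n_mis <- min(config$n_misplacements, length(ids))
  mis <- ids[seq_len(n_mis)]
  ids <- setdiff(ids, mis)
  n_or <- min(config$n_misorientations, length(ids))
  reor <- ids[seq_len(n_or)]
  ids <- setdiff(ids, reor)
  n_un <- min(config$n_old_unplaced, length(ids))
  unpl <- ids[seq_len(n_un)]
  out <- base
  chroms <- unique(base$chrom)
  for (id in mis) {
    i <- match(id, out$seq_id)
    other <- setdiff(chroms, out$chrom[i])
    out$chrom[i] <- if (length(other)) resample(other, 1L) else out$chrom[i]
    out$class_truth[i] <- "relocated"
  }
  for (id in reor) {
    i <- match(id, out$seq_id)
    out$orientation[i] <- if (out$orientation[i] == "+") "-" else "+"
    out$class_truth[i] <- "reoriented"
  }
  for (id in unpl) {
    i <- match(id, out$seq_id)
    out$chrom[i] <- "ChrUn"
    out$class_truth[i] <- "rescued"
  }
  # renumber positions inside each chromosome, keeping relative order
  out |>
    group_by(.data$chrom) |>
    arrange(.data$position_index, .by_group = TRUE) |>
    mutate(position_index = row_number()) |>
    ungroup()
}

#' Simulate an optical map of a genome
#'
#' True label positions come from in-silico digestion of each
#' chromosome.  Under the nick chemistry, each fragile pair
#' (opposite-strand sites within `fragile_distance_bp`) breaks the
#' contig with probability `fragile_break_prob` — reproducing the
#' fragmentation of nick-labeled maps; the direct chemistry never
#' breaks.  Per-label Bernoulli misses, Poisson false labels and
#' Gaussian interval sizing noise (sd = `sizing_sd_coeff * sqrt(bp)`)
#' are then applied, and contigs shorter than `min_molecule_kb` are
#' dropped.
#'
#' @param genome Result of [simulate_genome()].
#' @param config A [sim_config()] (fields `enzyme`, `noise`,
#'   `fragile_break_prob`, `min_molecule_kb`).
#' @param stream Sub-stream offset (use different values for two maps
#'   of one genome).
#' @param min_label_distance_bp Label-merge distance of the digestion.
#' @return List with `cmap` (label-map tibble) and `truth` (tibble
#'   `map_id`, `chrom`, `start`, `end` of the spanned chromosome
#'   interval).
#' @export
simulate_optical_map <- function(genome, config, stream = 0L,
                                 min_label_distance_bp = NULL) {
  enzyme <- config$enzyme
  nz <- config$noise
  min_label_distance_bp <- min_label_distance_bp %||%
    config$min_label_distance_bp %||% 1000
  with_stream(config$seed, .str_map + stream, {
    cmap_rows <- list(); truth_rows <- list()
    for (ci in seq_len(nrow(genome$sequences))) {
      chrom <- genome$sequences$seq_id[ci]
      L <- genome$sequences$length_bp[ci]
      dig <- digest_sequences(genome$sequences[ci, ], enzyme,
                              min_label_distance_bp)
      labels <- dig$position
      # fragile-site double-strand breaks (nick chemistry)
      cuts <- numeric(0)
      if (enzyme$chemistry == "nick" && config$fragile_break_prob > 0) {
        fs <- fragile_sites(genome$sequences[ci, ], enzyme)
        if (nrow(fs) > 0L) {
          sites <- unique(fs$site)
          broken <- sites[runif(length(sites)) < config$fragile_break_prob]
          cuts <- sort(broken)
        }
      }
      bounds <- c(0, cuts, L)
      for (k in seq_len(length(bounds) - 1L)) {
        c_start <- bounds[k] + 1; c_end <- bounds[k + 1]
        clen <- c_end - c_start + 1
        if (clen < config$min_molecule_kb * 1000) next
        lab <- labels[labels >= c_start & labels <= c_end] - c_start + 1
        # misses
        if (nz$miss_rate > 0 && length(lab)) {
          lab <- lab[runif(length(lab)) >= nz$miss_rate]
        }
        # false labels
        if (nz$false_rate > 0) {
          nf <- rpois(1L, nz$false_rate * clen / 1e5)
          if (nf > 0L) lab <- sort(c(lab, round(runif(nf, 1, clen))))
        }
        lab <- sort(unique(lab))
        out_len <- clen
        if (nz$sizing_sd_coeff > 0 && length(lab)) {
          iv <- diff(c(0, lab, clen))
          iv <- pmax(1, round(iv + rnorm(length(iv),
                                         0, nz$sizing_sd_coeff * sqrt(iv))))
          cum <- cumsum(iv)
          lab <- cum[-length(cum)]
          out_len <- cum[length(cum)]
        }
        if (length(lab) == 0L) next
        mid <- sprintf("ctg_%s_%d", chrom, k)
        cmap_rows[[length(cmap_rows) + 1L]] <- tibble(
          map_id = mid, length_bp = as.double(out_len),
          site_id = seq_along(lab), position = as.double(lab), channel = 1L)
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          map_id = mid, chrom = chrom, start = c_start, end = c_end)
      }
    }
    cm <- bind_rows(cmap_rows) %||% cmap_empty()
    list(cmap = cm, truth = bind_rows(truth_rows))
  })
}

#' Simulate a genetic (linkage) map
#'
#' Markers fall at Poisson positions along each chromosome; cM is a
#' monotone piecewise-linear transform of bp with random plateau
#' segments (so scaffolds with markers at a single cM value — the
#' undetermined-orientation case — arise naturally).  Marker scaffold
#' hits are derived through the true placements (and through chimera
#' hosts when `hosts` is given).
#'
#' @param genome Result of [simulate_genome()].
#' @param truth Placements from [fragment_genome()].
#' @param config A [sim_config()].
#' @param hosts Optional host mapping from [inject_errors()].
#' @return Marker tibble `marker_id`, `chrom`, `cm`, `scaffold_id`,
#'   `pos`.
#' @export
simulate_genetic_map <- function(genome, truth, config, hosts = NULL) {
  with_stream(config$seed, .str_markers, {
    rows <- list()
    for (ci in seq_len(nrow(genome$sequences))) {
      chrom <- genome$sequences$seq_id[ci]
      L <- genome$sequences$length_bp[ci]
      n <- rpois(1L, config$marker_density * L / 1e6)
      if (n == 0L) next
      bp <- sort(round(runif(n, 1, L)))
      # piecewise-linear bp -> cM with plateaus
      n_seg <- 8L
      knots <- c(0, sort(runif(n_seg - 1L, 0, L)), L)
      slopes <- if_else(runif(n_seg) < 0.3, 0, runif(n_seg, 0.5, 2)) / 1e6
      cum_cm <- c(0, cumsum(slopes * diff(knots)))
      cm <- stats::approx(knots, cum_cm, xout = bp)$y
      pl <- truth[truth$chrom == chrom, ]
      hit <- purrr::map(seq_along(bp), function(i) {
        j <- which(pl$start <= bp[i] & pl$end >= bp[i])
        if (length(j) == 0L) return(NULL)
        p <- pl[j[1], ]
        pos <- if (p$orientation == "+") bp[i] - p$start + 1 else
          p$end - bp[i] + 1
        tibble(chrom = chrom, cm = cm[i], scaffold_id = p$seq_id, pos = pos)
      })
      rows[[length(rows) + 1L]] <- bind_rows(hit)
    }
    mk <- bind_rows(rows)
    if (nrow(mk) == 0L) {
      return(tibble(marker_id = character(), chrom = character(),
                    cm = double(), scaffold_id = character(), pos = double()))
    }
    mk <- mutate(mk, marker_id = sprintf("mk%05d", row_number()),
                 .before = 1L)
    if (!is.null(hosts)) {
      mk <- mk |>
        left_join(hosts, by = c(scaffold_id = "orig_id")) |>
        mutate(scaffold_id = .data$host_id, pos = .data$pos + .data$offset_bp) |>
        select(-"host_id", -"offset_bp")
    }
    mk
  })
}

#' Run the full simulator
#'
#' Generates the genome, fragments it into scaffolds, injects assembly
#' errors, simulates optical maps under both chemistries (the direct
#' chemistry of `config$enzyme` and a second nick-chemistry map), and
#' simulates a linkage map — all with ground truth.
#'
#' @param config A [sim_config()].
#' @param second_enzyme [enzyme_spec()] of the second map.
#' @return A list of class `optscaf_sim`: `genome`, `scaffolds`,
#'   `truth` (list `placements`, `chimeras`, `hosts`, `old_layout`,
#'   `map1`, `map2`), `map1`, `map2` (label-map tibbles), `markers`,
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             second_enzyme = enzyme_spec("Nt.BspQI")) {
  genome <- simulate_genome(config)
  frag <- fragment_genome(genome, config)
  err <- inject_errors(frag$scaffolds, frag$truth, config)
  m1 <- simulate_optical_map(genome, config, stream = 0L)
  cfg2 <- config
  cfg2$enzyme <- second_enzyme
  m2 <- simulate_optical_map(genome, cfg2, stream = 1L)
  markers <- simulate_genetic_map(genome, frag$truth, config,
                                  hosts = err$hosts)
  structure(list(
    genome = genome, scaffolds = err$scaffolds,
    truth = list(placements = frag$truth, chimeras = err$chimeras,
                 hosts = err$hosts, old_layout = err$old_layout,
                 map1 = m1$truth, map2 = m2$truth),
    map1 = m1$cmap, map2 = m2$cmap, markers = markers, config = config),
    class = "optscaf_sim")
}

#' @export
print.optscaf_sim <- function(x, ...) {
  cat(sprintf(
    "<optscaf_sim> %d chromosomes x %.1f Mb, %d scaffolds (%d chimeric), %d+%d map contigs, %d markers\n",
    x$config$n_chromosomes, x$config$chromosome_length_bp / 1e6,
    nrow(x$scaffolds), nrow(x$truth$chimeras),
    length(unique(x$map1$map_id)), length(unique(x$map2$map_id)),
    nrow(x$markers)))
  invisible(x)
}
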