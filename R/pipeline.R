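# Unified configuration and the end-to-end pipeline driver.

#' Pipeline configuration
#'
#' All tunable constants of the workflow in one place: enzyme specs for
#' both chemistries, the alignment confidence ladder (initial alignment
#' 10, confirmation 11, second-round merging 15 — the log10 analogs of
#' P < 1e-10 / 1e-11 / 1e-15), conflict tolerances, and anchoring
#' settings.  `write_pipeline_config()`/`read_pipeline_config()`
#' round-trip the configuration through YAML so every constant is
#' visible and overridable.
#'
#' @param seed Integer seed for the simulation stage.
#' @param sim A [sim_config()].
#' @param enzyme1,enzyme2 [enzyme_spec()]s of the two chemistries.
#' @param align An [align_params()] (round-one threshold).
#' @param confidence_ladder Named list `initial`, `confirm`, `merge`.
#' @param tol A [conflict_tol()].
#' @param anchor List `gap_n`, `min_markers`.
#' @param min_gap Gap floor for super-scaffolding (bp).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            enzyme1 = enzyme_spec("DLE-1"),
                            enzyme2 = enzyme_spec("Nt.BspQI"),
                            align = align_params(),
                            confidence_ladder = list(initial = 10,
                                                     confirm = 11,
                                                     merge = 15),
                            tol = conflict_tol(),
                            anchor = list(gap_n = 1000, min_markers = 2L),
                            min_gap = 13) {
  stopifnot(confidence_ladder$initial > 0, confidence_ladder$confirm > 0,
            confidence_ladder$merge > 0)
  structure(list(seed = as.integer(seed), sim = sim, enzyme1 = enzyme1,
                 enzyme2 = enzyme2, align = align,
                 confidence_ladder = confidence_ladder, tol = tol,
                 anchor = anchor, min_gap = min_gap),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = y$seed %||% 1L)
  restore <- function(defaults, values, class) {
    out <- utils::modifyList(unclass(defaults), values %||% list())
    structure(out, class = class)
  }
  cfg$sim <- restore(cfg$sim, y$sim, "sim_config")
  cfg$sim$enzyme <- restore(cfg$sim$enzyme, y$sim$enzyme, "enzyme_spec")
  cfg$enzyme1 <- restore(cfg$enzyme1, y$enzyme1, "enzyme_spec")
  cfg$enzyme2 <- restore(cfg$enzyme2, y$enzyme2, "enzyme_spec")
  cfg$align <- restore(cfg$align, y$align, "align_params")
  cfg$tol <- restore(cfg$tol, y$tol, "conflict_tol")
  cfg$confidence_ladder <- utils::modifyList(cfg$confidence_ladder,
                                             y$confidence_ladder %||% list())
  cfg$anchor <- utils::modifyList(cfg$anchor, y$anchor %||% list())
  cfg$min_gap <- y$min_gap %||% cfg$min_gap
  cfg
}

stage_failed <- function(stage, err) {
  abort(sprintf("pipeline stage '%s' failed: %s", stage,
                conditionMessage(err)))
}

#' Run the complete pipeline
#'
#' Simulate (or load) inputs, digest the scaffolds, align them on the
#' first optical map, resolve chimeras with the second map, build
#' super-scaffolds in two rounds, and anchor them into pseudomolecules
#' with the genetic map.  Every stage's outputs are written under
#' `out_dir` together with a manifest (input hashes, parameters,
#' package version) that makes runs reproducible; a stage failure halts
#' with the stage name.  A missing second map skips the second round
#' with a warning.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param inputs Optional named list of file paths (`fasta`, `cmap1`,
#'   `cmap2`, `markers`); when `NULL` the simulation stage generates
#'   them from `config$sim`.
#' @return Invisibly, a list with the stage results (`sim`, `digest`,
#'   `alignments`, `conflicts`, `supers`, `pseudo`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         inputs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "optscaf",
                   version = as.character(utils::packageVersion("optscaf")),
                   seed = config$seed, stages = list())
  note <- function(stage, files, params = NULL) {
    manifest$stages[[stage]] <<- list(
      files = as.list(tools::md5sum(unlist(files))),
      params = params)
  }

  # -- stage 1: simulate / load ------------------------------------------
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(inputs)) {
      sim <- simulate_dataset(config$sim, second_enzyme = config$enzyme2)
      fa <- file.path(out_dir, "scaffolds.fasta")
      write_fasta(sim$scaffolds, fa)
      cm1 <- file.path(out_dir, "map1.cmap"); write_cmap(sim$map1, cm1)
      cm2 <- file.path(out_dir, "map2.cmap"); write_cmap(sim$map2, cm2)
      mkf <- file.path(out_dir, "markers.tsv")
      utils::write.table(sim$markers, mkf, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      list(scaffolds = sim$scaffolds, map1 = sim$map1, map2 = sim$map2,
           markers = sim$markers, sim = sim,
           files = c(fa, cm1, cm2, mkf))
    } else {
      list(scaffolds = read_fasta(inputs$fasta),
           map1 = read_cmap(inputs$cmap1),
           map2 = if (!is.null(inputs$cmap2) && file.exists(inputs$cmap2))
             read_cmap(inputs$cmap2),
           # markers are read lazily so their absence surfaces at the
           # anchor stage, not here
           markers_path = inputs$markers,
           sim = NULL,
           files = unlist(inputs[!purrr::map_lgl(inputs, is.null)]))
    }
  }, error = function(e) stage_failed(stage, e))
  note(stage, res$files,
       params = list(simulated = is.null(inputs)))
  scaffolds <- res$scaffolds

  # -- stage 2: digest ----------------------------------------------------
  stage <- "digest"
  dig <- tryCatch({
    d <- digest_sequences(scaffolds, config$enzyme1,
                          config$sim$min_label_distance_bp)
    f <- file.path(out_dir, "scaffolds_digest.cmap")
    write_cmap(d, f)
    note(stage, f, params = list(enzyme = config$enzyme1$name))
    d
  }, error = function(e) stage_failed(stage, e))

  # -- stage 3: align -----------------------------------------------------
  stage <- "align"
  p1 <- config$align
  p1$min_confidence <- config$confidence_ladder$initial
  p1$label_footprint_bp <- nchar(config$enzyme1$motif)
  aln1 <- tryCatch({
    a <- align_maps(dig, res$map1, p1)
    f <- file.path(out_dir, "round1.xmap")
    write_xmap(a, f)
    note(stage, f, params = list(min_confidence = p1$min_confidence))
    a
  }, error = function(e) stage_failed(stage, e))

  # -- stage 4: resolve ---------------------------------------------------
  stage <- "resolve"
  resolved <- tryCatch({
    conf <- detect_conflicts(aln1, config$tol)
    if (nrow(conf) > 0L && !is.null(res$map2)) {
      p2 <- config$align
      p2$min_confidence <- config$confidence_ladder$confirm
      p2$label_footprint_bp <- nchar(config$enzyme2$motif)
      dig2 <- digest_sequences(scaffolds, config$enzyme2,
                               config$sim$min_label_distance_bp)
      aln2 <- align_maps(
        dig2[dig2$map_id %in% conf$scaffold_id, , drop = FALSE],
        res$map2, p2)
      conf <- arbitrate_conflicts(conf, aln2, config$tol)
    }
    plans <- plan_splits(conf, find_n_runs(scaffolds))
    sp <- apply_splits(scaffolds, plans)
    f <- file.path(out_dir, "conflicts.tsv")
    utils::write.table(conf, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(stage, f, params = list(n_conflicts = nrow(conf),
                                 n_cuts = sum(!is.na(plans$cut_pos))))
    list(conflicts = conf, plans = plans, scaffolds = sp$scaffolds,
         provenance = sp$provenance)
  }, error = function(e) stage_failed(stage, e))

  # -- stage 5: scaffold (two rounds) ------------------------------------
  stage <- "scaffold"
  supers <- tryCatch({
    sc <- resolved$scaffolds
    dig <- digest_sequences(sc, config$enzyme1,
                            config$sim$min_label_distance_bp)
    aln <- align_maps(dig, res$map1, p1)
    bad <- unique(detect_conflicts(aln, config$tol)$scaffold_id)
    pl <- place_sequences(aln[!aln$query_id %in% bad, , drop = FALSE])
    gaps <- estimate_gaps(pl, min_gap = config$min_gap)
    round1 <- list(placements = pl, gaps = gaps)
    ss <- build_superscaffolds(pl, gaps, sc)
    if (!is.null(res$map2)) {
      pm <- config$align
      pm$min_confidence <- config$confidence_ladder$merge
      pm$label_footprint_bp <- nchar(config$enzyme2$motif)
      ss <- second_round(ss, sc, res$map2, enzyme = config$enzyme2,
                         params = pm, tol = config$tol,
                         min_label_distance_bp = config$sim$min_label_distance_bp,
                         min_gap = config$min_gap)
    } else {
      warn("no second map given: skipping the second scaffolding round")
    }
    em <- emit_sequences(ss, sc)
    write_fasta(em$sequences, file.path(out_dir, "superscaffolds.fasta"))
    write_agp(em$agp, file.path(out_dir, "superscaffolds.agp"))
    note(stage, file.path(out_dir, c("superscaffolds.fasta",
                                     "superscaffolds.agp")),
         params = list(n_super = length(unique(ss$super_id))))
    list(supers = ss, emitted = em, scaffolds = sc,
         placements = round1$placements, gaps = round1$gaps)
  }, error = function(e) stage_failed(stage, e))

  # -- stage 6: anchor ----------------------------------------------------
  stage <- "anchor"
  pseudo <- tryCatch({
    if (is.null(res$markers) && !is.null(res$markers_path)) {
      if (!file.exists(res$markers_path)) {
        abort(sprintf("marker file not found: %s", res$markers_path))
      }
      res$markers <- as_tibble(utils::read.delim(res$markers_path))
    }
    if (is.null(res$markers)) abort("no marker table available")
    mk <- lift_markers(res$markers, resolved$provenance)
    asg <- assign_chromosomes(mk, supers$supers,
                              min_markers = config$anchor$min_markers)
    ord <- order_and_orient(asg, mk, supers$supers)
    ps <- build_pseudomolecules(ord, supers$emitted$sequences,
                                gap_n = config$anchor$gap_n)
    write_fasta(ps$sequences, file.path(out_dir, "pseudomolecules.fasta"))
    write_agp(ps$agp, file.path(out_dir, "pseudomolecules.agp"))
    rep <- report_tables(ps)
    utils::write.table(rep, file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note(stage, file.path(out_dir, c("pseudomolecules.fasta",
                                     "pseudomolecules.agp", "report.tsv")),
         params = list(gap_n = config$anchor$gap_n))
    ps
  }, error = function(e) stage_failed(stage, e))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = res$sim, digest = dig, alignments = aln1,
                 conflicts = resolved$conflicts, plans = resolved$plans,
                 provenance = resolved$provenance,
                 scaffolds = supers$scaffolds,
                 placements = supers$placements, gaps = supers$gaps,
                 supers = supers$supers, pseudo = pseudo,
                 manifest = manifest))
}
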