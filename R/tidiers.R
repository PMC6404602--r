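# broom-style tidiers for the package's composite result objects.

#' @exportS3Method generics::tidy
tidy.optscaf_superscaffolds <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.optscaf_superscaffolds <- function(x, ...) {
  lens <- super_lengths(x)
  tibble(n_superscaffolds = nrow(lens),
         n_members = nrow(x),
         n_known_gaps = sum(!is.na(x$gap_after_bp) & x$gap_after_bp >= 0),
         n_unknown_gaps = sum(!is.na(x$gap_after_bp) & x$gap_after_bp < 0),
         total_bp = sum(lens$length_bp),
         n50_bp = n50(lens$length_bp))
}

#' @exportS3Method generics::tidy
tidy.pseudomolecule_set <- function(x, ...) {
  bind_rows(
    mutate(x$anchored, placement = "anchored"),
    tibble(chrom = "ChrUn", position_index = NA_integer_,
           super_id = x$chrun$seq_id, orientation = "+",
           orientation_determined = FALSE, mean_cm = NA_real_,
           n_markers = 0L, length_bp = x$chrun$length_bp,
           placement = "unplaced"))
}

#' @exportS3Method generics::glance
glance.pseudomolecule_set <- function(x, ...) {
  rep <- report_tables(x)
  tot <- rep[rep$chrom == "Total", ]
  tibble(n_chromosomes = nrow(x$sequences),
         n_anchored = nrow(x$anchored),
         n_chrun = nrow(x$chrun),
         total_bp = tot$length_bp,
         effective_bp = tot$effective_bp,
         n_pct = tot$n_pct,
         n_unknown_gaps = tot$n_unknown_gaps)
}

#' @exportS3Method generics::tidy
tidy.optscaf_sim <- function(x, ...) {
  x$truth$placements
}

#' @exportS3Method generics::glance
glance.optscaf_sim <- function(x, ...) {
  tibble(n_chromosomes = x$config$n_chromosomes,
         genome_bp = x$config$n_chromosomes * x$config$chromosome_length_bp,
         n_scaffolds = nrow(x$scaffolds),
         n_chimeras = nrow(x$truth$chimeras),
         n_map1_contigs = length(unique(x$map1$map_id)),
         n_map2_contigs = length(unique(x$map2$map_id)),
         n_markers = nrow(x$markers))
}
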