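# ggplot2 views of alignments, super-scaffold layouts and assembly
# progression.

#' Plot a label alignment
#'
#' The classic optical-map view: query labels above, reference labels
#' below, aligned pairs connected; conflicts show up as crossing or
#' interrupted connectors.
#'
#' @param alignments Alignment tibble from [align_maps()].
#' @param query One query id to plot (defaults to the first).
#' @return A ggplot object.
#' @export
plot_alignment <- function(alignments, query = NULL) {
  query <- query %||% alignments$query_id[1]
  al <- alignments[alignments$query_id == query, , drop = FALSE]
  if (nrow(al) == 0L) abort(sprintf("no alignment for query %s", query))
  seg <- purrr::map2(al$pairs, seq_len(nrow(al)), function(p, i) {
    tibble(q_pos = p$q_pos, r_pos = p$r_pos,
           ref = paste0(al$ref_id[i], " (", al$orientation[i], ")"))
  }) |> bind_rows()
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$q_pos, xend = .data$r_pos,
                                       y = 1, yend = 0,
                                       colour = .data$ref),
                          linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(x = .data$q_pos, y = 1), size = 0.6) +
    ggplot2::geom_point(ggplot2::aes(x = .data$r_pos, y = 0,
                                     colour = .data$ref), size = 0.6) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("reference", query)) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "reference") +
    ggplot2::theme_minimal()
}

#' Plot a super-scaffold layout
#'
#' Members drawn as arrows along the assembled coordinate, gaps as
#' breaks — the reconstruction view of a map contig.
#'
#' @param supers Super-scaffold tibble from [build_superscaffolds()].
#' @param super One super-scaffold id (defaults to the largest).
#' @return A ggplot object.
#' @export
plot_superscaffold <- function(supers, super = NULL) {
  lens <- super_lengths(supers)
  super <- super %||% lens$super_id[which.max(lens$length_bp)]
  mem <- supers[supers$super_id == super, , drop = FALSE]
  if (nrow(mem) == 0L) abort(sprintf("no super-scaffold %s", super))
  mem <- mem[order(mem$member_index), ]
  gap <- if_else(is.na(mem$gap_after_bp), 0,
                 if_else(mem$gap_after_bp < 0, 100, mem$gap_after_bp))
  start <- cumsum(dplyr::lag(mem$length_bp + gap, default = 0))
  df <- mutate(as_tibble(mem), start = start,
               end = start + .data$length_bp)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = if_else(.data$orientation == "+", .data$start, .data$end),
                   xend = if_else(.data$orientation == "+", .data$end, .data$start),
                   y = 1, yend = 1, colour = .data$seq_id),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      linewidth = 2, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = 1.08, label = .data$seq_id),
                       size = 2.5, angle = 30) +
    ggplot2::ylim(0.8, 1.3) +
    ggplot2::labs(x = "super-scaffold position (bp)", y = NULL,
                  title = super) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.optscaf_superscaffolds <- function(object, ...) {
  plot_superscaffold(object, ...)
}

#' Plot N50 progression across scaffolding rounds
#'
#' @param stats_list Named list of [assembly_stats()] rows, in round
#'   order.
#' @return A ggplot object.
#' @export
plot_n50_progression <- function(stats_list) {
  df <- bind_rows(stats_list, .id = "round") |>
    mutate(round = factor(.data$round, levels = names(stats_list)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$n50_bp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "N50 (bp)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pseudomolecule_set <- function(object, ...) {
  df <- object$agp |>
    filter(.data$component_type == "W") |>
    mutate(chrom = .data$object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$object_beg,
                                       xend = .data$object_end,
                                       y = .data$chrom, yend = .data$chrom,
                                       colour = .data$orientation),
                          linewidth = 4) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  colour = "orientation") +
    ggplot2::theme_minimal()
}
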