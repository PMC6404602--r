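# CMAP / XMAP readers and writers (the Bionano tab-separated dialects).

cmap_empty <- function() {
  tibble(map_id = character(), length_bp = double(), site_id = integer(),
         position = double(), channel = integer())
}

validate_cmap <- function(cmap, file = NULL) {
  ctx <- if (is.null(file)) "" else sprintf(" in %s", file)
  by_map <- split(cmap, cmap$map_id)
  for (m in by_map) {
    p <- m$position
    if (any(diff(p) <= 0)) {
      abort(sprintf("non-monotone label positions for map %s%s",
                    m$map_id[1], ctx))
    }
    if (any(p < 1 | p > m$length_bp)) {
      abort(sprintf("label position outside [1, length] for map %s%s",
                    m$map_id[1], ctx))
    }
  }
  invisible(cmap)
}

#' Read and write CMAP label-map files
#'
#' The standard tab-separated CMAP dialect: `#`-prefixed header lines and
#' at least the columns CMapId, ContigLength, NumSites, SiteID,
#' LabelChannel, Position.  On write, each map gains the conventional
#' terminal LabelChannel-0 row at the contig end; it is dropped again on
#' read.  Malformed headers and non-monotone positions are rejected with
#' file context.
#'
#' @param path File path.
#' @return `read_cmap()` returns a label-map tibble (`map_id`,
#'   `length_bp`, `site_id`, `position`, `channel`).
#' @export
read_cmap <- function(path) {
  if (!file.exists(path)) abort(sprintf("CMAP file not found: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#h", lines, value = TRUE)
  if (length(hdr) != 1L) {
    abort(sprintf("malformed CMAP %s: expected exactly one '#h' header line",
                  path))
  }
  cols <- strsplit(sub("^#h\\s*", "", hdr), "\t")[[1]]
  need <- c("CMapId", "ContigLength", "NumSites", "SiteID", "LabelChannel",
            "Position")
  if (!all(need %in% cols)) {
    abort(sprintf("malformed CMAP %s: missing columns %s", path,
                  paste(setdiff(need, cols), collapse = ", ")))
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) return(cmap_empty())
  mat <- strsplit(body, "\t")
  nfield <- lengths(mat)
  if (any(nfield != length(cols))) {
    bad <- which(nfield != length(cols))[1]
    abort(sprintf("malformed CMAP %s: line %d has %d fields, expected %d",
                  path, bad, nfield[bad], length(cols)))
  }
  df <- as.data.frame(do.call(rbind, mat), stringsAsFactors = FALSE)
  names(df) <- cols
  out <- tibble(
    map_id = as.character(df$CMapId),
    length_bp = as.double(df$ContigLength),
    site_id = as.integer(df$SiteID),
    position = as.double(df$Position),
    channel = as.integer(df$LabelChannel)
  )
  if (anyNA(out$position) || anyNA(out$length_bp)) {
    abort(sprintf("malformed CMAP %s: non-numeric Position/ContigLength", path))
  }
  out <- filter(out, .data$channel != 0L)
  validate_cmap(out, file = path)
  out
}

#' @rdname read_cmap
#' @param cmap A label-map tibble.
#' @export
write_cmap <- function(cmap, path) {
  validate_cmap(cmap)
  hdr <- c(
    "# CMAP File Version:\t0.2",
    "# Label Channels:\t1",
    paste0("#h\t", paste(c("CMapId", "ContigLength", "NumSites", "SiteID",
                           "LabelChannel", "Position"), collapse = "\t")),
    "#f\tstring\tfloat\tint\tint\tint\tfloat"
  )
  rows <- cmap |>
    group_by(.data$map_id) |>
    mutate(num_sites = max(.data$site_id)) |>
    ungroup()
  # terminal channel-0 anchor row at the contig end, one per map
  ends <- rows |>
    group_by(.data$map_id) |>
    summarise(length_bp = first(.data$length_bp),
              num_sites = first(.data$num_sites), .groups = "drop") |>
    mutate(site_id = .data$num_sites + 1L, position = .data$length_bp,
           channel = 0L)
  all_rows <- bind_rows(rows, ends) |>
    arrange(.data$map_id, .data$site_id)
  lines <- sprintf("%s\t%.1f\t%d\t%d\t%d\t%.1f",
                   all_rows$map_id, all_rows$length_bp, all_rows$num_sites,
                   all_rows$site_id, all_rows$channel, all_rows$position)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

map_positions <- function(cmap, id) {
  cmap$position[cmap$map_id == id]
}

map_length <- function(cmap, id) {
  cmap$length_bp[match(id, cmap$map_id)]
}

#' Mirror a label map
#'
#' Flips a label map end-for-end.  `footprint_bp` is the bp extent of the
#' label motif: a label recorded at the 1-based start `p` of a motif
#' match maps to the start of the mirrored match,
#' `length - p - footprint + 2` (for point labels use `footprint_bp = 1`).
#'
#' @param cmap A label-map tibble.
#' @param footprint_bp Label footprint in bp.
#' @return The mirrored label-map tibble.
#' @export
flip_map <- function(cmap, footprint_bp = 1L) {
  cmap |>
    group_by(.data$map_id) |>
    mutate(position = sort(.data$length_bp - .data$position - footprint_bp + 2),
           site_id = row_number()) |>
    ungroup()
}
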