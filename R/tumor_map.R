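#' Construct a tumor map
#'
#' A tumor map is the per-tile class-label grid produced by
#' [classify_slide()]: integer codes 0 (background / unclassified tile) and
#' 1..5 for AC, MP, SO, CR, NT, aligned to the slide's tile grid.
#'
#' @param labels integer matrix (grid rows x grid cols) of codes 0..5.
#' @param tile_px tile edge length in level-0 pixels.
#' @param slide_id slide identifier.
#' @return `gp_tumor_map`: list with `labels`, `tile_px`, `slide_id` and
#'   per-class tile `counts`.
#' @export
new_tumor_map <- function(labels, tile_px, slide_id = "slide") {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 5L)) {
    stop("tumor map codes must be in 0..5", call. = FALSE)
  }
  counts <- stats::setNames(tabulate(labels[labels > 0L], nbins = 5),
                            gp_classes())
  structure(list(labels = labels, tile_px = as.integer(tile_px),
                 slide_id = slide_id, counts = counts),
            class = "gp_tumor_map")
}

#' @export
print.gp_tumor_map <- function(x, ...) {
  cat(sprintf("<gp_tumor_map '%s'> %d x %d tiles of %d px; counts: %s\n",
              x$slide_id, ncol(x$labels), nrow(x$labels), x$tile_px,
              paste(names(x$counts), x$counts, sep = "=", collapse = " ")))
  invisible(x)
}

# Largest-remainder rounding of percentages to multiples of `step` so the
# rounded values sum to exactly 100.
round_percent_largest_remainder <- function(p, step = 5) {
  q <- p / step
  base <- floor(q)
  left <- round(100 / step) - sum(base)
  if (left > 0) {
    rem <- q - base
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  base * step
}

#' Per-class percentage summary of a tumor map
#'
#' Two summaries, mirroring how growth patterns are reported: (a) each
#' class as a percentage of all tissue tiles and (b) each tumor class (AC,
#' MP, SO, CR) as a percentage of tumor tiles. With `round_to_5 = TRUE`
#' the tumor-relative percentages are rounded to the nearest 5% increment
#' with a largest-remainder correction so they still sum to 100.
#'
#' @param map `gp_tumor_map`.
#' @param round_to_5 round tumor-relative percentages to 5% increments.
#' @return list with `tissue_pct` (named length-5), `tumor_pct` (named
#'   length-4), `n_tissue_tiles`, `n_tumor_tiles`. All-background maps
#'   yield an empty summary with a warning.
#' @export
class_percentages <- function(map, round_to_5 = FALSE) {
  stopifnot(inherits(map, "gp_tumor_map"))
  n_tissue <- sum(map$counts)
  if (n_tissue == 0L) {
    warning("all-background tumor map: no tissue tiles to summarize")
    return(list(tissue_pct = stats::setNames(numeric(0), character(0)),
                tumor_pct = stats::setNames(numeric(0), character(0)),
                n_tissue_tiles = 0L, n_tumor_tiles = 0L))
  }
  tissue_pct <- 100 * map$counts / n_tissue
  tumor_counts <- map$counts[c("AC", "MP", "SO", "CR")]
  n_tumor <- sum(tumor_counts)
  tumor_pct <- if (n_tumor > 0) 100 * tumor_counts / n_tumor else
    stats::setNames(rep(0, 4), names(tumor_counts))
  if (round_to_5 && n_tumor > 0) {
    tumor_pct <- stats::setNames(
      round_percent_largest_remainder(tumor_pct, 5), names(tumor_counts))
  }
  list(tissue_pct = tissue_pct, tumor_pct = tumor_pct,
       n_tissue_tiles = n_tissue, n_tumor_tiles = n_tumor)
}

#' Render a tumor map as a color overlay on the slide
#'
#' Alpha-blends the fixed class palette ([gp_palette()]) over a
#' low-magnification rendering of the slide; background tiles are left
#' untouched. Pure function of its inputs: the label grid is never
#' modified.
#'
#' @param map `gp_tumor_map`.
#' @param slide `gp_slide` sharing the map's frame.
#' @param alpha blend weight of the class color in \[0, 1\] (default 0.5;
#'   1 = pure palette colors over tissue tiles).
#' @param downsample rendering downsample (default: the coarsest stored
#'   level).
#' @param palette named class -> hex color vector.
#' @return RGB array of the rendered overlay.
#' @export
render_overlay <- function(map, slide, alpha = 0.5, downsample = NULL,
                           palette = gp_palette()) {
  stopifnot(inherits(map, "gp_tumor_map"), inherits(slide, "gp_slide"))
  if (!identical(map$slide_id, slide$id)) {
    stop("tumor map and slide frames do not match", call. = FALSE)
  }
  if (is.null(downsample)) downsample <- max(slide$downsamples)
  lev <- slide_level_at(slide, downsample)
  d <- lev$downsample
  out <- lev$raster
  pal_rgb <- grDevices::col2rgb(palette[gp_classes()])
  tpx <- map$tile_px / d
  for (r in seq_len(nrow(map$labels))) {
    for (cl in seq_len(ncol(map$labels))) {
      code <- map$labels[r, cl]
      if (code == 0L) next
      rows <- (floor((r - 1) * tpx) + 1):min(floor(r * tpx), dim(out)[1])
      cols <- (floor((cl - 1) * tpx) + 1):min(floor(cl * tpx), dim(out)[2])
      for (ch in 1:3) {
        out[rows, cols, ch] <- (1 - alpha) * out[rows, cols, ch] +
          alpha * pal_rgb[ch, code]
      }
    }
  }
  out
}

#' Serialize a tumor map to JSON
#'
#' Writes grid shape, tile size, row-major labels and per-class counts.
#'
#' @param map `gp_tumor_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tumor_map <- function(map, path) {
  payload <- list(
    slide_id = map$slide_id, tile_px = map$tile_px,
    shape = c(nrow(map$labels), ncol(map$labels)),
    labels = as.integer(t(map$labels)),
    counts = as.list(map$counts)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tumor map written by [write_tumor_map()]
#'
#' @param path JSON path.
#' @return `gp_tumor_map`.
#' @export
read_tumor_map <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- matrix(as.integer(p$labels), nrow = p$shape[1],
                   ncol = p$shape[2], byrow = TRUE)
  new_tumor_map(labels, p$tile_px, p$slide_id)
}
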