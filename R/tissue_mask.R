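#' Locate foreground tissue at low magnification
#'
#' Converts the ~5x rendering of the slide to gray (standard luma), marks
#' pixels darker than the intensity threshold `t` as tissue foreground
#' against the white optical background, then refines the mask by hole
#' filling (background components not connected to the raster border) and
#' binary morphological closing with a square structuring element.
#'
#' If the slide has no stored level at the target magnification, the nearest
#' stored level at or beyond the required downsample is used and the
#' threshold is applied unchanged.
#'
#' @param slide `gp_slide`.
#' @param t gray-level cutoff in \[0, 255\] (default 230); pixels with
#'   luma < `t` are foreground.
#' @param target_magnification magnification at which masking is performed
#'   (default 5).
#' @param closing_px edge of the square closing element (default 5).
#' @param luma_weights RGB luma weights (default BT.601).
#' @param min_tissue_fraction tile-retention cutoff stored with the mask
#'   (default 0.20); see [filter_tiles()].
#' @return `gp_tissue_mask`: list with logical `mask`, `mask_downsample`
#'   (level-0 px per mask px), `t`, `min_tissue_fraction`, `slide_id`.
#' @export
compute_tissue_mask <- function(slide, t = 230, target_magnification = 5,
                                closing_px = 5,
                                luma_weights = c(0.299, 0.587, 0.114),
                                min_tissue_fraction = 0.20) {
  stopifnot(inherits(slide, "gp_slide"))
  if (t < 0 || t > 255) stop("t must be in [0, 255]", call. = FALSE)
  if (min_tissue_fraction <= 0 || min_tissue_fraction > 1) {
    stop("min_tissue_fraction must be in (0, 1]", call. = FALSE)
  }
  want_ds <- max(1L, round(slide$magnification / target_magnification))
  lev <- slide_level_at(slide, want_ds)
  gray <- luma(lev$raster, luma_weights)
  fg <- gray < t
  storage.mode(fg) <- "integer"
  fg <- EBImage::fillHull(fg)
  if (closing_px > 1) {
    fg <- EBImage::closing(fg, EBImage::makeBrush(as.integer(closing_px),
                                                  shape = "box"))
  }
  structure(
    list(mask = fg > 0, mask_downsample = lev$downsample, t = t,
         min_tissue_fraction = min_tissue_fraction, slide_id = slide$id),
    class = "gp_tissue_mask"
  )
}

#' @export
print.gp_tissue_mask <- function(x, ...) {
  cat(sprintf(
    "<gp_tissue_mask> %d x %d at downsample %d, t=%g, %.1f%% foreground\n",
    ncol(x$mask), nrow(x$mask), x$mask_downsample, x$t, 100 * mean(x$mask)))
  invisible(x)
}

#' Filter a tile grid by tissue content
#'
#' A tile is retained iff the fraction of its footprint covered by mask
#' foreground is >= `min_tissue_fraction` (tiles with strictly less are
#' deleted; a tile at exactly the cutoff is kept). Fractions are computed
#' on the mask raster over the tile's downsampled footprint.
#'
#' @param grid `gp_tile_grid`.
#' @param mask `gp_tissue_mask` for the same slide.
#' @param min_tissue_fraction retention cutoff; defaults to the value stored
#'   in the mask (0.20).
#' @return `gp_tile_grid` containing the retained subset of tiles (full-grid
#'   extent `nx`, `ny` unchanged).
#' @export
filter_tiles <- function(grid, mask,
                         min_tissue_fraction = mask$min_tissue_fraction) {
  stopifnot(inherits(grid, "gp_tile_grid"), inherits(mask, "gp_tissue_mask"))
  if (!identical(grid$slide_id, mask$slide_id)) {
    stop("tile grid and tissue mask refer to different slides (",
         grid$slide_id, " vs ", mask$slide_id, ")", call. = FALSE)
  }
  d <- mask$mask_downsample
  keep <- vapply(seq_len(nrow(grid$tiles)), function(i) {
    x <- grid$tiles$x[i]; y <- grid$tiles$y[i]
    r0 <- floor(y / d) + 1L
    r1 <- min(ceiling((y + grid$tile_px) / d), nrow(mask$mask))
    c0 <- floor(x / d) + 1L
    c1 <- min(ceiling((x + grid$tile_px) / d), ncol(mask$mask))
    mean(mask$mask[r0:r1, c0:c1]) >= min_tissue_fraction
  }, logical(1))
  out <- grid
  out$tiles <- grid$tiles[keep, , drop = FALSE]
  rownames(out$tiles) <- NULL
  out
}
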