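#' Construct a slide object from an in-memory RGB raster
#'
#' A slide is a small pyramid of RGB rasters with pixel-size and
#' magnification metadata. Level 1 (downsample 1) is the full-resolution
#' raster; coarser levels are synthesized by integer-factor block-mean
#' downsampling on demand.
#'
#' @param rgb numeric array `c(height, width, 3)`, values in \[0, 255\].
#' @param pixel_size_um microns per pixel at level 0 (must be > 0).
#' @param magnification nominal objective power of level 0 (e.g. 20 or 40).
#' @param downsamples integer downsample factors to store; must start at 1
#'   and be strictly increasing.
#' @param id slide identifier (used in reports).
#' @return An object of class `gp_slide` with fields `levels` (list of
#'   rasters), `downsamples`, `pixel_size_um`, `magnification`, `width_px`,
#'   `height_px`, `id`.
#' @export
new_slide <- function(rgb, pixel_size_um, magnification = 20,
                      downsamples = c(1L, 4L), id = "slide") {
  assert_rgb(rgb, "slide raster")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0", call. = FALSE)
  }
  downsamples <- as.integer(downsamples)
  if (downsamples[1] != 1L || is.unsorted(downsamples, strictly = TRUE)) {
    stop("downsamples must start at 1 and be strictly increasing",
         call. = FALSE)
  }
  levels <- vector("list", length(downsamples))
  levels[[1]] <- rgb
  for (i in seq_along(downsamples)[-1]) {
    levels[[i]] <- block_downsample(rgb, downsamples[i])
  }
  structure(
    list(levels = levels, downsamples = downsamples,
         pixel_size_um = pixel_size_um, magnification = magnification,
         width_px = dim(rgb)[2], height_px = dim(rgb)[1], id = id),
    class = "gp_slide"
  )
}

#' @export
print.gp_slide <- function(x, ...) {
  cat(sprintf(
    "<gp_slide '%s'> %d x %d px @ %gx (%g um/px), levels: %s\n",
    x$id, x$width_px, x$height_px, x$magnification, x$pixel_size_um,
    paste(x$downsamples, collapse = ", ")))
  invisible(x)
}

#' Open a slide image file
#'
#' Reads pyramid TIFF (each page a level) or single-resolution PNG/TIFF.
#' Single-resolution files become a pyramid with synthesized coarser levels
#' by integer-factor block-mean downsampling; stored pyramid levels are
#' preserved with their stored downsample factors.
#'
#' @param path file path (png/tif/tiff).
#' @param pixel_size_um microns per pixel at level 0. PNG and plain TIFF
#'   carry no physical metadata, so this must be supplied (directly or from
#'   config); missing metadata is an error.
#' @param magnification nominal objective power at level 0 (default 20).
#' @param synth_downsamples downsample factors synthesized for
#'   single-resolution inputs (default `c(1, 4)`, i.e. a 5x-equivalent
#'   level for a 20x scan).
#' @return `gp_slide` object.
#' @export
open_slide <- function(path, pixel_size_um = NULL, magnification = 20,
                       synth_downsamples = c(1L, 4L)) {
  if (!file.exists(path)) stop("slide file not found: ", path, call. = FALSE)
  if (is.null(pixel_size_um)) {
    stop("pixel size metadata missing for '", basename(path),
         "': supply pixel_size_um (file formats png/tiff carry none)",
         call. = FALSE)
  }
  pages <- tryCatch(read_rgb_file(path),
                    error = function(e) stop("failed to read slide '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
  if (length(pages) == 1L) {
    return(new_slide(pages[[1]], pixel_size_um, magnification,
                     downsamples = synth_downsamples,
                     id = tools::file_path_sans_ext(basename(path))))
  }
  w0 <- dim(pages[[1]])[2]
  ds <- vapply(pages, function(p) round(w0 / dim(p)[2]), numeric(1))
  o <- order(ds)
  slide <- new_slide(pages[[o[1]]], pixel_size_um, magnification,
                     downsamples = 1L,
                     id = tools::file_path_sans_ext(basename(path)))
  slide$levels <- pages[o]
  slide$downsamples <- as.integer(ds[o])
  slide
}

#' Extract a level-0 rectangular region from a slide
#'
#' @param slide `gp_slide`.
#' @param x,y 0-based level-0 top-left corner.
#' @param w,h region width/height in level-0 pixels.
#' @return RGB array `c(h, w, 3)`.
#' @export
slide_region <- function(slide, x, y, w, h) {
  stopifnot(inherits(slide, "gp_slide"))
  if (x < 0 || y < 0 || x + w > slide$width_px || y + h > slide$height_px) {
    stop("requested region exceeds slide bounds", call. = FALSE)
  }
  slide$levels[[1]][(y + 1):(y + h), (x + 1):(x + w), , drop = FALSE]
}

# Raster of the stored level whose downsample is nearest >= `downsample`
# (exact match preferred); returns list(raster, downsample).
slide_level_at <- function(slide, downsample) {
  ds <- slide$downsamples
  i <- which(ds == downsample)
  if (length(i) == 0L) i <- which(ds >= downsample)[1]
  if (is.na(i) || length(i) == 0L) i <- length(ds)
  list(raster = slide$levels[[i]], downsample = ds[i])
}

#' Tile edge length matching a reference physical area
#'
#' Cross-scanner area matching: the tile edge in pixels is scaled so that the
#' physical tile area equals the reference tile's (600 px at the reference
#' 20x pixel size by default), i.e.
#' `round(reference_tile_px * reference_pixel_size_um / pixel_size_um)`.
#'
#' @param pixel_size_um microns per pixel of the slide to be tiled.
#' @param reference_tile_px reference tile edge in pixels (default 600).
#' @param reference_pixel_size_um pixel size at which the reference edge is
#'   defined (default 0.5).
#' @return integer tile edge in pixels.
#' @export
#' @examples
#' tile_size_for_area(0.25, 600, 0.5)  # 1200
tile_size_for_area <- function(pixel_size_um, reference_tile_px = 600,
                               reference_pixel_size_um = 0.5) {
  if (any(c(pixel_size_um, reference_tile_px, reference_pixel_size_um) <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  as.integer(round(reference_tile_px * reference_pixel_size_um /
                     pixel_size_um))
}

#' Build a non-overlapping tile grid over a slide
#'
#' Tiles are axis-aligned squares of `tile_px` level-0 pixels placed at
#' multiples of `tile_px` from the origin; half-open intervals
#' `[x, x + tile_px)`. Partial edge tiles that would exceed the slide bounds
#' are omitted.
#'
#' @param slide `gp_slide`.
#' @param tile_px tile edge length in level-0 pixels.
#' @return `gp_tile_grid`: list with `tile_px`, `nx`, `ny` (full-grid
#'   extent), `tiles` (data.frame of 0-based `x`, `y` and 1-based grid
#'   `col`, `row`), `slide_dim` `(width, height)` and `slide_id`.
#' @export
build_tile_grid <- function(slide, tile_px) {
  stopifnot(inherits(slide, "gp_slide"))
  tile_px <- as.integer(tile_px)
  if (tile_px <= 0) stop("tile_px must be > 0", call. = FALSE)
  if (tile_px > min(slide$width_px, slide$height_px)) {
    stop("tile_px (", tile_px, ") exceeds slide dimensions ",
         slide$width_px, " x ", slide$height_px, call. = FALSE)
  }
  nx <- slide$width_px %/% tile_px
  ny <- slide$height_px %/% tile_px
  tiles <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  tiles <- data.frame(
    x = (tiles$col - 1L) * tile_px, y = (tiles$row - 1L) * tile_px,
    col = tiles$col, row = tiles$row
  )
  structure(
    list(tile_px = tile_px, nx = nx, ny = ny, tiles = tiles,
         slide_dim = c(width = slide$width_px, height = slide$height_px),
         slide_id = slide$id),
    class = "gp_tile_grid"
  )
}

#' @export
print.gp_tile_grid <- function(x, ...) {
  cat(sprintf("<gp_tile_grid> %d tiles of %d px (%d x %d grid) on '%s'\n",
              nrow(x$tiles), x$tile_px, x$nx, x$ny, x$slide_id))
  invisible(x)
}

#' Parse Aperio ImageScope annotation XML
#'
#' Reads the `Annotations/Annotation/Regions/Region/Vertices/Vertex`
#' dialect. The class label is taken from a named attribute of each
#' `Region` element (default `"Text"`) and mapped to the five-class
#' enumeration; unknown labels are an error listing the offending strings.
#' Vertex coordinates are interpreted as level-0 pixels.
#'
#' @param path XML file path.
#' @param label_attribute attribute carrying the class label.
#' @param label_map optional named character vector of extra
#'   label-string -> class-code mappings.
#' @return `gp_annotations`: list with `regions`, each a list of
#'   `vertices` (two-column matrix x, y) and `label` (class code).
#' @export
parse_imagescope_xml <- function(path, label_attribute = "Text",
                                 label_map = NULL) {
  doc <- xml2::read_xml(path)
  region_nodes <- xml2::xml_find_all(
    doc, "//Annotation/Regions/Region | /Annotations/Annotation/Regions/Region")
  regions <- lapply(region_nodes, function(node) {
    label_raw <- xml2::xml_attr(node, label_attribute)
    if (is.na(label_raw)) {
      stop("Region without a '", label_attribute, "' label attribute",
           call. = FALSE)
    }
    vx <- xml2::xml_find_all(node, "./Vertices/Vertex")
    verts <- cbind(
      x = as.numeric(xml2::xml_attr(vx, "X")),
      y = as.numeric(xml2::xml_attr(vx, "Y"))
    )
    if (nrow(verts) < 3L) {
      stop("annotation polygon with fewer than 3 vertices", call. = FALSE)
    }
    list(vertices = verts, label = canonical_class(label_raw, label_map))
  })
  structure(list(regions = regions), class = "gp_annotations")
}

#' @export
print.gp_annotations <- function(x, ...) {
  labs <- vapply(x$regions, `[[`, character(1), "label")
  cat(sprintf("<gp_annotations> %d region(s): %s\n", length(labs),
              paste(labs, collapse = ", ")))
  invisible(x)
}

#' Write an annotation set as Aperio ImageScope XML
#'
#' Inverse of [parse_imagescope_xml()]; used by the synthetic slide
#' generator so that generated ground truth round-trips through the same
#' reader as real annotations.
#'
#' @param ann `gp_annotations`.
#' @param path output XML path.
#' @param label_attribute attribute name to carry the class label.
#' @return `path`, invisibly.
#' @export
write_imagescope_xml <- function(ann, path, label_attribute = "Text") {
  stopifnot(inherits(ann, "gp_annotations"))
  doc <- xml2::xml_new_root("Annotations")
  anno <- xml2::xml_add_child(doc, "Annotation", Id = "1")
  regs <- xml2::xml_add_child(anno, "Regions")
  for (i in seq_along(ann$regions)) {
    region <- ann$regions[[i]]
    rn <- xml2::xml_add_child(regs, "Region", Id = as.character(i))
    xml2::xml_set_attr(rn, label_attribute, region$label)
    vs <- xml2::xml_add_child(rn, "Vertices")
    for (j in seq_len(nrow(region$vertices))) {
      xml2::xml_add_child(vs, "Vertex",
                          X = format(region$vertices[j, 1], scientific = FALSE),
                          Y = format(region$vertices[j, 2], scientific = FALSE))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# Even-odd point-in-polygon for a lattice of pixel centers, vectorized over
# one polygon edge at a time. `cx`, `cy` are vectors of pixel-center
# coordinates; returns a logical matrix length(cy) x length(cx).
polygon_fill_mask <- function(vertices, cx, cy) {
  nx <- length(cx); ny <- length(cy)
  crossings <- matrix(0L, ny, nx)
  v <- vertices
  n <- nrow(v)
  px <- matrix(cx, ny, nx, byrow = TRUE)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    if (y1 == y2) next
    # rows whose center y is spanned by the edge (half-open in y)
    spans <- (cy >= pmin(y1, y2)) & (cy < pmax(y1, y2))
    if (!any(spans)) next
    xi <- x1 + (cy[spans] - y1) * (x2 - x1) / (y2 - y1)
    crossings[spans, ] <- crossings[spans, ] +
      (px[spans, , drop = FALSE] > xi)
  }
  crossings %% 2L == 1L
}

#' Rasterize ground-truth annotation polygons
#'
#' Fills each polygon with its class code (AC=1, MP=2, SO=3, CR=4, NT=5) at
#' the requested downsample; pixels outside all polygons are 0 (excluded
#' from evaluation). A pixel belongs to a polygon when its center is inside
#' under the even-odd rule. Overlapping polygons of different classes are an
#' error by default; `overlap = "last-wins"` lets later regions overwrite
#' earlier ones.
#'
#' @param ann `gp_annotations`.
#' @param slide `gp_slide` providing the frame dimensions.
#' @param downsample integer >= 1; mask resolution in level-0 px per mask px.
#' @param overlap `"error"` (default) or `"last-wins"`.
#' @return `gp_gt_mask`: list with integer `raster` (values 0..5),
#'   `downsample`, `slide_id`.
#' @export
rasterize_annotations <- function(ann, slide, downsample = 1,
                                  overlap = c("error", "last-wins")) {
  stopifnot(inherits(ann, "gp_annotations"), inherits(slide, "gp_slide"))
  overlap <- match.arg(overlap)
  d <- as.integer(downsample)
  if (d < 1L) stop("downsample must be >= 1", call. = FALSE)
  nx <- slide$width_px %/% d
  ny <- slide$height_px %/% d
  # pixel centers in level-0 coordinates
  cx <- ((seq_len(nx) - 0.5) * d)
  cy <- ((seq_len(ny) - 0.5) * d)
  raster <- matrix(0L, ny, nx)
  for (region in ann$regions) {
    code <- match(region$label, gp_classes())
    inside <- polygon_fill_mask(region$vertices, cx, cy)
    clash <- inside & raster != 0L & raster != code
    if (any(clash) && overlap == "error") {
      stop("overlapping annotation polygons of different classes ",
           "(use overlap = \"last-wins\" to let later regions take ",
           "precedence)", call. = FALSE)
    }
    raster[inside] <- code
  }
  structure(list(raster = raster, downsample = d, slide_id = slide$id),
            class = "gp_gt_mask")
}
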