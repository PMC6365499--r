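# Seeded synthetic histology stand-ins. Textures are procedural and
# feature-separable by construction (foreground density, component count and
# size, lumina per component) -- they emulate the *statistical* structure of
# H&E growth patterns (dark-stained tumor elements on a bright background,
# pale non-tumor stroma, two lab-dependent base palettes), not nuclear
# morphology.

# Two pseudo-cohort H&E palettes (inter-lab stain variance): RGB triples.
gp_synth_palettes <- function() {
  list(
    site_a = list(bg = c(247, 244, 246), tumor = c(98, 62, 148),
                  nt = c(226, 199, 213)),
    site_b = list(bg = c(250, 240, 244), tumor = c(72, 40, 118),
                  nt = c(233, 206, 221))
  )
}

# jittered-grid element centers over a canvas extended by `margin` so border
# elements are cut naturally
jittered_centers <- function(w, h, spacing, jitter, margin) {
  gx <- seq(spacing / 2 - margin, w + margin, by = spacing)
  gy <- seq(spacing / 2 - margin, h + margin, by = spacing)
  g <- expand.grid(cx = gx, cy = gy)
  g$cx <- g$cx + stats::runif(nrow(g), -jitter, jitter)
  g$cy <- g$cy + stats::runif(nrow(g), -jitter, jitter)
  g
}

#' Generate a procedural texture tile for one tissue class
#'
#' Texture families (seeded, deterministic): `NT` pale elongated wisps on a
#' bright background; `SO` densely packed solid discs merging into sheets;
#' `AC` annular elements with one lumen each; `MP` small tight element
#' clusters in clear space; `CR` large blobs perforated by several lumina.
#' Element colors take per-element jitter around the palette base; the
#' background carries mild pixel noise.
#'
#' @param class tissue class (AC/MP/SO/CR/NT).
#' @param size_px output edge length (scalar) or `c(height, width)`.
#' @param palette pseudo-cohort palette name (`"site_a"` or `"site_b"`) or a
#'   list with `bg`, `tumor`, `nt` RGB triples.
#' @param seed RNG seed.
#' @return RGB array `c(height, width, 3)` in \[0, 255\].
#' @export
generate_texture <- function(class, size_px, palette = "site_a", seed = 1) {
  class <- canonical_class(class)
  if (length(size_px) == 1L) size_px <- c(size_px, size_px)
  h <- as.integer(size_px[1]); w <- as.integer(size_px[2])
  if (h <= 0 || w <= 0) stop("size_px must be positive", call. = FALSE)
  pal <- if (is.character(palette)) gp_synth_palettes()[[palette]] else palette
  if (is.null(pal)) stop("unknown palette", call. = FALSE)
  withr::with_seed(seed, {
    ch <- lapply(1:3, function(i) {
      matrix(pal$bg[i], h, w) + matrix(stats::rnorm(h * w, 0, 1.5), h, w)
    })
    paint_disc <- function(cy, cx, r, col) {
      r0 <- max(1L, floor(cy - r)); r1 <- min(h, ceiling(cy + r))
      c0 <- max(1L, floor(cx - r)); c1 <- min(w, ceiling(cx + r))
      if (r0 > r1 || c0 > c1) return(invisible())
      dy <- (r0:r1) - cy; dx <- (c0:c1) - cx
      inside <- outer(dy^2, dx^2, `+`) <= r^2
      for (i in 1:3) {
        sub <- ch[[i]][r0:r1, c0:c1]
        sub[inside] <- col[i]
        ch[[i]][r0:r1, c0:c1] <<- sub
      }
    }
    paint_ellipse <- function(cy, cx, a, b, theta, col) {
      r <- a
      r0 <- max(1L, floor(cy - r)); r1 <- min(h, ceiling(cy + r))
      c0 <- max(1L, floor(cx - r)); c1 <- min(w, ceiling(cx + r))
      if (r0 > r1 || c0 > c1) return(invisible())
      dy <- (r0:r1) - cy; dx <- (c0:c1) - cx
      dxm <- matrix(dx, length(dy), length(dx), byrow = TRUE)
      dym <- matrix(dy, length(dy), length(dx))
      u <- dxm * cos(theta) + dym * sin(theta)
      v <- -dxm * sin(theta) + dym * cos(theta)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      for (i in 1:3) {
        sub <- ch[[i]][r0:r1, c0:c1]
        sub[inside] <- col[i]
        ch[[i]][r0:r1, c0:c1] <<- sub
      }
    }
    jcol <- function(base, jit) clip255(base + stats::runif(3, -jit, jit))
    switch(class,
      NT = {
        cs <- jittered_centers(w, h, spacing = 30, jitter = 6, margin = 20)
        for (k in seq_len(nrow(cs))) {
          paint_ellipse(cs$cy[k], cs$cx[k], a = stats::runif(1, 14, 20),
                        b = stats::runif(1, 4, 7),
                        theta = stats::runif(1, 0, pi),
                        col = jcol(pal$nt, 3))
        }
      },
      SO = {
        cs <- jittered_centers(w, h, spacing = 12, jitter = 1, margin = 14)
        for (k in seq_len(nrow(cs))) {
          paint_disc(cs$cy[k], cs$cx[k], stats::runif(1, 10, 12),
                     jcol(pal$tumor, 12))
        }
      },
      AC = {
        cs <- jittered_centers(w, h, spacing = 28, jitter = 2, margin = 14)
        for (k in seq_len(nrow(cs))) {
          r_out <- stats::runif(1, 10, 12)
          paint_disc(cs$cy[k], cs$cx[k], r_out, jcol(pal$tumor, 12))
          paint_disc(cs$cy[k], cs$cx[k], stats::runif(1, 3.2, 4.2),
                     jcol(pal$bg, 2))
        }
      },
      MP = {
        cs <- jittered_centers(w, h, spacing = 14, jitter = 4, margin = 8)
        for (k in seq_len(nrow(cs))) {
          paint_disc(cs$cy[k], cs$cx[k], stats::runif(1, 3, 4.5),
                     jcol(pal$tumor, 12))
        }
      },
      CR = {
        cs <- jittered_centers(w, h, spacing = 72, jitter = 4, margin = 34)
        for (k in seq_len(nrow(cs))) {
          r <- stats::runif(1, 26, 32)
          paint_disc(cs$cy[k], cs$cx[k], r, jcol(pal$tumor, 12))
          # one central lumen plus five peripheral ones, all large relative
          # to acinar lumina so hole size separates CR from AC
          paint_disc(cs$cy[k], cs$cx[k], 0.22 * r, jcol(pal$bg, 2))
          ang <- stats::runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = 6)[-6]
          for (li in 1:5) {
            d <- 0.55 * r
            paint_disc(cs$cy[k] + d * sin(ang[li]),
                       cs$cx[k] + d * cos(ang[li]),
                       0.22 * r, jcol(pal$bg, 2))
          }
        }
      }
    )
    out <- array(0, c(h, w, 3))
    for (i in 1:3) out[, , i] <- clip255(ch[[i]])
    out
  })
}

#' Random region layout for a synthetic slide
#'
#' Places one rectangular region per tissue class (all five classes by
#' default) on a slot grid with one-tile gaps between slots, aligned to the
#' tile grid so every tile intersecting a region lies fully inside it.
#'
#' @param seed RNG seed for the class-to-slot assignment.
#' @param tile_px tile edge length (default 128).
#' @param region_tiles region edge length in tiles (default 3).
#' @param classes classes to place (default all five).
#' @return data.frame `x`, `y`, `w`, `h`, `class` (level-0 px) with
#'   attribute `slide_dim = c(width, height)`.
#' @export
random_slide_layout <- function(seed = 1, tile_px = 128, region_tiles = 3,
                                classes = gp_classes()) {
  slot_cols <- 3; slot_rows <- 2
  step <- region_tiles + 1  # one-tile gap between slots
  slots <- expand.grid(sc = seq_len(slot_cols) - 1, sr = seq_len(slot_rows) - 1)
  if (length(classes) > nrow(slots)) {
    stop("more classes than layout slots", call. = FALSE)
  }
  pick <- withr::with_seed(seed, sample(nrow(slots), length(classes)))
  layout <- data.frame(
    x = slots$sc[pick] * step * tile_px,
    y = slots$sr[pick] * step * tile_px,
    w = region_tiles * tile_px,
    h = region_tiles * tile_px,
    class = classes,
    stringsAsFactors = FALSE
  )
  attr(layout, "slide_dim") <- c(
    width = (slot_cols * step - 1) * tile_px,
    height = (slot_rows * step - 1) * tile_px
  )
  attr(layout, "tile_px") <- tile_px
  layout
}

#' Generate a synthetic annotated slide
#'
#' Composes class textures into the layout's rectangular regions on a
#' bright background and builds the exactly matching annotation set (one
#' rectangular polygon per region). Optionally writes the slide as PNG and
#' the annotations as ImageScope XML.
#'
#' @param layout data.frame with `x`, `y`, `w`, `h`, `class` (level-0 px);
#'   regions must not overlap. A `slide_dim` attribute (or `slide_dim`
#'   argument) sets the canvas size.
#' @param seed RNG seed.
#' @param palette pseudo-cohort palette name or list (see
#'   [generate_texture()]).
#' @param pixel_size_um,magnification slide metadata. By default the pixel
#'   size is derived from the layout's `tile_px` attribute so that
#'   physical-area matching against the 600 px / 0.5 um reference yields
#'   exactly the layout's tile edge (e.g. 2.34375 um for 128 px tiles);
#'   without that attribute it falls back to 0.5 um.
#' @param slide_dim `c(width, height)`; defaults to the layout attribute.
#' @param id slide identifier.
#' @param dir if non-NULL, write `<id>.png` and `<id>.xml` there.
#' @return list with `slide` (`gp_slide`), `annotations`
#'   (`gp_annotations`), `layout`, and (if written) `slide_path`,
#'   `xml_path`.
#' @export
generate_slide <- function(layout, seed = 1, palette = "site_a",
                           pixel_size_um = NULL, magnification = 20,
                           slide_dim = NULL, id = "synthetic", dir = NULL) {
  if (is.null(pixel_size_um)) {
    tp <- attr(layout, "tile_px")
    pixel_size_um <- if (is.null(tp)) 0.5 else 600 * 0.5 / tp
  }
  if (is.null(slide_dim)) slide_dim <- attr(layout, "slide_dim")
  if (is.null(slide_dim)) stop("slide_dim not given", call. = FALSE)
  w <- as.integer(slide_dim[1]); h <- as.integer(slide_dim[2])
  if (nrow(layout) > 1) {
    for (i in seq_len(nrow(layout) - 1)) {
      for (j in (i + 1):nrow(layout)) {
        if (layout$x[i] < layout$x[j] + layout$w[j] &&
            layout$x[j] < layout$x[i] + layout$w[i] &&
            layout$y[i] < layout$y[j] + layout$h[j] &&
            layout$y[j] < layout$y[i] + layout$h[i]) {
          stop("layout regions ", i, " and ", j, " overlap", call. = FALSE)
        }
      }
    }
  }
  pal <- if (is.character(palette)) gp_synth_palettes()[[palette]] else palette
  canvas <- withr::with_seed(seed, {
    arr <- array(0, c(h, w, 3))
    for (i in 1:3) {
      arr[, , i] <- clip255(pal$bg[i] + matrix(stats::rnorm(h * w, 0, 1.5),
                                               h, w))
    }
    arr
  })
  regions <- list()
  for (i in seq_len(nrow(layout))) {
    tex <- generate_texture(layout$class[i], c(layout$h[i], layout$w[i]),
                            palette = pal, seed = seed + i)
    rr <- (layout$y[i] + 1):(layout$y[i] + layout$h[i])
    cc <- (layout$x[i] + 1):(layout$x[i] + layout$w[i])
    canvas[rr, cc, ] <- tex
    regions[[i]] <- list(
      vertices = cbind(
        x = layout$x[i] + c(0, layout$w[i], layout$w[i], 0),
        y = layout$y[i] + c(0, 0, layout$h[i], layout$h[i])),
      label = canonical_class(layout$class[i]))
  }
  slide <- new_slide(canvas, pixel_size_um, magnification, id = id)
  ann <- structure(list(regions = regions), class = "gp_annotations")
  out <- list(slide = slide, annotations = ann, layout = layout)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$slide_path <- file.path(dir, paste0(id, ".png"))
    out$xml_path <- file.path(dir, paste0(id, ".xml"))
    write_rgb_file(canvas, out$slide_path)
    write_imagescope_xml(ann, out$xml_path)
  }
  out
}

#' Published composition of the two-lab training tile corpus
#'
#' Per-class, per-cohort tile counts of the reference training corpus
#' assembled from two pathology labs (totals 10,304 + 9,638 = 19,942
#' tiles). `scale` shrinks every count proportionally (ceiling, minimum 1)
#' for desk-scale corpora.
#'
#' @param scale multiplicative factor applied to every count (default 1).
#' @return data.frame with columns `cohort`, `label`, `n`.
#' @export
reference_tile_counts <- function(scale = 1) {
  counts <- data.frame(
    cohort = rep(c("site_a", "site_b"), each = 5),
    label = rep(gp_classes(), 2),
    n = c(1533L, 2071L, 2357L, 863L, 3480L,    # lab A: AC MP SO CR NT
          2670L, 1165L, 1205L, 2375L, 2223L),  # lab B
    stringsAsFactors = FALSE
  )
  if (scale != 1) counts$n <- pmax(1L, as.integer(ceiling(counts$n * scale)))
  counts
}

#' Generate a labeled synthetic tile corpus
#'
#' Emits labeled texture tiles with per-pseudo-cohort base palettes
#' (emulating inter-lab H&E variance) and a manifest whose per-class,
#' per-cohort totals equal the requested counts. In dry mode only the
#' manifest is produced (placeholder paths, no rasters), so full-scale
#' corpus bookkeeping stays cheap.
#'
#' @param counts data.frame with columns `cohort` (palette name), `label`,
#'   `n`; default [reference_tile_counts()] at `scale = 1` in dry mode.
#' @param seed RNG seed.
#' @param tile_px tile edge length (default 128).
#' @param dry manifest only (default FALSE).
#' @param dir if non-NULL, write tile PNGs there.
#' @return list with `manifest` (data.frame `path`, `label`, `source_id`,
#'   `cohort`) and `tiles` (named list of rasters; empty in dry mode).
#' @export
generate_tile_corpus <- function(counts = reference_tile_counts(),
                                 seed = 1, tile_px = 128, dry = FALSE,
                                 dir = NULL) {
  stopifnot(all(c("cohort", "label", "n") %in% names(counts)))
  if (any(counts$n < 0)) stop("counts must be >= 0", call. = FALSE)
  rows <- counts[rep(seq_len(nrow(counts)), counts$n), c("cohort", "label")]
  if (nrow(rows) == 0L) {
    return(list(manifest = data.frame(path = character(),
                                      label = character(),
                                      source_id = character(),
                                      cohort = character()),
                tiles = list()))
  }
  rows$label <- canonical_class(rows$label)
  source_id <- sprintf("%s_%s_%04d", rows$cohort, rows$label,
                       stats::ave(seq_len(nrow(rows)),
                                  paste(rows$cohort, rows$label),
                                  FUN = seq_along))
  manifest <- data.frame(
    path = paste0(source_id, ".png"), label = rows$label,
    source_id = source_id, cohort = rows$cohort, stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  tiles <- list()
  if (!dry) {
    tiles <- lapply(seq_len(nrow(manifest)), function(i) {
      generate_texture(manifest$label[i], tile_px,
                       palette = manifest$cohort[i], seed = seed + i)
    })
    names(tiles) <- manifest$source_id
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      manifest$path <- file.path(dir, manifest$path)
      for (i in seq_along(tiles)) write_rgb_file(tiles[[i]], manifest$path[i])
    }
  }
  list(manifest = manifest, tiles = tiles)
}
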