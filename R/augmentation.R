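#' Apply one of the eight square-symmetry orientations to a tile
#'
#' Orientation codes 0..3 are counter-clockwise rotations of the original by
#' 0, 90, 180, 270 degrees; codes 4..7 are the same rotations applied to the
#' diagonally flipped (transposed) tile. Code 0 is the identity.
#'
#' @param tile square RGB array.
#' @param code integer orientation code in 0..7.
#' @return transformed RGB array.
#' @export
orient_tile <- function(tile, code) {
  assert_rgb(tile)
  if (dim(tile)[1] != dim(tile)[2]) {
    stop("orientation variants require a square tile", call. = FALSE)
  }
  if (!code %in% 0:7) stop("orientation code must be in 0..7", call. = FALSE)
  rot90 <- function(a) {
    # counter-clockwise quarter turn per channel
    out <- array(0, c(dim(a)[2], dim(a)[1], 3))
    for (ch in 1:3) out[, , ch] <- t(a[, , ch])[dim(a)[2]:1, , drop = FALSE]
    out
  }
  transpose3 <- function(a) {
    out <- array(0, c(dim(a)[2], dim(a)[1], 3))
    for (ch in 1:3) out[, , ch] <- t(a[, , ch])
    out
  }
  out <- if (code >= 4L) transpose3(tile) else tile
  for (i in seq_len(code %% 4L)) out <- rot90(out)
  out
}

#' All eight orientation variants of a tile
#'
#' Rotations by 0/90/180/270 degrees of the original, then the diagonal flip
#' rotated the same way -- the full symmetry group of the square, in a fixed
#' deterministic order (codes 0..7). Symmetric tiles still yield all eight
#' variants.
#'
#' @param tile square RGB array.
#' @return list of 8 RGB arrays, names `"orient0"`..`"orient7"`.
#' @export
orientation_variants <- function(tile) {
  stats::setNames(lapply(0:7, function(k) orient_tile(tile, k)),
                  paste0("orient", 0:7))
}

#' Expand one labeled tile by the color x orientation product
#'
#' The original tile plus one Reinhard color transfer per pattern, each in
#' all eight orientations: `(1 + length(patterns)) * 8` variants (40 with
#' the default four patterns). Labels are inherited; each variant carries a
#' descriptor of its color pattern (or `"original"`) and orientation code.
#'
#' @param tile square RGB array.
#' @param label class label (AC/MP/SO/CR/NT).
#' @param patterns list of `gp_color_pattern` (possibly empty).
#' @param source_id identifier of the source tile.
#' @return list of variants, each
#'   `list(raster, label, source_id, color_variant, orientation)`.
#' @export
augment_tile <- function(tile, label, patterns = list(), source_id = "tile") {
  label <- canonical_class(label)
  colored <- c(list(original = tile),
               stats::setNames(
                 lapply(patterns, function(p) normalize_tile(tile, p)),
                 vapply(patterns, `[[`, character(1), "pattern_id")))
  out <- list()
  for (cv in names(colored)) {
    for (k in 0:7) {
      out[[length(out) + 1L]] <- list(
        raster = orient_tile(colored[[cv]], k), label = label,
        source_id = source_id, color_variant = cv, orientation = k)
    }
  }
  out
}

#' Expand a labeled-tile manifest by color x orientation augmentation
#'
#' Every input row becomes `(1 + length(patterns)) * 8` output rows; class
#' proportions are preserved exactly. In dry-run mode (the default when
#' `out_dir` is `NULL`) only the expanded manifest is produced, so corpus
#' bookkeeping -- e.g. 19,942 tiles times 40 variants = 797,680 -- never
#' needs the variant rasters on disk. With `out_dir` set, variant PNGs are
#' written and the manifest `path` column points at them.
#'
#' @param manifest data.frame with columns `path`, `label` and optionally
#'   `source_id` (defaults to the file stem).
#' @param patterns list of `gp_color_pattern`.
#' @param out_dir output directory for variant rasters, or `NULL` for
#'   dry-run counting mode.
#' @return data.frame with columns `path`, `label`, `source_id`,
#'   `color_variant`, `orientation`.
#' @export
augment_dataset <- function(manifest, patterns = list(), out_dir = NULL) {
  stopifnot(is.data.frame(manifest))
  if (nrow(manifest) == 0L) {
    return(data.frame(path = character(), label = character(),
                      source_id = character(), color_variant = character(),
                      orientation = integer()))
  }
  if (!all(c("path", "label") %in% names(manifest))) {
    stop("manifest needs columns 'path' and 'label'", call. = FALSE)
  }
  labels <- canonical_class(manifest$label)
  source_id <- if ("source_id" %in% names(manifest)) manifest$source_id else
    tools::file_path_sans_ext(basename(manifest$path))
  color_names <- c("original",
                   vapply(patterns, `[[`, character(1), "pattern_id"))
  combos <- expand.grid(orientation = 0:7, color_variant = color_names,
                        row = seq_len(nrow(manifest)),
                        stringsAsFactors = FALSE)
  out <- data.frame(
    path = manifest$path[combos$row],
    label = labels[combos$row],
    source_id = source_id[combos$row],
    color_variant = combos$color_variant,
    orientation = combos$orientation,
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
    pat_by_id <- stats::setNames(patterns,
                                 vapply(patterns, `[[`, character(1),
                                        "pattern_id"))
    new_paths <- character(nrow(out))
    for (ri in seq_len(nrow(manifest))) {
      tile <- read_rgb_file(manifest$path[ri])[[1]]
      rows <- which(combos$row == ri)
      cache <- list(original = tile)
      for (j in rows) {
        cv <- out$color_variant[j]
        if (is.null(cache[[cv]])) {
          cache[[cv]] <- normalize_tile(tile, pat_by_id[[cv]])
        }
        fn <- file.path(out_dir, sprintf("%s_%s_o%d.png", out$source_id[j],
                                         cv, out$orientation[j]))
        write_rgb_file(orient_tile(cache[[cv]], out$orientation[j]), fn)
        new_paths[j] <- fn
      }
    }
    out$path <- new_paths
  }
  out
}
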