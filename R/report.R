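#' Run the full pipeline on one slide
#'
#' Tissue mask -> tile grid (physical-area-matched tile size) -> tissue
#' filtering -> contextual soft-voted classification -> tumor map, and,
#' when annotations are given, ground-truth rasterization and a slide-level
#' confusion matrix.
#'
#' @param slide `gp_slide`.
#' @param model classifier-contract model.
#' @param annotations optional `gp_annotations`.
#' @param cfg pipeline configuration (default [default_config()]).
#' @param tile_px tile edge override; by default derived from the slide's
#'   pixel size via [tile_size_for_area()], capped at the slide extent.
#' @param normalize_target optional `gp_color_pattern` for models that
#'   request normalized input.
#' @return list with `map`, `mask`, `grid`, `percentages` and (with
#'   annotations) `gt`, `confusion`, `metrics`.
#' @export
process_slide <- function(slide, model, annotations = NULL,
                          cfg = default_config(), tile_px = NULL,
                          normalize_target = NULL) {
  if (is.null(tile_px)) {
    tile_px <- tile_size_for_area(slide$pixel_size_um,
                                  cfg$tiles$reference_tile_px,
                                  cfg$tiles$reference_pixel_size_um)
    tile_px <- min(tile_px, slide$width_px, slide$height_px)
  }
  mask <- compute_tissue_mask(
    slide, t = cfg$mask$threshold,
    target_magnification = cfg$mask$target_magnification,
    closing_px = cfg$mask$closing_px,
    min_tissue_fraction = cfg$mask$min_tissue_fraction)
  grid <- filter_tiles(build_tile_grid(slide, tile_px), mask)
  map <- classify_slide(slide, grid, model,
                        normalize_target = normalize_target,
                        shift_fraction = cfg$voting$shift_fraction,
                        neighborhood = cfg$voting$neighborhood)
  out <- list(map = map, mask = mask, grid = grid,
              percentages = if (sum(map$counts) > 0)
                class_percentages(map, round_to_5 = TRUE) else NULL)
  if (!is.null(annotations)) {
    out$gt <- rasterize_annotations(annotations, slide,
                                    downsample = cfg$synthetic$gt_downsample,
                                    overlap = cfg$annotations$overlap)
    out$confusion <- confusion_from_overlay(map, out$gt)
    out$metrics <- cm_metrics(out$confusion)
  }
  out
}

#' End-to-end report over a set of slides
#'
#' Chains classification and evaluation for every slide and aggregates
#' confusion matrices to set level (by the `sets` grouping) and study
#' level. Individual slide failures are caught, logged and reported
#' without aborting the remaining slides.
#'
#' @param slides list of `gp_slide`.
#' @param annotations list of `gp_annotations`, parallel to `slides`.
#' @param model classifier-contract model.
#' @param cfg pipeline configuration.
#' @param sets optional character vector assigning each slide to a set
#'   (default: one set `"all"`).
#' @param out_dir optional directory for JSON/CSV artifacts (per-slide
#'   maps, study matrix, summary CSV).
#' @return `gp_report`: list with `slides` (per-slide results), `failed`
#'   (named list of error messages), `set_confusions`, `study_confusion`,
#'   `study_metrics`, `study_binary`.
#' @export
run_report <- function(slides, annotations, model, cfg = default_config(),
                       sets = NULL, out_dir = NULL) {
  if (length(slides) == 0L) stop("empty slide list", call. = FALSE)
  if (length(annotations) != length(slides)) {
    stop("annotations must parallel slides", call. = FALSE)
  }
  if (is.null(sets)) sets <- rep("all", length(slides))
  results <- list(); failed <- list()
  for (i in seq_along(slides)) {
    id <- slides[[i]]$id
    res <- tryCatch(
      process_slide(slides[[i]], model, annotations[[i]], cfg = cfg),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("slide '", id, "' failed: ", conditionMessage(res))
      failed[[id]] <- conditionMessage(res)
    } else {
      results[[id]] <- res
    }
  }
  if (length(results) == 0L) stop("all slides failed", call. = FALSE)
  ok_ids <- names(results)
  ok_sets <- sets[match(ok_ids, vapply(slides, `[[`, character(1), "id"))]
  set_confusions <- lapply(split(ok_ids, ok_sets), function(ids) {
    aggregate_confusion(lapply(results[ids], `[[`, "confusion"),
                        level = "set")
  })
  study <- aggregate_confusion(unname(set_confusions), level = "study")
  report <- structure(
    list(slides = results, failed = failed,
         set_confusions = set_confusions,
         study_confusion = study,
         study_metrics = cm_metrics(study),
         study_binary = merge_tumor_vs_nontumor(study)),
    class = "gp_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.gp_report <- function(x, ...) {
  m <- x$study_metrics
  cat(sprintf(
    "<gp_report> %d slide(s) (%d failed), study ACC %.3f, F1: %s\n",
    length(x$slides), length(x$failed), m$acc,
    paste(names(m$f1), sprintf("%.3f", m$f1), sep = "=", collapse = " ")))
  invisible(x)
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (id in names(report$slides)) {
    write_tumor_map(report$slides[[id]]$map,
                    file.path(out_dir, paste0(id, "_map.json")))
  }
  study <- list(
    confusion = unname(apply(report$study_confusion$counts, 1, as.list)),
    unclassified = as.list(report$study_confusion$unclassified),
    f1 = as.list(report$study_metrics$f1),
    acc = report$study_metrics$acc,
    binary_f1 = as.list(report$study_binary$f1),
    binary_acc = report$study_binary$acc
  )
  jsonlite::write_json(study, file.path(out_dir, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  per_slide <- do.call(rbind, lapply(names(report$slides), function(id) {
    m <- report$slides[[id]]$metrics
    data.frame(slide = id, acc = m$acc, t(m$f1))
  }))
  write.csv(per_slide, file.path(out_dir, "slides.csv"), row.names = FALSE)
  invisible(out_dir)
}
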