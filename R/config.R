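#' Default pipeline configuration
#'
#' All module defaults in one nested list: intensity threshold 230 for
#' tissue masking, 20% minimum tissue per tile, 600 px reference tile at
#' 0.5 um/px, 1/3 glimpse shift with N = 9 uniform-weight neighborhood,
#' 256 px classifier input, 4 target color patterns. Seeds are mandatory
#' for every stochastic path; configuration loading rejects unknown keys.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    tiles = list(
      reference_tile_px = 600,
      reference_pixel_size_um = 0.5
    ),
    mask = list(
      threshold = 230,
      min_tissue_fraction = 0.20,
      target_magnification = 5,
      closing_px = 5
    ),
    color = list(
      k_total = 4,
      pixels_per_corpus = 50000,
      normalize_target = "pooled"
    ),
    voting = list(
      neighborhood = 9,
      shift_fraction = 1 / 3
    ),
    classifier = list(
      backend = "mock",
      input_px = 256,
      sharpness = 0.9,
      tiny_net = list(input_px = 16, hidden_units = 12, maxit = 200,
                      decay = 5e-4)
    ),
    annotations = list(
      label_attribute = "Text",
      overlap = "error"
    ),
    synthetic = list(
      tile_px = 128,
      region_tiles = 3,
      gt_downsample = 4
    ),
    seeds = list(
      patterns = 1,
      corpus = 1,
      slides = 1,
      training = 1
    )
  )
}

merge_validate <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop("config key ", full, " must be a section", call. = FALSE)
      }
      defaults[[key]] <- merge_validate(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a pipeline configuration from YAML
#'
#' Layered configuration: package defaults overridden by the file's keys.
#' Unknown keys are rejected; seeds must be present (the defaults provide
#' them) so no stochastic path ever runs silently unseeded.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return validated nested list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_validate(cfg, user)
  }
  for (s in c("patterns", "corpus", "slides", "training")) {
    if (is.null(cfg$seeds[[s]])) {
      stop("config seeds.", s, " must be set", call. = FALSE)
    }
  }
  cfg
}

#' Write a pipeline configuration as YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
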