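#' Resample a square tile to the classifier input size
#'
#' Area-style resampling: exact block averaging when the tile edge is an
#' integer multiple of `input_px`, bilinear resampling otherwise. Returns
#' raw intensities; batch standardization is a separate step
#' ([preprocess_batch()]).
#'
#' @param tile square RGB array.
#' @param input_px classifier input edge (default 256).
#' @return RGB array `c(input_px, input_px, 3)`.
#' @export
preprocess_tile <- function(tile, input_px = 256) {
  assert_rgb(tile)
  d <- dim(tile)
  if (d[1] != d[2]) stop("classifier input must be square", call. = FALSE)
  if (d[1] == input_px) return(tile)
  if (d[1] %% input_px == 0L) return(block_downsample(tile, d[1] %/% input_px))
  out <- EBImage::resize(EBImage::Image(tile / 255, colormode = "Color"),
                         w = input_px, h = input_px)
  array(EBImage::imageData(out) * 255, c(input_px, input_px, 3))
}

#' Standardize a batch of model inputs
#'
#' Zero-mean / unit-variance per channel over the whole batch; a
#' zero-variance channel is guarded by `eps` so constant batches map to
#' all-zero rasters.
#'
#' @param tiles list of equally sized RGB arrays.
#' @param eps variance guard (default 1e-6).
#' @return list of standardized arrays.
#' @export
preprocess_batch <- function(tiles, eps = 1e-6) {
  if (length(tiles) == 0L) return(tiles)
  for (ch in 1:3) {
    vals <- unlist(lapply(tiles, function(tl) tl[, , ch]))
    m <- mean(vals); s <- max(stats::sd(vals), eps)
    tiles <- lapply(tiles, function(tl) {
      tl[, , ch] <- (tl[, , ch] - m) / s
      tl
    })
  }
  tiles
}

as_class_probs <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 5L || any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop("classifier contract violation: output is not a length-5 ",
         "probability vector summing to 1", call. = FALSE)
  }
  stats::setNames(pmax(p, 0), gp_classes())
}

#' Classify a batch of tiles through a classifier-contract model
#'
#' A model is a list with fields `name`, `predict(tiles) -> n x 5 matrix`
#' and `normalize_input` (whether [classify_slide()] should Reinhard-
#' normalize tiles before calling it). Output rows are validated against
#' the probability contract (entries >= 0, sum 1 within 1e-6).
#'
#' @param tiles list of RGB arrays (possibly empty).
#' @param model classifier-contract model, e.g. [mock_model()].
#' @return list of named length-5 probability vectors (AC, MP, SO, CR, NT).
#' @export
classify_batch <- function(tiles, model) {
  stopifnot(is.list(model), is.function(model$predict))
  if (length(tiles) == 0L) return(list())
  out <- model$predict(tiles)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  lapply(seq_len(nrow(out)), function(i) as_class_probs(out[i, ]))
}

#' Interpretable texture features of a tile
#'
#' Features the deterministic mock backend (and the generator contract
#' tests) are built on: the fraction of pixels darker than a fixed luma
#' threshold (`fg_fraction`), the number of dark connected components above
#' a minimum area, the number and median size of enclosed background holes
#' (lumina, found by hole filling), holes per component, and the median
#' component area. Hole sizes are crop-robust: a lumen cut open by a tile
#' border stops being enclosed and drops out entirely instead of shrinking.
#'
#' @param tile RGB array.
#' @param fg_luma luma threshold below which a pixel counts as stained
#'   foreground (default 200).
#' @param min_component_area,min_hole_area noise cutoffs in pixels
#'   (defaults 40 and 25).
#' @return named list of scalar features.
#' @export
tile_texture_features <- function(tile, fg_luma = 200,
                                  min_component_area = 40,
                                  min_hole_area = 25) {
  g <- luma(tile)
  fg <- g < fg_luma
  storage.mode(fg) <- "integer"
  fg_fraction <- mean(fg)
  if (fg_fraction == 0) {
    return(list(fg_fraction = 0, n_components = 0L, n_holes = 0L,
                holes_per_component = 0, median_component_area = 0,
                median_hole_area = 0))
  }
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_component_area)
  holes <- EBImage::fillHull(fg) - fg
  hole_sizes <- if (any(holes > 0)) {
    hl <- EBImage::bwlabel(holes)
    tabulate(hl[hl > 0])
  } else integer(0)
  hole_sizes <- hole_sizes[hole_sizes >= min_hole_area]
  n_holes <- length(hole_sizes)
  n_comp <- length(keep)
  list(
    fg_fraction = fg_fraction,
    n_components = n_comp,
    n_holes = as.integer(n_holes),
    holes_per_component = if (n_comp > 0) n_holes / n_comp else 0,
    median_component_area = if (n_comp > 0) stats::median(sizes[keep]) else 0,
    median_hole_area = if (n_holes > 0) stats::median(hole_sizes) else 0
  )
}

#' Deterministic texture-rule classifier for one tile
#'
#' Maps the [tile_texture_features()] of a tile through fixed decision
#' rules to a near-one-hot probability vector (default 0.9 winner / 0.025
#' others). The rules mirror the synthetic texture families: near-zero dark
#' foreground -> NT (non-tumor textures are pale); at least two enclosed
#' lumina -> large lumina are CR, small lumina are AC; otherwise small
#' median component area -> MP, large -> SO. Pure: identical tiles give
#' identical outputs.
#'
#' @param tile RGB array.
#' @param sharpness winner probability (default 0.9); the remaining mass is
#'   spread uniformly over the other four classes.
#' @param rules named list of rule thresholds: `fg_nt`, `min_holes`,
#'   `cr_hole_area`, `mp_max_area`.
#' @return named length-5 probability vector.
#' @export
mock_classifier <- function(tile, sharpness = 0.9,
                            rules = list(fg_nt = 0.05, min_holes = 2,
                                         cr_hole_area = 80,
                                         mp_max_area = 150)) {
  f <- tile_texture_features(tile)
  label <-
    if (f$fg_fraction < rules$fg_nt) "NT"
    else if (f$n_holes >= rules$min_holes) {
      if (f$median_hole_area >= rules$cr_hole_area) "CR" else "AC"
    }
    else if (f$median_component_area <= rules$mp_max_area) "MP"
    else "SO"
  p <- rep((1 - sharpness) / 4, 5)
  names(p) <- gp_classes()
  p[label] <- sharpness
  p
}

#' Deterministic texture-rule classifier model
#'
#' Wraps [mock_classifier()] in the classifier contract. It operates on the
#' raw color scale of the synthetic textures, so it declares
#' `normalize_input = FALSE` (see the methods vignette).
#'
#' @param sharpness winner probability (default 0.9).
#' @return classifier-contract model.
#' @export
mock_model <- function(sharpness = 0.9) {
  list(
    name = "mock",
    normalize_input = FALSE,
    predict = function(tiles) {
      do.call(rbind, lapply(tiles, mock_classifier, sharpness = sharpness))
    }
  )
}

#' Wrap a model with independent per-tile label noise
#'
#' With probability `noise` the model's argmax label is replaced by a
#' uniformly random other class; the emitted vector puts `winner_prob` on
#' the (possibly corrupted) label and spreads the rest uniformly. Draws are
#' seeded and advance deterministically per call, so a wrapper constructed
#' with the same seed reproduces its prediction stream. Used to study the
#' benefit of contextual soft voting under classifier noise.
#'
#' @param base_model classifier-contract model.
#' @param noise per-tile corruption probability (default 0.2).
#' @param winner_prob probability mass on the emitted label (default 0.6).
#' @param seed RNG seed for the corruption stream.
#' @return classifier-contract model.
#' @export
make_noisy_model <- function(base_model, noise = 0.2, winner_prob = 0.6,
                             seed = 1) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  list(
    name = paste0(base_model$name, "+noise"),
    normalize_input = base_model$normalize_input,
    predict = function(tiles) {
      base <- base_model$predict(tiles)
      if (is.null(dim(base))) base <- matrix(base, nrow = 1)
      counter$i <- counter$i + 1L
      withr::with_seed(seed + counter$i, {
        labels <- max.col(base, ties.method = "first")
        flip <- stats::runif(length(labels)) < noise
        wrong <- vapply(labels, function(l) {
          sample(setdiff(1:5, l), 1)
        }, integer(1))
        labels[flip] <- wrong[flip]
      })
      out <- matrix((1 - winner_prob) / 4, length(labels), 5)
      out[cbind(seq_along(labels), labels)] <- winner_prob
      out
    }
  )
}

# 3-channel block-pooled pixel features for the trainable backend
tiny_net_features <- function(tile, input_px = 16) {
  small <- preprocess_tile(tile, input_px)
  as.numeric(small) / 255
}

#' Train the small neural tile classifier
#'
#' The trainable backend: tiles are area-resampled to a small square input
#' (default 12 x 12 x 3) and fed to a seeded single-hidden-layer network
#' (via \pkg{nnet}) with softmax output over the five classes. Training is
#' stochastic but reproducible for a fixed seed. The pipeline and test
#' suite are fully functional with the deterministic texture-rule backend
#' alone; this backend exists to exercise the pluggable-classifier
#' contract with a learned model.
#'
#' @param tiles list of RGB arrays.
#' @param labels class labels, one per tile.
#' @param input_px model input edge (default 12).
#' @param hidden_units hidden layer size (default 8).
#' @param maxit optimizer iteration cap (default 120).
#' @param decay weight decay (default 5e-4).
#' @param seed RNG seed for weight initialization.
#' @return classifier-contract model (with `normalize_input = TRUE`).
#' @export
train_tiny_net <- function(tiles, labels, input_px = 12, hidden_units = 8,
                           maxit = 120, decay = 5e-4, seed = 1) {
  if (length(tiles) == 0L) stop("empty training manifest", call. = FALSE)
  if (length(tiles) != length(labels)) {
    stop("tiles and labels must have equal length", call. = FALSE)
  }
  labels <- factor(canonical_class(labels), levels = gp_classes())
  x <- do.call(rbind, lapply(tiles, tiny_net_features, input_px = input_px))
  y <- nnet::class.ind(labels)
  fit <- withr::with_seed(seed, {
    nnet::nnet(x, y, size = hidden_units, softmax = TRUE, decay = decay,
               maxit = maxit, MaxNWts = 1e5, trace = FALSE)
  })
  list(
    name = "tiny_net",
    normalize_input = TRUE,
    input_px = input_px,
    fit = fit,
    predict = function(tiles) {
      x <- do.call(rbind,
                   lapply(tiles, tiny_net_features, input_px = input_px))
      p <- stats::predict(fit, x)
      if (is.null(dim(p))) p <- matrix(p, nrow = 1)
      # renormalize against float drift before the contract check
      sweep(p, 1, pmax(rowSums(p), 1e-12), "/")
    }
  )
}
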