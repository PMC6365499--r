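#' Glimpse coordinates for contextual classification
#'
#' The central tile plus the eight tiles obtained by shifting it by a fixed
#' fraction (default 1/3) of its edge length horizontally, vertically or
#' diagonally. Glimpses that would extend beyond the slide bounds are
#' dropped, so the neighborhood shrinks at slide borders; the central
#' glimpse is always retained and listed first.
#'
#' @param x,y 0-based level-0 top-left corner of the central tile.
#' @param tile_px tile edge length.
#' @param slide_dim `c(width, height)` of the slide in level-0 pixels.
#' @param shift_fraction glimpse offset as a fraction of the tile edge
#'   (default 1/3); the pixel shift is `round(shift_fraction * tile_px)`.
#' @param neighborhood total neighborhood size N; 9 (default) uses all
#'   glimpses, 1 uses the central tile only.
#' @return data.frame of 0-based glimpse corners `x`, `y`, central first.
#' @export
glimpse_coords <- function(x, y, tile_px, slide_dim, shift_fraction = 1 / 3,
                           neighborhood = 9) {
  if (x < 0 || y < 0 || x + tile_px > slide_dim[1] ||
      y + tile_px > slide_dim[2]) {
    stop("central tile lies outside the slide", call. = FALSE)
  }
  if (neighborhood < 1) stop("neighborhood must be >= 1", call. = FALSE)
  if (shift_fraction <= 0 || shift_fraction >= 1) {
    stop("shift_fraction must be in (0, 1)", call. = FALSE)
  }
  if (neighborhood == 1) return(data.frame(x = x, y = y))
  s <- round(shift_fraction * tile_px)
  offs <- expand.grid(dx = c(-s, 0, s), dy = c(-s, 0, s))
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  gx <- x + offs$dx; gy <- y + offs$dy
  ok <- gx >= 0 & gy >= 0 & gx + tile_px <= slide_dim[1] &
    gy + tile_px <= slide_dim[2]
  data.frame(x = c(x, gx[ok]), y = c(y, gy[ok]))
}

#' Soft-voting decision over glimpse probability vectors
#'
#' Returns the class maximizing the weighted sum of per-glimpse class
#' probabilities, `argmax_i sum_j a_j p_ij`. Weights default to uniform and
#' are truncated to the number of glimpses supplied; ties are broken
#' deterministically toward the lowest class index (enum order
#' AC < MP < SO < CR < NT). With uniform weights the vote is permutation
#' invariant in the glimpse order.
#'
#' @param prob_vectors list of length-5 probability vectors (or an n x 5
#'   matrix), one per glimpse.
#' @param weights non-negative glimpse weights `a_j` (default uniform 1).
#' @return class label (character scalar).
#' @export
soft_vote <- function(prob_vectors, weights = NULL) {
  if (is.matrix(prob_vectors)) {
    prob_vectors <- lapply(seq_len(nrow(prob_vectors)),
                           function(i) prob_vectors[i, ])
  }
  n <- length(prob_vectors)
  if (n == 0L) stop("soft_vote needs at least one probability vector",
                    call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) < n) {
    stop("fewer weights than probability vectors", call. = FALSE)
  }
  weights <- weights[seq_len(n)]
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  score <- rep(0, 5)
  for (j in seq_len(n)) score <- score + weights[j] * as.numeric(prob_vectors[[j]])
  gp_classes()[which.max(score)]  # which.max returns the lowest tied index
}

#' Classify a whole slide into a tumor map
#'
#' For every retained tile of the (tissue-filtered) grid: extract the
#' central and shifted glimpse rasters at full resolution, optionally
#' Reinhard-normalize each to the target color pattern (when the model
#' declares `normalize_input`), classify each glimpse independently, and
#' assign the soft-voted class to the central tile. Grid positions that
#' were filtered out remain background.
#'
#' @param slide `gp_slide`.
#' @param grid `gp_tile_grid` after tissue filtering.
#' @param model classifier-contract model.
#' @param normalize_target `gp_color_pattern` used when the model requests
#'   normalized input (e.g. the pooled training-corpus pattern); `NULL`
#'   disables normalization.
#' @param shift_fraction glimpse offset fraction (default 1/3).
#' @param neighborhood neighborhood size N (default 9; 1 = central only).
#' @param weights glimpse weights for [soft_vote()] (default uniform).
#' @param verbose log per-slide tile counts (default FALSE).
#' @return `gp_tumor_map` (see [new_tumor_map()]).
#' @export
classify_slide <- function(slide, grid, model, normalize_target = NULL,
                           shift_fraction = 1 / 3, neighborhood = 9,
                           weights = NULL, verbose = FALSE) {
  stopifnot(inherits(slide, "gp_slide"), inherits(grid, "gp_tile_grid"))
  labels <- matrix(0L, grid$ny, grid$nx)
  do_norm <- isTRUE(model$normalize_input) && !is.null(normalize_target)
  for (i in seq_len(nrow(grid$tiles))) {
    tl <- grid$tiles[i, ]
    coords <- glimpse_coords(tl$x, tl$y, grid$tile_px, grid$slide_dim,
                             shift_fraction, neighborhood)
    glimpses <- lapply(seq_len(nrow(coords)), function(j) {
      g <- slide_region(slide, coords$x[j], coords$y[j],
                        grid$tile_px, grid$tile_px)
      if (do_norm) normalize_tile(g, normalize_target) else g
    })
    probs <- classify_batch(glimpses, model)
    labels[tl$row, tl$col] <- match(soft_vote(probs, weights), gp_classes())
  }
  if (verbose) {
    message(sprintf("slide '%s': %d/%d grid tiles classified", slide$id,
                    nrow(grid$tiles), grid$nx * grid$ny))
  }
  new_tumor_map(labels, grid$tile_px, slide$id)
}
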