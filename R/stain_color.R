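# Reinhard's decorrelated log-chromatic (l-alpha-beta) color space.
# RGB -> LMS cone response -> log10 -> fixed decorrelating rotation.
# Matrices follow Reinhard's color-transfer formulation; RGB is worked in
# [0, 1] internally, LMS values are clamped to a small epsilon before log.

.RGB2LMS <- matrix(c(
  0.3811, 0.5783, 0.0402,
  0.1967, 0.7244, 0.0782,
  0.0241, 0.1288, 0.8444
), 3, 3, byrow = TRUE)

# exact inverse of the forward matrix (the published rounded inverse leaves
# round-trip errors above one intensity level on bright pixels)
.LMS2RGB <- solve(.RGB2LMS)

.LOG2LAB <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1,
           1, 1, -2,
           1, -1, 0), 3, 3, byrow = TRUE)

.LAB2LOG <- solve(.LOG2LAB)

#' Convert an RGB tile to the l-alpha-beta color space
#'
#' The channels are `l` (achromatic log-luminance), `alpha` (yellow-blue
#' opponent) and `beta` (red-green opponent); achromatic pixels have
#' `alpha`, `beta` near 0. This is the space in which Reinhard color
#' transfer matches per-channel means and standard deviations.
#'
#' @param rgb RGB array `c(h, w, 3)` in \[0, 255\].
#' @param eps clamp for zero LMS responses before the log (default 1e-6).
#' @return numeric array `c(h, w, 3)` of l, alpha, beta.
#' @export
to_lab <- function(rgb, eps = 1e-6) {
  assert_rgb(rgb)
  d <- dim(rgb)
  px <- matrix(rgb, ncol = 3) / 255
  lms <- pmax(px %*% t(.RGB2LMS), eps)
  lab <- log10(lms) %*% t(.LOG2LAB)
  array(lab, d)
}

#' Convert an l-alpha-beta tile back to 8-bit RGB
#'
#' Inverse of [to_lab()]; output is clipped to \[0, 255\].
#'
#' @param lab array `c(h, w, 3)` of l, alpha, beta values.
#' @return RGB array in \[0, 255\].
#' @export
from_lab <- function(lab) {
  assert_rgb(lab, "lab tile")
  d <- dim(lab)
  lms <- 10^(matrix(lab, ncol = 3) %*% t(.LAB2LOG))
  rgb <- lms %*% t(.LMS2RGB)
  array(clip255(rgb * 255), d)
}

#' Per-channel mean and standard deviation in l-alpha-beta
#'
#' @param x RGB tile (converted internally) or an l-alpha-beta array when
#'   `space = "lab"`.
#' @param space `"rgb"` (default) or `"lab"`.
#' @return `gp_lab_stats`: list of numeric `mean` and `std`, each length 3
#'   named l, alpha, beta.
#' @export
lab_stats <- function(x, space = c("rgb", "lab")) {
  space <- match.arg(space)
  lab <- if (space == "rgb") to_lab(x) else x
  px <- matrix(lab, ncol = 3)
  structure(
    list(mean = stats::setNames(colMeans(px), c("l", "alpha", "beta")),
         std = stats::setNames(apply(px, 2, stats::sd), c("l", "alpha", "beta"))),
    class = "gp_lab_stats"
  )
}

#' @export
print.gp_lab_stats <- function(x, ...) {
  cat("<gp_lab_stats> mean:", sprintf("%.4f", x$mean),
      " std:", sprintf("%.4f", x$std), "\n")
  invisible(x)
}

new_lab_stats <- function(mean, std) {
  if (any(std < 0)) stop("std components must be >= 0", call. = FALSE)
  structure(list(mean = stats::setNames(as.numeric(mean), c("l", "alpha", "beta")),
                 std = stats::setNames(as.numeric(std), c("l", "alpha", "beta"))),
            class = "gp_lab_stats")
}

#' Reinhard color transfer between statistics
#'
#' Per channel `c` in l-alpha-beta:
#' `out = (in - mean_src_c) * std_tgt_c / max(std_src_c, eps) + mean_tgt_c`,
#' then converted back to RGB and clipped to \[0, 255\]. With
#' `target == source` the tile is reproduced within rounding; a
#' constant-color tile maps to the target means (the degenerate
#' zero-variance source is guarded by `eps`).
#'
#' @param tile RGB array in \[0, 255\].
#' @param source_stats `gp_lab_stats` of the source distribution; computed
#'   from `tile` when `NULL`.
#' @param target_stats `gp_lab_stats` of the transfer target.
#' @param eps degenerate-std guard (default 1e-6).
#' @return RGB array in \[0, 255\].
#' @export
reinhard_transfer <- function(tile, source_stats = NULL, target_stats,
                              eps = 1e-6) {
  assert_rgb(tile)
  lab <- to_lab(tile)
  if (is.null(source_stats)) source_stats <- lab_stats(lab, space = "lab")
  stopifnot(inherits(source_stats, "gp_lab_stats"),
            inherits(target_stats, "gp_lab_stats"))
  out <- lab
  for (ch in 1:3) {
    scale <- target_stats$std[ch] / max(source_stats$std[ch], eps)
    out[, , ch] <- (lab[, , ch] - source_stats$mean[ch]) * scale +
      target_stats$mean[ch]
  }
  from_lab(out)
}

#' Construct a color pattern (a Reinhard transfer target)
#'
#' @param stats `gp_lab_stats`.
#' @param pattern_id unique identifier within a pattern set.
#' @param provenance free-text tag naming the corpus/cluster that produced
#'   the pattern.
#' @return `gp_color_pattern`.
#' @export
new_color_pattern <- function(stats, pattern_id, provenance = "") {
  stopifnot(inherits(stats, "gp_lab_stats"))
  structure(list(stats = stats, pattern_id = pattern_id,
                 provenance = provenance),
            class = "gp_color_pattern")
}

#' @export
print.gp_color_pattern <- function(x, ...) {
  cat(sprintf("<gp_color_pattern '%s'> (%s) mean: %s\n", x$pattern_id,
              x$provenance, paste(sprintf("%.3f", x$stats$mean),
                                  collapse = ", ")))
  invisible(x)
}

# Deterministic farthest-point ("k-means++"-style, without randomness in the
# propagation step) seeding: first center = point closest to the data mean,
# each next = point farthest from its nearest chosen center.
farthest_point_centers <- function(px, k) {
  ctr <- matrix(0, k, ncol(px))
  d0 <- rowSums(sweep(px, 2, colMeans(px))^2)
  ctr[1, ] <- px[which.min(d0), ]
  if (k > 1) {
    dmin <- rowSums(sweep(px, 2, ctr[1, ])^2)
    for (i in 2:k) {
      ctr[i, ] <- px[which.max(dmin), ]
      dmin <- pmin(dmin, rowSums(sweep(px, 2, ctr[i, ])^2))
    }
  }
  ctr
}

#' Derive target color patterns from tile corpora by k-means
#'
#' Pixels of each corpus (subsampled, seeded) are converted to
#' l-alpha-beta and clustered by k-means separately per corpus, with
#' `k_total` split evenly across corpora (4 total from two corpora -> 2 + 2).
#' Each cluster contributes one color pattern from its members' per-channel
#' mean and standard deviation. Deterministic under a fixed seed:
#' farthest-point initial centers, Lloyd iterations, 300-iteration cap.
#'
#' @param tile_corpora named list of corpora; each corpus is a list of RGB
#'   tiles.
#' @param k_total total number of patterns to derive (default 4).
#' @param seed RNG seed for pixel subsampling.
#' @param pixels_per_corpus pixel subsample size per corpus (default 50000).
#' @return list of `k_total` `gp_color_pattern` objects.
#' @export
derive_color_patterns <- function(tile_corpora, k_total = 4, seed = 1,
                                  pixels_per_corpus = 50000) {
  if (is.null(names(tile_corpora))) {
    names(tile_corpora) <- paste0("corpus", seq_along(tile_corpora))
  }
  n_corp <- length(tile_corpora)
  if (n_corp == 0L) stop("no corpora supplied", call. = FALSE)
  if (k_total < n_corp) {
    stop("k_total must be >= number of corpora", call. = FALSE)
  }
  ks <- rep(k_total %/% n_corp, n_corp)
  if (sum(ks) < k_total) ks[seq_len(k_total - sum(ks))] <- ks[1] + 1L
  patterns <- list()
  for (ci in seq_len(n_corp)) {
    corpus <- tile_corpora[[ci]]
    if (length(corpus) == 0L) {
      stop("empty tile corpus: ", names(tile_corpora)[ci], call. = FALSE)
    }
    px <- do.call(rbind, lapply(corpus, function(tl) {
      assert_rgb(tl)
      matrix(to_lab(tl), ncol = 3)
    }))
    if (nrow(px) > pixels_per_corpus) {
      px <- withr::with_seed(seed + ci, px[sample.int(nrow(px),
                                                      pixels_per_corpus), ])
    }
    k <- ks[ci]
    uniq <- unique(round(px, 10))
    if (nrow(uniq) < k) {
      # degenerate corpus (fewer distinct colors than clusters): repeat stats
      km_cluster <- rep(seq_len(nrow(uniq)), length.out = k)
      centers_assign <- apply(px, 1, function(p) {
        which.min(colSums((t(uniq) - p)^2))
      })
      groups <- split(seq_len(nrow(px)), centers_assign)
      groups <- rep(groups, length.out = k)
    } else {
      km <- stats::kmeans(px, centers = farthest_point_centers(px, k),
                          iter.max = 300, algorithm = "Lloyd")
      groups <- split(seq_len(nrow(px)), km$cluster)
    }
    for (gi in seq_along(groups)) {
      rows <- px[groups[[gi]], , drop = FALSE]
      st <- new_lab_stats(colMeans(rows),
                          if (nrow(rows) > 1) apply(rows, 2, stats::sd)
                          else c(0, 0, 0))
      patterns[[length(patterns) + 1L]] <- new_color_pattern(
        st, pattern_id = sprintf("%s_k%d", names(tile_corpora)[ci], gi),
        provenance = names(tile_corpora)[ci])
    }
  }
  patterns[seq_len(k_total)]
}

#' Normalize a tile to a target color pattern
#'
#' Reinhard transfer with source statistics computed from the tile itself;
#' idempotent within one intensity level.
#'
#' @param tile RGB array in \[0, 255\].
#' @param target `gp_color_pattern` (or `gp_lab_stats`).
#' @return RGB array in \[0, 255\].
#' @export
normalize_tile <- function(tile, target) {
  stats <- if (inherits(target, "gp_color_pattern")) target$stats else target
  reinhard_transfer(tile, source_stats = NULL, target_stats = stats)
}

#' Serialize color patterns to JSON
#'
#' Each pattern becomes `{pattern_id, mean[3], std[3], provenance}`.
#'
#' @param patterns list of `gp_color_pattern`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_color_patterns <- function(patterns, path) {
  payload <- lapply(patterns, function(p) {
    list(pattern_id = p$pattern_id, mean = unname(p$stats$mean),
         std = unname(p$stats$std), provenance = p$provenance)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read color patterns from JSON
#'
#' @param path JSON file written by [write_color_patterns()].
#' @return list of `gp_color_pattern`.
#' @export
read_color_patterns <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(p) {
    new_color_pattern(new_lab_stats(unlist(p$mean), unlist(p$std)),
                      p$pattern_id, p$provenance %||% "")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pooled l-alpha-beta statistics of a set of tiles
#'
#' Convenience constructor for the default inference-time normalization
#' target: the pooled pixel statistics of a training corpus.
#'
#' @param tiles list of RGB tiles.
#' @param pattern_id identifier for the resulting pattern.
#' @return `gp_color_pattern`.
#' @export
pooled_pattern <- function(tiles, pattern_id = "pooled") {
  px <- do.call(rbind, lapply(tiles, function(tl) matrix(to_lab(tl), ncol = 3)))
  new_color_pattern(new_lab_stats(colMeans(px), apply(px, 2, stats::sd)),
                    pattern_id, provenance = "pooled")
}
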