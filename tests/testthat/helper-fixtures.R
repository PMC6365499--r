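# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive per-element loops, independent of the vectorized implementations
# they check.

const_tile <- function(r, g, b, n = 8) {
  array(rep(c(r, g, b), each = n * n), c(n, n, 3))
}

random_tile <- function(n = 8, seed = 1) {
  withr::with_seed(seed, array(runif(n * n * 3, 0, 255), c(n, n, 3)))
}

# tiny slide: flat background with an optional dark block
flat_slide <- function(w = 64, h = 64, value = 255, pixel_size = 0.5,
                       id = "flat") {
  new_slide(array(value, c(h, w, 3)), pixel_size, magnification = 20,
            downsamples = c(1L, 4L), id = id)
}

# scalar even-odd point-in-polygon (ray toward -x), one point at a time
oracle_point_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- verts[i, 1]; y1 <- verts[i, 2]
    x2 <- verts[j, 1]; y2 <- verts[j, 2]
    if (y1 == y2) next
    if (py >= min(y1, y2) && py < max(y1, y2)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px > xi) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# brute-force ground-truth rasterization, pixel by pixel
oracle_rasterize <- function(ann, width, height, downsample = 1) {
  nx <- width %/% downsample
  ny <- height %/% downsample
  out <- matrix(0L, ny, nx)
  for (r in seq_len(ny)) {
    for (c in seq_len(nx)) {
      cx <- (c - 0.5) * downsample
      cy <- (r - 0.5) * downsample
      for (region in ann$regions) {
        if (oracle_point_in_polygon(cx, cy, region$vertices)) {
          out[r, c] <- match(region$label, gp_classes())
        }
      }
    }
  }
  out
}

# brute-force weighted-sum argmax with lowest-index tie break
oracle_soft_vote <- function(prob_list, weights) {
  best <- 1L
  best_score <- -Inf
  for (i in 1:5) {
    s <- 0
    for (j in seq_along(prob_list)) s <- s + weights[j] * prob_list[[j]][i]
    if (s > best_score + 1e-12) {
      best <- i
      best_score <- s
    }
  }
  gp_classes()[best]
}

# brute-force per-pixel confusion tally
oracle_confusion <- function(labels, tile_px, gt_raster, downsample) {
  cm <- matrix(0, 5, 5)
  uncl <- rep(0, 5)
  for (r in seq_len(nrow(gt_raster))) {
    for (c in seq_len(ncol(gt_raster))) {
      g <- gt_raster[r, c]
      if (g == 0L) next
      tr <- floor(((r - 0.5) * downsample) / tile_px) + 1
      tc <- floor(((c - 0.5) * downsample) / tile_px) + 1
      p <- if (tr <= nrow(labels) && tc <= ncol(labels)) labels[tr, tc] else 0L
      if (p == 0L) uncl[g] <- uncl[g] + 1 else cm[g, p] <- cm[g, p] + 1
    }
  }
  list(cm = cm, unclassified = uncl)
}

# scalar per-channel Reinhard transfer of a single lalphabeta pixel
oracle_reinhard_pixel <- function(lab_px, src_mean, src_std, tgt_mean,
                                  tgt_std, eps = 1e-6) {
  sapply(1:3, function(ch) {
    (lab_px[ch] - src_mean[ch]) * tgt_std[ch] / max(src_std[ch], eps) +
      tgt_mean[ch]
  })
}
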