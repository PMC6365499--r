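test_that("overlay confusion matches direct construction on simple cases", {
  # perfect prediction over a 10x10 AC region, tile 10
  lab <- matrix(1L, 1, 1)
  map <- new_tumor_map(lab, 10, "s")
  gt <- structure(list(raster = matrix(1L, 10, 10), downsample = 1,
                       slide_id = "s"), class = "gp_gt_mask")
  cm <- confusion_from_overlay(map, gt)
  expect_equal(cm$counts["AC", "AC"], 100)
  expect_equal(sum(cm$counts), 100)

  # AC region predicted entirely NT
  mapNT <- new_tumor_map(matrix(5L, 1, 1), 10, "s")
  cm2 <- confusion_from_overlay(mapNT, gt)
  expect_equal(cm2$counts["AC", "NT"], 100)
  expect_equal(cm_metrics(cm2)$f1[["AC"]], 0)

  # 15x10 AC polygon spanning two tiles predicted (AC, SO)
  lab3 <- matrix(c(1L, 3L), 1, 2)
  map3 <- new_tumor_map(lab3, 10, "s")
  gt3 <- structure(list(raster = cbind(matrix(1L, 10, 15), matrix(0L, 10, 5)),
                        downsample = 1, slide_id = "s"),
                   class = "gp_gt_mask")
  cm3 <- confusion_from_overlay(map3, gt3)
  expect_equal(cm3$counts["AC", "AC"], 100)
  expect_equal(cm3$counts["AC", "SO"], 50)

  # annotated pixels over unclassified tiles are tallied separately
  map0 <- new_tumor_map(matrix(0L, 1, 2), 10, "s")
  cm0 <- confusion_from_overlay(map0, gt3)
  expect_equal(sum(cm0$counts), 0)
  expect_equal(cm0$unclassified[["AC"]], 150)

  gt_bad <- gt3; gt_bad$slide_id <- "other"
  expect_error(confusion_from_overlay(map3, gt_bad), "different slides")
})

test_that("overlay confusion equals the per-pixel oracle on random pairs", {
  withr::with_seed(11, {
    for (i in 1:25) {
      tile_px <- sample(c(8, 16), 1)
      n <- 64 %/% tile_px
      labels <- matrix(sample(0:5, n * n, replace = TRUE), n, n)
      d <- sample(c(1, 2), 1)
      gt_raster <- matrix(sample(0:5, (64 %/% d)^2, replace = TRUE),
                          64 %/% d, 64 %/% d)
      map <- new_tumor_map(labels, tile_px, "x")
      gt <- structure(list(raster = gt_raster, downsample = d,
                           slide_id = "x"), class = "gp_gt_mask")
      got <- confusion_from_overlay(map, gt)
      want <- oracle_confusion(labels, tile_px, gt_raster, d)
      expect_equal(unname(unclass(got$counts)), want$cm, info = i)
      expect_equal(unname(got$unclassified), want$unclassified, info = i)
    }
  })
})

test_that("aggregation sums entrywise and is order invariant", {
  withr::with_seed(12, {
    ms <- lapply(1:3, function(i) {
      new_confusion(matrix(sample(0:50, 25, replace = TRUE), 5, 5),
                    unclassified = sample(0:5, 5, replace = TRUE))
    })
  })
  zero <- new_confusion(matrix(0, 5, 5))
  expect_equal(aggregate_confusion(list(ms[[1]], zero))$counts,
               ms[[1]]$counts)
  agg <- aggregate_confusion(ms, level = "study")
  expect_equal(agg$counts, ms[[1]]$counts + ms[[2]]$counts + ms[[3]]$counts)
  expect_equal(agg$counts, aggregate_confusion(rev(ms))$counts)
  expect_identical(agg$level, "study")
  expect_error(aggregate_confusion(list()), "empty")
})

test_that("F1 and accuracy follow the closed formulas", {
  diag5 <- new_confusion(diag(c(10, 20, 30, 40, 50)))
  m <- cm_metrics(diag5)
  expect_equal(unname(m$f1), rep(1, 5))
  expect_equal(m$acc, 1)

  cm <- diag(100, 5); cm[1, ] <- c(50, 50, 0, 0, 0)
  got <- cm_metrics(new_confusion(cm))
  # oracle: recompute from per-class TP/FP/FN definitions
  expect_equal(got$f1[["AC"]], 2 * 50 / (2 * 50 + 0 + 50))
  expect_equal(got$f1[["MP"]], 2 * 100 / (2 * 100 + 50 + 0))
  expect_equal(got$acc, 450 / 500)

  off <- matrix(0, 5, 5); off[2, 4] <- 7
  expect_equal(cm_metrics(new_confusion(off))$acc, 0)
  expect_error(cm_metrics(new_confusion(matrix(0, 5, 5))), "all-zero")
})

test_that("study metrics equal metrics of pooled per-pixel records", {
  withr::with_seed(13, {
    slides <- lapply(1:4, function(i) {
      new_confusion(matrix(sample(0:30, 25, replace = TRUE), 5, 5))
    })
  })
  study <- aggregate_confusion(slides, level = "study")
  # pool raw per-pixel records, rebuild one matrix, compare metrics
  pooled <- matrix(0, 5, 5)
  for (s in slides) pooled <- pooled + s$counts
  expect_equal(cm_metrics(study), cm_metrics(new_confusion(pooled)))
})

test_that("tumor/non-tumor merging uses block summation", {
  expect_equal(merge_tumor_vs_nontumor(new_confusion(diag(1:5)))$acc, 1)
  # all AC predicted MP: within-tumor confusion vanishes after merging
  cm <- matrix(0, 5, 5); cm[1, 2] <- 80; cm[5, 5] <- 20
  expect_equal(merge_tumor_vs_nontumor(new_confusion(cm))$acc, 1)

  withr::with_seed(14, {
    m <- matrix(sample(0:40, 25, replace = TRUE), 5, 5)
  })
  got <- merge_tumor_vs_nontumor(new_confusion(m))
  want <- matrix(c(sum(m[1:4, 1:4]), sum(m[1:4, 5]),
                   sum(m[5, 1:4]), m[5, 5]), 2, 2, byrow = TRUE)
  expect_equal(unname(got$counts), want)
})

test_that("rank-sum test: exact enumeration and invariances", {
  sep <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p, 0.1)  # 2 / choose(6, 3)
  expect_identical(sep$method, "exact")

  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.99)

  a <- c(3.2, 5.1, 4.4, 8); b <- c(4.0, 6.5, 9.1)
  shifted <- wilcoxon_rank_sum(a + 100, b + 100)
  base <- wilcoxon_rank_sum(a, b)
  expect_equal(shifted$statistic, base$statistic)
  expect_equal(shifted$p, base$p)
  expect_error(wilcoxon_rank_sum(numeric(0), b), "non-empty")
})

test_that("signed-rank test: exact sign enumeration and conventions", {
  a <- c(10, 20, 30, 40, 50, 60)
  b <- a - c(1, 2, 3, 4, 5, 6)  # six positive distinct differences
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$p, 2 / 2^6)  # both one-sided extremes of the sign flips
  expect_identical(res$method, "exact")

  expect_warning(z <- wilcoxon_signed_rank(a, a), "zero")
  expect_equal(z$p, 1)

  swapped <- wilcoxon_signed_rank(b, a)
  expect_equal(swapped$p, res$p)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal")
})
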