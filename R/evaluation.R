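#' Construct a 5x5 confusion matrix object
#'
#' Rows are ground truth, columns are predicted class; entries are
#' non-negative pixel counts. An `unclassified` vector tallies annotated
#' pixels that fell over background (unclassified) tiles, kept separate
#' from the 5x5 matrix so they never bias the NT column.
#'
#' @param counts 5x5 numeric matrix (ground truth x predicted).
#' @param unclassified length-5 vector of annotated pixels over
#'   unclassified tiles, by ground-truth class.
#' @param level `"slide"`, `"set"` or `"study"`.
#' @return `gp_confusion`.
#' @export
new_confusion <- function(counts, unclassified = rep(0, 5),
                          level = "slide") {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(5L, 5L)), all(counts >= 0))
  dimnames(counts) <- list(truth = gp_classes(), predicted = gp_classes())
  structure(list(counts = counts,
                 unclassified = stats::setNames(as.numeric(unclassified),
                                                gp_classes()),
                 level = level),
            class = "gp_confusion")
}

#' @export
print.gp_confusion <- function(x, ...) {
  cat(sprintf("<gp_confusion> level=%s, %d annotated pixels (%d over ",
              x$level, sum(x$counts) + sum(x$unclassified),
              sum(x$unclassified)), "unclassified tiles)\n")
  print(x$counts)
  invisible(x)
}

#' Confusion matrix from a tumor map and a ground-truth mask
#'
#' Superimposes the tumor map onto the rasterized pathologist mask and
#' counts pixel detections at the mask's resolution: every annotated pixel
#' (ground-truth code != 0) whose covering tile carries a class increments
#' cell (truth, predicted); annotated pixels over background tiles are
#' tallied separately per ground-truth class.
#'
#' @param map `gp_tumor_map`.
#' @param gt `gp_gt_mask` in the same slide frame.
#' @return `gp_confusion` at slide level.
#' @export
confusion_from_overlay <- function(map, gt) {
  stopifnot(inherits(map, "gp_tumor_map"), inherits(gt, "gp_gt_mask"))
  if (!identical(map$slide_id, gt$slide_id)) {
    stop("tumor map and ground-truth mask refer to different slides",
         call. = FALSE)
  }
  d <- gt$downsample
  nr <- nrow(gt$raster); nc <- ncol(gt$raster)
  # tile covering each mask pixel, by pixel-center level-0 coordinates
  pr <- pmin(floor(((seq_len(nr) - 0.5) * d) / map$tile_px) + 1L,
             nrow(map$labels) + 1L)
  pc <- pmin(floor(((seq_len(nc) - 0.5) * d) / map$tile_px) + 1L,
             ncol(map$labels) + 1L)
  padded <- rbind(cbind(map$labels, 0L), 0L)  # beyond-grid pixels -> code 0
  pred <- padded[pr, pc, drop = FALSE]
  sel <- gt$raster != 0L
  tab <- table(factor(gt$raster[sel], levels = 1:5),
               factor(pred[sel], levels = 0:5))
  new_confusion(unclass(tab)[, 2:6, drop = FALSE],
                unclassified = as.numeric(tab[, 1]), level = "slide")
}

#' Aggregate confusion matrices by entrywise summation
#'
#' @param matrices non-empty list of `gp_confusion`.
#' @param level level tag of the aggregate (default `"set"`).
#' @return `gp_confusion`.
#' @export
aggregate_confusion <- function(matrices, level = "set") {
  if (length(matrices) == 0L) {
    stop("cannot aggregate an empty list of confusion matrices",
         call. = FALSE)
  }
  stopifnot(all(vapply(matrices, inherits, logical(1), "gp_confusion")))
  counts <- Reduce(`+`, lapply(matrices, `[[`, "counts"))
  uncl <- Reduce(`+`, lapply(matrices, `[[`, "unclassified"))
  new_confusion(counts, uncl, level = level)
}

#' F1-scores and accuracy from a confusion matrix
#'
#' Per class i: `F1_i = 2 TP_i / (2 TP_i + FP_i + FN_i)` with
#' `TP_i = cm[i, i]`, FP the column sum minus TP, FN the row sum minus TP
#' (F1 defined as 0 when the denominator is 0); `ACC = trace / total`.
#'
#' @param cm `gp_confusion` with a positive total.
#' @return list with named `f1` (length 5) and scalar `acc`.
#' @export
cm_metrics <- function(cm) {
  stopifnot(inherits(cm, "gp_confusion"))
  m <- cm$counts
  if (sum(m) == 0) stop("all-zero confusion matrix", call. = FALSE)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  den <- 2 * tp + fp + fn
  f1 <- ifelse(den == 0, 0, 2 * tp / den)
  list(f1 = stats::setNames(as.numeric(f1), gp_classes()),
       acc = sum(tp) / sum(m))
}

#' Merge the four growth patterns into one tumor category
#'
#' Rows/columns AC, MP, SO, CR are summed into "tumor"; NT stays
#' "non-tumor". Within-tumor confusion therefore no longer counts as error.
#'
#' @param cm `gp_confusion`.
#' @return list with the 2x2 `counts` matrix (tumor, non-tumor), named
#'   binary `f1` pair and scalar `acc`.
#' @export
merge_tumor_vs_nontumor <- function(cm) {
  stopifnot(inherits(cm, "gp_confusion"))
  m <- cm$counts
  t_idx <- 1:4
  m2 <- matrix(c(sum(m[t_idx, t_idx]), sum(m[t_idx, 5]),
                 sum(m[5, t_idx]), m[5, 5]),
               2, 2, byrow = TRUE,
               dimnames = list(truth = c("tumor", "non-tumor"),
                               predicted = c("tumor", "non-tumor")))
  tp <- diag(m2); fp <- colSums(m2) - tp; fn <- rowSums(m2) - tp
  den <- 2 * tp + fp + fn
  f1 <- ifelse(den == 0, 0, 2 * tp / den)
  list(counts = m2,
       f1 = stats::setNames(as.numeric(f1), c("tumor", "non-tumor")),
       acc = sum(tp) / sum(m2))
}

#' Two-sided Wilcoxon rank sum test
#'
#' Exact p-value by enumeration when the combined sample size is at most
#' `exact_max` and there are no ties; normal approximation with tie
#' correction (and continuity correction) otherwise.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param exact_max combined-size cutoff for the exact path (default 12).
#' @return list with `statistic` (rank-sum W of `sample_a`), `p`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b, exact_max = 12) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  no_ties <- !anyDuplicated(c(sample_a, sample_b))
  exact <- (length(sample_a) + length(sample_b)) <= exact_max && no_ties
  ht <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Two-sided Wilcoxon signed rank test on paired samples
#'
#' Differences of exactly zero are dropped (documented convention); the
#' p-value is exact for at most `exact_max` non-zero untied differences and
#' a normal approximation otherwise. If every difference is zero the test
#' is degenerate and p = 1 is returned with a warning.
#'
#' @param paired_a,paired_b numeric vectors of equal length >= 1.
#' @param exact_max cutoff for the exact path (default 12).
#' @return list with `statistic` (V), `p`, `method`, `n_used`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_max = 12) {
  if (length(paired_a) != length(paired_b) || length(paired_a) == 0L) {
    stop("paired samples must have equal, positive length", call. = FALSE)
  }
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; p = 1 by convention")
    return(list(statistic = 0, p = 1, method = "degenerate", n_used = 0L))
  }
  exact <- length(d) <= exact_max && !anyDuplicated(abs(d))
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal approximation",
       n_used = length(d))
}
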