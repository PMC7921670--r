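# Segmentation and detection evaluation (DICE + confusion-rate panel,
# point-detection and object-level P/R/F1) and the group statistics used at
# slide level (rank tests, Cohen's d with its effect-size bands, Spearman).

#' Pixelwise segmentation metrics
#'
#' Computes the pixel confusion counts of a predicted binary mask against a
#' ground-truth mask together with DICE, PPV, NPV, TPR, TNR, FPR and FNR.
#' Ratios with a zero denominator are reported as `NA` rather than 0. Also
#' emits a four-colour overlap raster (TP green, FN magenta, FP yellow,
#' TN blue).
#'
#' @param pred,gt logical/0-1 matrices of equal shape.
#' @return list with the counts, the derived rates and `overlay`
#'   (an `(H, W, 3)` RGB array).
#' @export
segMetrics <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("mask shapes differ")
  p <- pred > 0; g <- gt > 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  dice <- sdiv(2 * tp, 2 * tp + fp + fn)
  tpr <- sdiv(tp, tp + fn)
  tnr <- sdiv(tn, tn + fp)
  # colour legend: TP (0,0.8,0)  FN (1,0,1)  FP (1,1,0)  TN (0,0,1)
  overlay <- array(0, dim = c(nrow(p), ncol(p), 3))
  overlay[, , 1] <- (p & !g) + (!p & g)
  overlay[, , 2] <- 0.8 * (p & g) + (p & !g)
  overlay[, , 3] <- (!p & g) + (!p & !g)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       dice = dice,
       ppv = sdiv(tp, tp + fp),
       npv = sdiv(tn, tn + fn),
       tpr = tpr, tnr = tnr,
       fpr = if (is.na(tnr)) NA_real_ else 1 - tnr,
       fnr = if (is.na(tpr)) NA_real_ else 1 - tpr,
       overlay = overlay)
}

#' Match predicted and ground-truth point detections
#'
#' Greedy one-to-one matching in ascending distance order; a pair is a match
#' only when its distance is at most `radius_px`. Precision with no
#' predictions is reported missing; F1 is 0 by convention when there are no
#' true positives.
#'
#' @param pred,gt matrices/data.frames of point coordinates (x, y).
#' @param radius_px maximum matching distance in pixels.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
matchPointDetections <- function(pred, gt, radius_px) {
  stopifnot(radius_px > 0)
  pred <- as.matrix(as.data.frame(pred)[, 1:2, drop = FALSE])
  gt <- as.matrix(as.data.frame(gt)[, 1:2, drop = FALSE])
  np <- nrow(pred); ng <- nrow(gt)
  tp <- 0L
  if (np > 0 && ng > 0) {
    d <- sqrt(outer(pred[, 1], gt[, 1], "-")^2 +
              outer(pred[, 2], gt[, 2], "-")^2)
    cand <- which(d <= radius_px, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_p <- logical(np); used_g <- logical(ng)
      for (i in seq_len(nrow(cand))) {
        pi <- cand[i, 1]; gi <- cand[i, 2]
        if (!used_p[pi] && !used_g[gi]) {
          used_p[pi] <- TRUE; used_g[gi] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- np - tp; fn <- ng - tp
  precision <- if (np == 0) NA_real_ else tp / np
  recall <- if (ng == 0) NA_real_ else tp / ng
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}

#' Object-level duct detection precision/recall/F1
#'
#' Pairs predicted and ground-truth duct objects greedily by descending
#' intersection-over-union; a pair counts as a true positive when its IoU
#' reaches `iou_threshold`. Objects are given as integer label masks
#' (0 = background), so IoU is exact pixel overlap.
#'
#' @param pred_labels,gt_labels integer label matrices of equal shape.
#' @param iou_threshold IoU needed to count a match, in (0, 1); default 0.5.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
ductDetectionPrf <- function(pred_labels, gt_labels, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold < 1,
            all(dim(pred_labels) == dim(gt_labels)))
  np <- max(pred_labels); ng <- max(gt_labels)
  tp <- 0L
  if (np > 0 && ng > 0) {
    both <- pred_labels > 0 & gt_labels > 0
    inter <- table(factor(pred_labels[both], levels = 1:np),
                   factor(gt_labels[both], levels = 1:ng))
    ap <- tabulate(pred_labels[pred_labels > 0], np)
    ag <- tabulate(gt_labels[gt_labels > 0], ng)
    iou <- as.matrix(inter) /
      (outer(ap, ag, "+") - as.matrix(inter))
    cand <- which(iou >= iou_threshold, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(-iou[cand]), , drop = FALSE]
      used_p <- logical(np); used_g <- logical(ng)
      for (i in seq_len(nrow(cand))) {
        if (!used_p[cand[i, 1]] && !used_g[cand[i, 2]]) {
          used_p[cand[i, 1]] <- TRUE; used_g[cand[i, 2]] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- np - tp; fn <- ng - tp
  precision <- if (np == 0) NA_real_ else tp / np
  recall <- if (ng == 0) NA_real_ else tp / ng
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}

#' Compare two groups of slide scores
#'
#' Two-sided Wilcoxon test (unpaired rank-sum by default, paired signed-rank
#' on request) plus Cohen's d with pooled standard deviation, banded as
#' small (|d| <= 0.2), medium (0.2 < |d| <= 0.5) or large (|d| > 0.5).
#'
#' @param a,b numeric score vectors (each length >= 2).
#' @param paired use the paired signed-rank flavour.
#' @return list with `wilcoxon_p`, `cohens_d`, `d_band`.
#' @export
groupCompare <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  p <- suppressWarnings(stats::wilcox.test(a, b, paired = paired)$p.value)
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
             (na + nb - 2))
  d <- if (sp == 0) NA_real_ else (mean(a) - mean(b)) / sp
  list(wilcoxon_p = p, cohens_d = d, d_band = cohensBand(d))
}

#' @rdname groupCompare
#' @param d a Cohen's d value.
#' @export
cohensBand <- function(d) {
  if (is.na(d)) return(NA_character_)
  ad <- abs(d)
  if (ad <= 0.2) "small" else if (ad <= 0.5) "medium" else "large"
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and the t-approximation
#' p-value. A constant vector leaves the coefficient undefined (`NA`).
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearmanCor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
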