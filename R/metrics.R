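# Evaluation metrics: MAE/RMSE for lengths, pixel-wise segmentation scores
# for centerline maps, and COCO-style mask AP with 101-point interpolation.

#' Mean absolute error and root mean squared error
#'
#' `MAE = mean(|y - yhat|)`, `RMSE = sqrt(mean((y - yhat)^2))`. By
#' Cauchy-Schwarz `RMSE >= MAE`, with equality iff all absolute errors are
#' equal.
#'
#' @param truth,pred equal-length non-empty numeric vectors.
#' @return list with `mae` and `rmse`.
#' @export
mae_rmse <- function(truth, pred) {
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(pred)) stop("length mismatch")
  e <- truth - pred
  list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Pixel-wise centerline segmentation scores
#'
#' Binarizes the prediction at `threshold` and scores it against the 3-px
#' target: precision, recall, F1 (harmonic mean), and mIoU, the mean of the
#' foreground IoU `TP / (TP + FP + FN)` and the background IoU (two-class
#' convention). Degenerate ratios (0/0) are defined as 0.
#'
#' @param pred probability or binary matrix.
#' @param target binary matrix of the same size.
#' @param threshold binarization threshold for a probabilistic `pred`.
#' @return object of class `centerline_scores`: list with `precision`,
#'   `recall`, `f1`, `miou`, `threshold`.
#' @export
centerline_scores <- function(pred, target, threshold = 0.5) {
  if (!all(dim(pred) == dim(target))) stop("pred/target shape mismatch")
  p <- pred >= threshold
  y <- target > 0
  tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y)
  tn <- sum(!p & !y)
  ratio <- function(num, den) if (den == 0) 0 else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  iou_fg <- ratio(tp, tp + fp + fn)
  iou_bg <- ratio(tn, tn + fp + fn)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 miou = mean(c(iou_fg, iou_bg)), iou_fg = iou_fg,
                 threshold = threshold),
            class = "centerline_scores")
}

#' @export
print.centerline_scores <- function(x, ...) {
  cat(sprintf(
    "<centerline_scores> P %.3f  R %.3f  F1 %.3f  mIoU %.3f (thr %.2f)\n",
    x$precision, x$recall, x$f1, x$miou, x$threshold))
  invisible(x)
}

#' COCO-style mask average precision
#'
#' Score-descending greedy matching per image at each IoU threshold (every
#' ground truth matched at most once, predictions match the best-IoU unmatched
#' truth); AP is the area under the interpolated precision-recall curve using
#' the COCO 101-point convention. `ap50_95` averages thresholds
#' 0.50:0.05:0.95.
#'
#' @param preds list of `shrimp_detections` (one per image), or a single one.
#' @param truths list of per-image lists of ground-truth masks.
#' @param iou_thresholds IoU thresholds to evaluate.
#' @return list with `ap` (named per threshold), `ap50`, `ap75`, `ap50_95`.
#' @export
mask_ap <- function(preds, truths,
                    iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (inherits(preds, "shrimp_detections")) preds <- list(preds)
  if (length(truths) && is.matrix(truths[[1]])) truths <- list(truths)
  if (length(preds) != length(truths))
    stop("one truth set per image is required")
  for (p in preds)
    if (length(p$masks) && is.null(p$scores))
      stop("predictions must carry scores")
  n_truth <- sum(vapply(truths, length, 1L))
  # flatten predictions with provenance, order by score (deterministic ties)
  img <- integer(0); idx <- integer(0); sc <- numeric(0)
  for (i in seq_along(preds)) {
    k <- length(preds[[i]]$masks)
    if (k) {
      img <- c(img, rep(i, k)); idx <- c(idx, seq_len(k))
      sc <- c(sc, preds[[i]]$scores)
    }
  }
  ord <- order(-sc, img, idx)
  # IoU of each prediction against each truth of its image (computed once)
  ious <- lapply(seq_along(img), function(j) {
    m <- preds[[img[j]]]$masks[[idx[j]]]
    vapply(truths[[img[j]]], function(t) mask_iou(m, t), 1.0)
  })
  ap <- vapply(iou_thresholds, function(thr) {
    used <- lapply(truths, function(t) logical(length(t)))
    tp <- fp <- numeric(length(ord))
    for (r in seq_along(ord)) {
      j <- ord[r]
      iou <- ious[[j]]
      avail <- which(!used[[img[j]]] & iou >= thr)
      if (length(avail)) {
        best <- avail[which.max(iou[avail])]
        used[[img[j]]][best] <- TRUE
        tp[r] <- 1
      } else fp[r] <- 1
    }
    ap_from_counts(cumsum(tp), cumsum(fp), n_truth)
  }, 1.0)
  names(ap) <- sprintf("%.2f", iou_thresholds)
  list(ap = ap,
       ap50 = unname(ap["0.50"]),
       ap75 = if ("0.75" %in% names(ap)) unname(ap["0.75"]) else NA_real_,
       ap50_95 = mean(ap))
}

# 101-point interpolated AP from cumulative TP/FP counts.
ap_from_counts <- function(ctp, cfp, n_truth) {
  if (n_truth == 0) return(NA_real_)
  if (length(ctp) == 0) return(0)
  recall <- ctp / n_truth
  precision <- ctp / (ctp + cfp)
  # precision envelope (monotone non-increasing from the right)
  for (i in rev(seq_len(length(precision) - 1)))
    precision[i] <- max(precision[i], precision[i + 1])
  rq <- seq(0, 1, by = 0.01)
  pq <- vapply(rq, function(r) {
    ok <- which(recall >= r)
    if (length(ok)) precision[ok[1]] else 0
  }, 1.0)
  mean(pq)
}
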