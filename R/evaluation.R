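# Detection metrics: IoU, greedy matching, average precision with the
# all-point (continuous) interpolation, per-class P/R/F1, mAP over
# configurable IoU thresholds, and stratified k-fold drivers.

#' Intersection-over-union of axis-aligned boxes
#'
#' Vectorized: `a` and `b` are matrices/data.frames with columns
#' xmin, ymin, xmax, ymax; returns the nrow(a) x nrow(b) IoU matrix
#' (0 for disjoint pairs).
#'
#' @param a,b box coordinates (one row per box).
#' @return IoU matrix in [0, 1].
#' @export
boxIou <- function(a, b) {
  am <- as.matrix(as.data.frame(a)[, c("xmin", "ymin", "xmax", "ymax")])
  bm <- as.matrix(as.data.frame(b)[, c("xmin", "ymin", "xmax", "ymax")])
  n <- nrow(am); m <- nrow(bm)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  ix <- pmax(0, outer(am[, 3], bm[, 3], pmin) - outer(am[, 1], bm[, 1], pmax))
  iy <- pmax(0, outer(am[, 4], bm[, 4], pmin) - outer(am[, 2], bm[, 2], pmax))
  inter <- ix * iy
  area_a <- (am[, 3] - am[, 1]) * (am[, 4] - am[, 2])
  area_b <- (bm[, 3] - bm[, 1]) * (bm[, 4] - bm[, 2])
  un <- outer(area_a, area_b, `+`) - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}

#' Greedy detection-to-ground-truth matching
#'
#' Detections are processed in decreasing confidence; each matches the
#' highest-IoU unmatched ground-truth box of the same class with IoU at or
#' above the threshold. A threshold of exactly 0 means any-overlap matching
#' (IoU > 0), the classification-like evaluation mode. Each ground truth is
#' matched at most once.
#'
#' @param dets detection table (label, xmin..ymax, confidence).
#' @param gts ground-truth table (label, xmin..ymax).
#' @param iou_threshold matching threshold in [0, 1).
#' @return data.frame: the detections (sorted by confidence descending) with
#'   logical `tp` and the matched GT row index (NA for FP).
#' @export
matchDetections <- function(dets, gts, iou_threshold = 0.5) {
  if (nrow(dets) == 0) {
    out <- dets
    out$tp <- logical(0)
    out$gt <- integer(0)
    return(out)
  }
  ord <- order(-dets$confidence)
  dets <- dets[ord, , drop = FALSE]
  rownames(dets) <- NULL
  tp <- logical(nrow(dets))
  gt_match <- rep(NA_integer_, nrow(dets))
  taken <- rep(FALSE, nrow(gts))
  if (nrow(gts) > 0) {
    iou <- boxIou(dets, gts)
    for (i in seq_len(nrow(dets))) {
      cand <- which(!taken & gts$label == dets$label[i])
      if (length(cand) == 0) next
      ious <- iou[i, cand]
      j <- cand[which.max(ious)]
      best <- iou[i, j]
      hit <- if (iou_threshold > 0) best >= iou_threshold else best > 0
      if (hit) {
        tp[i] <- TRUE
        gt_match[i] <- j
        taken[j] <- TRUE
      }
    }
  }
  dets$tp <- tp
  dets$gt <- gt_match
  dets
}

#' Average precision from TP/FP flags (all-point interpolation)
#'
#' Builds the precision-recall curve from cumulative TP/FP counts in
#' decreasing-confidence order and integrates the precision envelope over
#' recall (VOC-2010-style continuous interpolation).
#'
#' @param tp logical flags per detection.
#' @param confidence matching confidences (used only for ordering).
#' @param n_gt number of ground-truth instances of the class.
#' @return AP in [0, 1]; NA when `n_gt` is 0 and there are no detections,
#'   0 when there are ground truths but no detections.
#' @export
averagePrecision <- function(tp, confidence, n_gt) {
  if (n_gt == 0 && length(tp) == 0) return(NA_real_)
  if (n_gt == 0) return(0)
  if (length(tp) == 0) return(0)
  ord <- order(-confidence)
  tp <- tp[ord]
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  # precision envelope: running max from the right
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Evaluate detections against ground truth over IoU thresholds
#'
#' Aggregates greedy matches per class over all images; AP uses the full
#' confidence range, while precision/recall/F1 are read off at the
#' operating confidence threshold. mAP averages the AP of classes with at
#' least one ground-truth instance.
#'
#' @param dets_list list of detection tables (or [DetectionSet-class]),
#'   one per image.
#' @param gts_list list of ground-truth tables (or [LabeledImage-class]),
#'   one per image, aligned with `dets_list`.
#' @param iou_thresholds numeric vector of matching thresholds.
#' @param conf_threshold operating confidence for P/R/F1.
#' @param classes class list; detections outside it raise an error.
#' @return a named list of [EvalResult-class], one per threshold.
#' @export
evaluateDetections <- function(dets_list, gts_list, iou_thresholds = 0.5,
                               conf_threshold = 0.25, classes = NULL) {
  stopifnot(length(dets_list) == length(gts_list))
  dets_list <- lapply(dets_list, function(d) {
    if (is(d, "DetectionSet")) d@detections else d
  })
  gts_list <- lapply(gts_list, function(g) {
    if (is(g, "LabeledImage")) g@boxes else g
  })
  if (is.null(classes)) {
    classes <- sort(unique(c(
      unlist(lapply(gts_list, function(g) g$label)),
      unlist(lapply(dets_list, function(d) d$label))
    )))
  }
  det_classes <- unique(unlist(lapply(dets_list, function(d) d$label)))
  unknown <- setdiff(det_classes, classes)
  if (length(unknown) > 0) {
    stop("detections carry classes outside the class list: ",
         paste(unknown, collapse = ", "))
  }
  out <- list()
  for (thr in iou_thresholds) {
    recs <- list()
    for (i in seq_along(dets_list)) {
      m <- matchDetections(dets_list[[i]], gts_list[[i]], iou_threshold = thr)
      if (nrow(m) > 0) recs[[length(recs) + 1L]] <- m[, c("label", "confidence", "tp")]
    }
    all_m <- if (length(recs)) do.call(rbind, recs) else
      data.frame(label = character(), confidence = numeric(), tp = logical())
    n_gt <- vapply(classes, function(cl) {
      sum(vapply(gts_list, function(g) sum(g$label == cl), 1))
    }, 1)
    per <- lapply(classes, function(cl) {
      mm <- all_m[all_m$label == cl, , drop = FALSE]
      ap <- averagePrecision(mm$tp, mm$confidence, n_gt[[cl]])
      op <- mm[mm$confidence >= conf_threshold, , drop = FALSE]
      tp <- sum(op$tp)
      fp <- sum(!op$tp)
      fn <- n_gt[[cl]] - tp
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (n_gt[[cl]] > 0) tp / n_gt[[cl]] else 0
      f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
      data.frame(class = cl, n_gt = n_gt[[cl]], tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r, ap = ap, f1 = f1,
                 stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, per)
    rownames(per) <- NULL
    aps <- per$ap[per$n_gt > 0]
    mAP <- if (length(aps)) mean(aps) else NA_real_
    out[[sprintf("iou_%g", thr)]] <- new(
      "EvalResult", perClass = per, mAP = mAP,
      iouThreshold = thr, confThreshold = conf_threshold
    )
  }
  out
}

#' Stratified k-fold cross-validation splits
#'
#' Folds are stratified per class with sizes within one image of equal;
#' every item appears in exactly one test fold.
#'
#' @param manifest manifest with a `class` column.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of k elements, each list(train=, test=) of manifests.
#' @export
kfoldSplits <- function(manifest, k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  fold <- rep(NA_integer_, nrow(manifest))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(manifest$class)) {
      idx <- which(manifest$class == cls)
      if (length(idx) < k) {
        warning(sprintf("class '%s' has fewer items (%d) than folds (%d)",
                        cls, length(idx), k))
      }
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    te <- manifest[fold == f, , drop = FALSE]
    tr <- manifest[fold != f, , drop = FALSE]
    rownames(te) <- NULL
    rownames(tr) <- NULL
    list(train = tr, test = te)
  })
}
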