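# VegetableDet assembly: lightweight conv stem + CSP backbone with DAT
# blocks at the stride-16/32 stages, a feature-pyramid neck with one CSAAM
# after each fusion, and an anchor-free centre-based head with class, box
# and objectness branches over strides 8/16/32.
#
# The head is a deliberate hybrid: anchor-free box regression (log-distance
# to the four box sides, in stride units) combined with an objectness
# branch so that the composite loss carries the configured IoU / class /
# objectness gains (0.05 / 0.5 / 1.0).

make_div <- function(x, by = 4L, lo = 4L) as.integer(pmax(round(x / by) * by, lo))

#' Default loss gains and training-assignment threshold
#' @export
defaultLossGains <- function() c(box = 0.05, cls = 0.5, obj = 1.0)

#' Build the VegetableDet detector
#'
#' @param num_classes number of classes (>= 1).
#' @param width_multiple channel width multiplier; the default yields the
#'   lightweight configuration within the published parameter budget.
#' @param use_dat insert DAT (window + deformable) blocks at the stride-16
#'   and stride-32 backbone stages.
#' @param use_csaam insert one CSAAM after each neck fusion.
#' @param window_size local-attention window side of the DAT blocks.
#' @param mlp_ratio transformer MLP expansion.
#' @param offset_range_factor deformable offset bound (grid cells).
#' @param seed integer seed for weight initialization.
#' @return model environment: `$params` (named parameter tensors whose name
#'   prefix backbone/neck/head is the transfer-learning partition),
#'   `$states` (batch-norm statistics), `$forward(x, train)` returning
#'   per-level head outputs, `$strides`, `$num_classes`, `$cfg`.
#' @export
buildModel <- function(num_classes, width_multiple = 0.75, use_dat = TRUE,
                       use_csaam = TRUE, window_size = 4L, mlp_ratio = 4L,
                       offset_range_factor = 2, seed = 0L) {
  stopifnot(num_classes >= 1)
  if (!is.numeric(width_multiple) || width_multiple <= 0 || width_multiple > 4) {
    stop("invalid width_multiple: ", width_multiple)
  }
  withr::with_seed(as.integer(seed), {
    ctx <- new_ctx()
    ch <- make_div(c(16, 32, 64, 128, 256) * width_multiple)
    c1 <- ch[1]; c2 <- ch[2]; c3 <- ch[3]; c4 <- ch[4]; c5 <- ch[5]
    heads4 <- max(1L, c4 %/% 32L)
    heads5 <- max(1L, c5 %/% 32L)

    stem <- nnConvBnAct(ctx, "backbone.stem", 3L, c1, k = 3L, stride = 2L)
    d2 <- nnConvBnAct(ctx, "backbone.d2", c1, c2, k = 3L, stride = 2L)
    b2 <- nnCspBlock(ctx, "backbone.c2", c2, n = 1L)
    d3 <- nnConvBnAct(ctx, "backbone.d3", c2, c3, k = 3L, stride = 2L)
    b3 <- nnCspBlock(ctx, "backbone.c3", c3, n = 2L)
    d4 <- nnConvBnAct(ctx, "backbone.d4", c3, c4, k = 3L, stride = 2L)
    b4 <- nnCspBlock(ctx, "backbone.c4", c4, n = 2L)
    d5 <- nnConvBnAct(ctx, "backbone.d5", c4, c5, k = 3L, stride = 2L)
    b5 <- nnCspBlock(ctx, "backbone.c5", c5, n = 1L)
    if (use_dat) {
      dat4w <- nnWindowBlock(ctx, "backbone.dat4.win", c4, window_size, 0L,
                             heads4, mlp_ratio)
      dat4d <- nnDeformBlock(ctx, "backbone.dat4.def", c4, heads4,
                             orf = offset_range_factor, mlp_ratio = mlp_ratio)
      dat5w <- nnWindowBlock(ctx, "backbone.dat5.win", c5, window_size, 0L,
                             heads5, mlp_ratio)
      dat5d <- nnDeformBlock(ctx, "backbone.dat5.def", c5, heads5,
                             orf = offset_range_factor, mlp_ratio = mlp_ratio)
    }

    lat5 <- nnConvBnAct(ctx, "neck.lat5", c5, c4, k = 1L)
    fuse4 <- nnConvBnAct(ctx, "neck.fuse4", 2L * c4, c4, k = 1L)
    lat4 <- nnConvBnAct(ctx, "neck.lat4", c4, c3, k = 1L)
    fuse3 <- nnConvBnAct(ctx, "neck.fuse3", 2L * c3, c3, k = 1L)
    down3 <- nnConvBnAct(ctx, "neck.down3", c3, c3, k = 3L, stride = 2L)
    fuse4b <- nnConvBnAct(ctx, "neck.fuse4b", c3 + c4, c4, k = 1L)
    down4 <- nnConvBnAct(ctx, "neck.down4", c4, c4, k = 3L, stride = 2L)
    fuse5 <- nnConvBnAct(ctx, "neck.fuse5", 2L * c4, c5, k = 1L)
    if (use_csaam) {
      cs3 <- nnCsaam(ctx, "neck.csaam3", c3)
      cs4 <- nnCsaam(ctx, "neck.csaam4", c4)
      cs4b <- nnCsaam(ctx, "neck.csaam4b", c4)
      cs5 <- nnCsaam(ctx, "neck.csaam5", c5)
    }

    hc <- c3
    lvl_ch <- c(c3, c4, c5)
    heads_fns <- lapply(1:3, function(l) {
      stemf <- nnConvBnAct(ctx, sprintf("head.l%d.stem", l), lvl_ch[l], hc, k = 3L)
      clsf <- nnConv(ctx, sprintf("head.l%d.cls", l), hc, num_classes, k = 1L,
                     bias_init = -4)
      boxf <- nnConv(ctx, sprintf("head.l%d.box", l), hc, 4L, k = 1L,
                     zero_init = TRUE)
      objf <- nnConv(ctx, sprintf("head.l%d.obj", l), hc, 1L, k = 1L,
                     bias_init = -4)
      list(stem = stemf, cls = clsf, box = boxf, obj = objf)
    })

    model <- new.env(parent = emptyenv())
    model$params <- ctx$params
    model$states <- ctx$states
    model$strides <- c(8L, 16L, 32L)
    model$num_classes <- as.integer(num_classes)
    model$cfg <- list(num_classes = as.integer(num_classes),
                      width_multiple = width_multiple, use_dat = use_dat,
                      use_csaam = use_csaam, window_size = as.integer(window_size),
                      mlp_ratio = as.integer(mlp_ratio),
                      offset_range_factor = offset_range_factor,
                      seed = as.integer(seed), channels = ch)
    model$forward <- function(x, train = FALSE) {
      if (!inherits(x, "ag_tensor")) {
        x <- as_3hw(x)
        if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
        x <- agConst(x)
      }
      x <- stem(x, train)
      x <- b2(d2(x, train), train)
      p3 <- b3(d3(x, train), train)
      p4 <- b4(d4(p3, train), train)
      if (use_dat) p4 <- dat4d(dat4w(p4, train), train)
      p5 <- b5(d5(p4, train), train)
      if (use_dat) p5 <- dat5d(dat5w(p5, train), train)

      l5 <- lat5(p5, train)
      t4 <- fuse4(agConcatC(list(p4, agUpsample2(l5))), train)
      if (use_csaam) t4 <- cs4(t4, train)
      l4 <- lat4(t4, train)
      n3 <- fuse3(agConcatC(list(p3, agUpsample2(l4))), train)
      if (use_csaam) n3 <- cs3(n3, train)
      n4 <- fuse4b(agConcatC(list(down3(n3, train), t4)), train)
      if (use_csaam) n4 <- cs4b(n4, train)
      n5 <- fuse5(agConcatC(list(down4(n4, train), l5)), train)
      if (use_csaam) n5 <- cs5(n5, train)

      feats <- list(n3, n4, n5)
      lapply(1:3, function(l) {
        h <- heads_fns[[l]]$stem(feats[[l]], train)
        list(box = heads_fns[[l]]$box(h, train),
             obj = heads_fns[[l]]$obj(h, train),
             cls = heads_fns[[l]]$cls(h, train))
      })
    }
    model
  })
}

# ---- target assignment ----------------------------------------------------

level_centers <- function(Hl, Wl, stride) {
  list(
    cx = (rep(seq_len(Wl), each = Hl) - 0.5) * stride,
    cy = (rep(seq_len(Hl), times = Wl) - 0.5) * stride
  )
}

#' Assign ground-truth boxes to head locations
#'
#' A location is a positive candidate for a box when its prior (a square of
#' `prior_scale` x stride per side centred on the cell) overlaps the box
#' with IoU at or above the threshold and the cell centre lies inside the
#' box; locations claimed by several boxes go to the nearest box centre.
#' Every ground truth without a candidate is force-assigned its best-IoU
#' location so no target is unsupervised.
#'
#' @param gt ground-truth box table.
#' @param image_size (height, width) in pixels.
#' @param strides head strides.
#' @param iou_threshold training assignment threshold (published default
#'   0.2).
#' @param prior_scale prior side length in stride units.
#' @param classes class list mapping labels to indices.
#' @return data.frame: level, iy, ix, gt (row index into `gt`), forced flag.
#' @export
assignTargets <- function(gt, image_size, strides = c(8L, 16L, 32L),
                          iou_threshold = 0.2, prior_scale = 4L,
                          classes = NULL) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  H <- image_size[1]; W <- image_size[2]
  empty <- data.frame(level = integer(), iy = integer(), ix = integer(),
                      gt = integer(), forced = logical())
  if (nrow(gt) == 0) return(empty)
  rows <- list()
  best_global <- data.frame(gt = seq_len(nrow(gt)), iou = -1,
                            level = NA_integer_, iy = NA_integer_,
                            ix = NA_integer_)
  for (l in seq_along(strides)) {
    s <- strides[l]
    Hl <- as.integer(ceiling(H / s)); Wl <- as.integer(ceiling(W / s))
    ctr <- level_centers(Hl, Wl, s)
    half <- prior_scale * s / 2
    priors <- data.frame(xmin = ctr$cx - half, ymin = ctr$cy - half,
                         xmax = ctr$cx + half, ymax = ctr$cy + half)
    iou <- boxIou(priors, gt) # (cells x gts)
    inside <- outer(ctr$cx, gt$xmin, `>`) & outer(ctr$cx, gt$xmax, `<`) &
      outer(ctr$cy, gt$ymin, `>`) & outer(ctr$cy, gt$ymax, `<`)
    cand <- iou >= iou_threshold & inside
    for (g in seq_len(nrow(gt))) {
      j <- which.max(iou[, g])
      if (iou[j, g] > best_global$iou[g]) {
        best_global$iou[g] <- iou[j, g]
        best_global$level[g] <- l
        best_global$iy[g] <- (j - 1L) %% Hl + 1L
        best_global$ix[g] <- (j - 1L) %/% Hl + 1L
      }
    }
    pos_cells <- which(rowSums(cand) > 0)
    for (j in pos_cells) {
      gs <- which(cand[j, ])
      if (length(gs) > 1L) {
        gcx <- (gt$xmin[gs] + gt$xmax[gs]) / 2
        gcy <- (gt$ymin[gs] + gt$ymax[gs]) / 2
        dd <- (gcx - ctr$cx[j])^2 + (gcy - ctr$cy[j])^2
        gs <- gs[which.min(dd)]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        level = l, iy = (j - 1L) %% Hl + 1L, ix = (j - 1L) %/% Hl + 1L,
        gt = gs, forced = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  # forced best match for uncovered ground truths
  missing <- setdiff(seq_len(nrow(gt)), unique(out$gt))
  for (g in missing) {
    bg <- best_global[g, ]
    clash <- out$level == bg$level & out$iy == bg$iy & out$ix == bg$ix
    out <- out[!clash, , drop = FALSE]
    out <- rbind(out, data.frame(level = bg$level, iy = bg$iy, ix = bg$ix,
                                 gt = g, forced = TRUE))
  }
  rownames(out) <- NULL
  out
}

# ---- loss -----------------------------------------------------------------

slice_row <- function(t2, i) {
  # (K, P) tensor -> (1, P) row i, via transpose + column gather
  P <- dim(t2$v)[2]
  agReshape(agGatherCols(agPermute(t2, c(2, 1)), i), c(1L, P))
}

#' Composite detection loss
#'
#' Box term: 1 - IoU between decoded and ground-truth boxes on positives;
#' class and objectness terms: binary cross-entropy with the configured
#' positive-sample weights. Totals use the published gains
#' 0.05 / 0.5 / 1.0. With no positives the box and class terms are exactly
#' zero.
#'
#' @param preds per-level list(box, obj, cls) of autodiff tensors from
#'   `model$forward`.
#' @param assignments list (one per batch image) of [assignTargets()]
#'   tables.
#' @param gts_list list of ground-truth box tables, aligned.
#' @param classes class list.
#' @param strides head strides.
#' @param gains named gains (box, cls, obj).
#' @param pos_weights BCE positive-sample weights (cls, obj).
#' @param class_weights optional named per-class loss weights (mean 1).
#' @return a `LossBreakdown` list: box_loss, cls_loss, obj_loss, total
#'   (numerics), n_pos and `total_tensor` for backprop.
#' @export
computeLoss <- function(preds, assignments, gts_list, classes,
                        strides = c(8L, 16L, 32L),
                        gains = defaultLossGains(),
                        pos_weights = c(cls = 1, obj = 1),
                        class_weights = NULL) {
  N <- dim(preds[[1]]$obj$v)[4]
  stopifnot(length(assignments) == N, length(gts_list) == N)
  nc <- dim(preds[[1]]$cls$v)[1]
  if (nc != length(classes)) stop("prediction/class-list shape mismatch")
  box_terms <- list()
  cls_terms <- list()
  obj_loss <- NULL
  n_pos_total <- 0L
  for (l in seq_along(preds)) {
    pb <- preds[[l]]$box
    po <- preds[[l]]$obj
    pc <- preds[[l]]$cls
    dl <- dim(po$v)
    Hl <- dl[2]; Wl <- dl[3]
    s <- strides[l]
    obj_target <- array(0, dim(po$v))
    idx <- integer(); gt_rows <- integer(); img_of <- integer()
    for (n in seq_len(N)) {
      a <- assignments[[n]]
      a <- a[a$level == l, , drop = FALSE]
      if (nrow(a) == 0) next
      obj_target[cbind(1L, a$iy, a$ix, n)] <- 1
      idx <- c(idx, a$iy + Hl * (a$ix - 1L) + Hl * Wl * (n - 1L))
      gt_rows <- c(gt_rows, a$gt)
      img_of <- c(img_of, rep(n, nrow(a)))
    }
    P <- length(idx)
    if (P == 0) {
      obj_l <- agBceLogits(po, obj_target, pos_weight = pos_weights[["obj"]])
      obj_loss <- if (is.null(obj_loss)) obj_l else agAdd(obj_loss, obj_l)
      next
    }
    n_pos_total <- n_pos_total + P
    gtb <- do.call(rbind, lapply(seq_len(P), function(i) {
      gts_list[[img_of[i]]][gt_rows[i], c("xmin", "ymin", "xmax", "ymax", "label")]
    }))
    cx <- ((idx - 1L) %% (Hl * Wl)) # position within image
    iy <- cx %% Hl + 1L
    ix <- cx %/% Hl + 1L
    ccx <- (ix - 0.5) * s
    ccy <- (iy - 0.5) * s
    # clamp encodable distances: forced matches may sit outside the box
    eps <- 1e-3
    d_l <- pmax(ccx - gtb$xmin, eps); d_t <- pmax(ccy - gtb$ymin, eps)
    d_r <- pmax(gtb$xmax - ccx, eps); d_b <- pmax(gtb$ymax - ccy, eps)
    tb <- agGatherCols(pb, idx) # (4, P)
    dd <- agMul(agExp(tb), array(s, c(1L, P)))
    row1 <- slice_row(dd, 1L); row2 <- slice_row(dd, 2L)
    row3 <- slice_row(dd, 3L); row4 <- slice_row(dd, 4L)
    cxa <- array(ccx, c(1L, P)); cya <- array(ccy, c(1L, P))
    px1 <- agSub(agConst(cxa), row1); py1 <- agSub(agConst(cya), row2)
    px2 <- agAdd(agConst(cxa), row3); py2 <- agAdd(agConst(cya), row4)
    gx1 <- array(ccx - d_l, c(1L, P)); gy1 <- array(ccy - d_t, c(1L, P))
    gx2 <- array(ccx + d_r, c(1L, P)); gy2 <- array(ccy + d_b, c(1L, P))
    iw <- agRelu(agSub(agPmin(px2, agConst(gx2)), agPmax(px1, agConst(gx1))))
    ih <- agRelu(agSub(agPmin(py2, agConst(gy2)), agPmax(py1, agConst(gy1))))
    inter <- agMul(iw, ih)
    area_p <- agMul(agSub(px2, px1), agSub(py2, py1))
    area_g <- (gx2 - gx1) * (gy2 - gy1)
    un <- agSub(agAdd(area_p, agConst(area_g)), inter)
    iou <- agDiv(inter, agAddScalar(un, 1e-9))
    box_terms[[length(box_terms) + 1L]] <-
      agSum(agSub(agConst(array(1, c(1L, P))), iou))
    # objectness target at positives = detached IoU of the decoded box
    # (confidence learns to rank localization quality, YOLO-family style)
    om <- obj_target
    dim(om) <- c(1L, Hl * Wl * N)
    om[1L, idx] <- pmax(as.numeric(iou$v), 0.05)
    dim(om) <- dim(po$v)
    obj_l <- agBceLogits(po, om, pos_weight = pos_weights[["obj"]])
    obj_loss <- if (is.null(obj_loss)) obj_l else agAdd(obj_loss, obj_l)
    # classification on positives
    tcls <- agGatherCols(pc, idx) # (nc, P)
    onehot <- matrix(0, nc, P)
    wmat <- matrix(1, nc, P)
    for (i in seq_len(P)) {
      ci <- match(gtb$label[i], classes)
      if (is.na(ci)) stop("ground-truth label outside class list: ", gtb$label[i])
      onehot[ci, i] <- 1
      if (!is.null(class_weights)) wmat[, i] <- class_weights[[gtb$label[i]]]
    }
    cls_terms[[length(cls_terms) + 1L]] <- list(
      t = agBceLogits(tcls, onehot, weight = wmat,
                      pos_weight = pos_weights[["cls"]]),
      P = P
    )
  }
  obj_loss <- agScale(obj_loss, 1 / length(preds))
  if (n_pos_total > 0) {
    box_loss <- NULL
    for (bt in box_terms) box_loss <- if (is.null(box_loss)) bt else agAdd(box_loss, bt)
    box_loss <- agScale(box_loss, 1 / n_pos_total)
    cls_loss <- NULL
    for (ct in cls_terms) {
      term <- agScale(ct$t, ct$P / n_pos_total)
      cls_loss <- if (is.null(cls_loss)) term else agAdd(cls_loss, term)
    }
  } else {
    box_loss <- agConst(array(0, 1L))
    cls_loss <- agConst(array(0, 1L))
  }
  total <- agAdd(agAdd(agScale(box_loss, gains[["box"]]),
                       agScale(cls_loss, gains[["cls"]])),
                 agScale(obj_loss, gains[["obj"]]))
  structure(list(
    box_loss = as.numeric(box_loss$v), cls_loss = as.numeric(cls_loss$v),
    obj_loss = as.numeric(obj_loss$v), total = as.numeric(total$v),
    n_pos = n_pos_total, total_tensor = total
  ), class = "LossBreakdown")
}

#' @export
print.LossBreakdown <- function(x, ...) {
  cat(sprintf("loss: total %.4f (box %.4f, cls %.4f, obj %.4f; %d positives)\n",
              x$total, x$box_loss, x$cls_loss, x$obj_loss, x$n_pos))
  invisible(x)
}

# ---- decoding and NMS -----------------------------------------------------

greedy_nms <- function(det, nms_iou, merge_boxes = FALSE) {
  if (nrow(det) <= 1) return(det)
  det <- det[order(-det$confidence), , drop = FALSE]
  keep <- logical(nrow(det))
  alive <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(det)) {
      rest <- which(alive & seq_len(nrow(det)) > i)
      if (length(rest)) {
        ious <- boxIou(det[i, , drop = FALSE], det[rest, , drop = FALSE])
        sup <- rest[ious[1, ] > nms_iou]
        alive[sup] <- FALSE
        if (merge_boxes && length(sup)) {
          # box voting: confidence-weighted average of the cluster
          grp <- c(i, sup)
          w <- det$confidence[grp]
          for (cc in c("xmin", "ymin", "xmax", "ymax")) {
            det[[cc]][i] <- sum(det[[cc]][grp] * w) / sum(w)
          }
        }
      }
    }
  }
  det[keep, , drop = FALSE]
}

#' Decode head outputs and apply per-class greedy NMS
#'
#' @param preds per-level list(box, obj, cls) of arrays or autodiff tensors
#'   for a single image (trailing batch dim 1 allowed).
#' @param classes class list.
#' @param image_size (height, width).
#' @param conf_threshold minimum confidence (sigmoid(obj) * sigmoid(cls)).
#' @param nms_iou per-class NMS IoU threshold.
#' @param strides head strides.
#' @param max_det cap on returned detections.
#' @param merge_boxes box voting: each surviving box becomes the
#'   confidence-weighted average of the candidates it suppressed (reduces
#'   grid jitter of centre-based decoding); the survivor set is identical
#'   to plain greedy NMS.
#' @return a [DetectionSet-class] sorted by confidence descending.
#' @export
decodeAndNms <- function(preds, classes, image_size, conf_threshold = 0.25,
                         nms_iou = 0.45, strides = c(8L, 16L, 32L),
                         max_det = 300L, merge_boxes = TRUE) {
  stopifnot(conf_threshold > 0, conf_threshold < 1, nms_iou > 0, nms_iou < 1)
  H <- image_size[1]; W <- image_size[2]
  nc <- length(classes)
  rows <- list()
  for (l in seq_along(preds)) {
    pb <- preds[[l]]$box; po <- preds[[l]]$obj; pc <- preds[[l]]$cls
    if (inherits(pb, "ag_tensor")) pb <- pb$v
    if (inherits(po, "ag_tensor")) po <- po$v
    if (inherits(pc, "ag_tensor")) pc <- pc$v
    d <- dim(po)
    Hl <- d[2]; Wl <- d[3]
    M <- Hl * Wl
    dim(pb) <- c(4L, M); dim(po) <- c(1L, M); dim(pc) <- c(nc, M)
    s <- strides[l]
    obj <- stats::plogis(po[1, ])
    cls <- stats::plogis(pc)
    conf <- cls * rep(obj, each = nc)
    hits <- which(conf >= conf_threshold, arr.ind = TRUE)
    if (length(hits) == 0) next
    m <- hits[, 2]
    iy <- (m - 1L) %% Hl + 1L
    ix <- (m - 1L) %/% Hl + 1L
    ccx <- (ix - 0.5) * s
    ccy <- (iy - 0.5) * s
    dd <- exp(pb[, m, drop = FALSE]) * s
    rows[[length(rows) + 1L]] <- data.frame(
      label = classes[hits[, 1]],
      xmin = pmax(ccx - dd[1, ], 0), ymin = pmax(ccy - dd[2, ], 0),
      xmax = pmin(ccx + dd[3, ], W), ymax = pmin(ccy + dd[4, ], H),
      confidence = conf[hits],
      stringsAsFactors = FALSE
    )
  }
  det <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), xmin = numeric(), ymin = numeric(),
               xmax = numeric(), ymax = numeric(), confidence = numeric())
  det <- det[det$xmax > det$xmin & det$ymax > det$ymin, , drop = FALSE]
  if (nrow(det) > 0) {
    kept <- lapply(split(det, det$label), greedy_nms, nms_iou = nms_iou,
                   merge_boxes = merge_boxes)
    det <- do.call(rbind, kept)
    det <- det[order(-det$confidence), , drop = FALSE]
    if (nrow(det) > max_det) det <- det[seq_len(max_det), , drop = FALSE]
    rownames(det) <- NULL
    det$occlusion <- 0
    det$visible_frac <- 1
    det$difficult <- FALSE
  }
  detectionSet(det, image_size)
}

#' Run the detector on a single image
#'
#' @param model a [buildModel()] model.
#' @param image H x W x 3 raster in [0, 1] (or 3 x H x W).
#' @param classes class list.
#' @param conf_threshold,nms_iou decoding thresholds.
#' @param tta horizontal-flip test-time augmentation: detections from the
#'   mirrored view are mapped back and fused with the direct view by
#'   box-voting NMS.
#' @return a [DetectionSet-class].
#' @export
detectImage <- function(model, image, classes, conf_threshold = 0.25,
                        nms_iou = 0.45, tta = FALSE) {
  x <- as_3hw(image)
  sz <- dim(x)[2:3]
  preds <- agNoGrad(model$forward(x, train = FALSE))
  ds <- decodeAndNms(preds, classes, sz, conf_threshold, nms_iou,
                     strides = model$strides)
  if (!tta) return(ds)
  xf <- x[, , dim(x)[3]:1, drop = FALSE]
  predsf <- agNoGrad(model$forward(xf, train = FALSE))
  dsf <- decodeAndNms(predsf, classes, sz, conf_threshold, nms_iou,
                      strides = model$strides)
  df <- dsf@detections
  if (nrow(df) > 0) {
    x0 <- df$xmin
    df$xmin <- sz[2] - df$xmax
    df$xmax <- sz[2] - x0
  }
  both <- rbind(ds@detections, df)
  if (nrow(both) > 1) {
    both <- do.call(rbind, lapply(split(both, both$label), greedy_nms,
                                  nms_iou = nms_iou, merge_boxes = TRUE))
    both <- both[order(-both$confidence), , drop = FALSE]
    rownames(both) <- NULL
  }
  detectionSet(both, sz)
}

# ---- checkpoints ----------------------------------------------------------

#' Save model weights, batch-norm state and architecture config
#' @param model a [buildModel()] model.
#' @param path output file (RDS).
#' @export
saveWeights <- function(model, path) {
  saveRDS(list(
    cfg = model$cfg,
    values = get_param_values(model),
    states = lapply(model$states, function(s) {
      list(running_mean = s$running_mean, running_var = s$running_var)
    })
  ), path)
  invisible(path)
}

#' Load a checkpoint into a freshly built model
#' @param path checkpoint file from [saveWeights()].
#' @return a [buildModel()] model with restored parameters and statistics.
#' @export
loadWeights <- function(path) {
  ck <- readRDS(path)
  model <- do.call(buildModel, ck$cfg[c("num_classes", "width_multiple",
                                        "use_dat", "use_csaam", "window_size",
                                        "mlp_ratio", "offset_range_factor",
                                        "seed")])
  set_param_values(model, ck$values)
  for (nm in names(ck$states)) {
    model$states[[nm]]$running_mean <- ck$states[[nm]]$running_mean
    model$states[[nm]]$running_var <- ck$states[[nm]]$running_var
  }
  model
}
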