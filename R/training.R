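# Hierarchical progressive transfer learning: two stages with tiered
# per-partition learning rates, warm-up plus stepped decay, balanced
# sampling and class-weighted loss, optimized with Adam.
#
# Stage "init" (domain initialization): backbone and neck are transferred
# from a source model, the head is freshly initialized, and rates are
# (backbone 3e-4, neck 1e-3, head 1e-3). Stage "diversity" (diversity
# adaptation) carries all weights over and uses the three-tier rates
# (1e-4, 5e-4, 1e-3).

#' Stage configuration for the two-stage transfer trainer
#'
#' Defaults reproduce the published recipe: tiered learning rates per
#' stage, learning rate multiplied by 0.8 every 30 epochs (the alternative
#' stepped coefficient 0.2 is available via `decay_factor`), 3 warm-up
#' epochs ramping from 0.1 x base rate and momentum 0.8 to 0.937, weight
#' decay 5e-4, batch size 32.
#'
#' @param stage "init" or "diversity".
#' @param lr_backbone,lr_neck,lr_head per-partition learning rates;
#'   defaults depend on the stage.
#' @param epochs training epochs.
#' @param dataset_scope optional class subset defining the stage's data
#'   (stage-1 convention: a single-vegetable subset).
#' @param decay_factor multiplicative LR decay.
#' @param decay_every epochs between decays.
#' @param warmup_epochs linear warm-up length.
#' @param warmup_lr_factor starting LR as a fraction of base.
#' @param warmup_momentum starting momentum.
#' @param momentum optimizer momentum (Adam beta1).
#' @param weight_decay L2 coefficient.
#' @param batch_size minibatch size.
#' @param seed integer seed.
#' @return a `StageConfig` list.
#' @export
stageConfig <- function(stage = c("init", "diversity"),
                        lr_backbone = NULL, lr_neck = NULL, lr_head = NULL,
                        epochs = 200L, dataset_scope = NULL,
                        decay_factor = 0.8, decay_every = 30L,
                        warmup_epochs = 3L, warmup_lr_factor = 0.1,
                        warmup_momentum = 0.8, momentum = 0.937,
                        weight_decay = 5e-4, batch_size = 32L, seed = 1L) {
  stage <- match.arg(stage)
  if (is.null(lr_backbone)) lr_backbone <- if (stage == "init") 3e-4 else 1e-4
  if (is.null(lr_neck)) lr_neck <- if (stage == "init") 1e-3 else 5e-4
  if (is.null(lr_head)) lr_head <- 1e-3
  stopifnot(lr_backbone > 0, lr_neck > 0, lr_head > 0)
  structure(list(
    stage = stage, lr_backbone = lr_backbone, lr_neck = lr_neck,
    lr_head = lr_head, epochs = as.integer(epochs),
    dataset_scope = dataset_scope, decay_factor = decay_factor,
    decay_every = as.integer(decay_every),
    warmup_epochs = as.integer(warmup_epochs),
    warmup_lr_factor = warmup_lr_factor, warmup_momentum = warmup_momentum,
    momentum = momentum, weight_decay = weight_decay,
    batch_size = as.integer(batch_size), seed = as.integer(seed)
  ), class = "StageConfig")
}

partition_of <- function(name) sub("\\..*$", "", name)

#' Partition model parameters into backbone / neck / head groups
#'
#' Every trainable array belongs to exactly one group; an array whose name
#' prefix is none of the three partitions is an error (no silent default
#' group).
#'
#' @param model a [buildModel()] model.
#' @param cfg a [stageConfig()].
#' @return named list of three groups, each list(params, lr).
#' @export
makeParamGroups <- function(model, cfg) {
  parts <- vapply(names(model$params), partition_of, "")
  bad <- setdiff(unique(parts), c("backbone", "neck", "head"))
  if (length(bad) > 0) {
    stop("parameters outside the backbone/neck/head partitions: ",
         paste(names(model$params)[parts %in% bad], collapse = ", "))
  }
  lrs <- c(backbone = cfg$lr_backbone, neck = cfg$lr_neck, head = cfg$lr_head)
  out <- lapply(c("backbone", "neck", "head"), function(p) {
    list(params = model$params[parts == p], lr = lrs[[p]])
  })
  names(out) <- c("backbone", "neck", "head")
  out
}

#' Transfer weights between models per the two-stage protocol
#'
#' Stage "init" copies backbone and neck from the source and leaves the
#' target's freshly initialized head untouched (the random-head rule);
#' stage "diversity" copies all partitions. Batch-norm statistics follow
#' their partition. Shape mismatches abort listing the offending arrays.
#'
#' @param source,target models from [buildModel()].
#' @param stage "init" or "diversity".
#' @return the target model, modified in place.
#' @export
transferWeights <- function(source, target, stage = c("init", "diversity")) {
  stage <- match.arg(stage)
  parts_copy <- if (stage == "init") c("backbone", "neck") else
    c("backbone", "neck", "head")
  nms <- names(source$params)
  nms <- nms[vapply(nms, partition_of, "") %in% parts_copy]
  missing <- setdiff(nms, names(target$params))
  if (length(missing)) {
    stop("target lacks source arrays: ", paste(missing, collapse = ", "))
  }
  bad <- nms[!vapply(nms, function(nm) {
    length(source$params[[nm]]$v) == length(target$params[[nm]]$v)
  }, TRUE)]
  if (length(bad)) {
    stop("shape mismatch in transferred arrays: ", paste(bad, collapse = ", "))
  }
  for (nm in nms) target$params[[nm]]$v <- source$params[[nm]]$v
  for (nm in names(source$states)) {
    if (partition_of(nm) %in% parts_copy && nm %in% names(target$states)) {
      target$states[[nm]]$running_mean <- source$states[[nm]]$running_mean
      target$states[[nm]]$running_var <- source$states[[nm]]$running_var
    }
  }
  target
}

#' Learning rates and momentum at a given epoch
#'
#' During warm-up (first `warmup_epochs` epochs) rates ramp linearly from
#' `warmup_lr_factor` x base to base and momentum from `warmup_momentum` to
#' `momentum`; afterwards rate = base x decay_factor^floor(epoch /
#' decay_every).
#'
#' @param cfg a [stageConfig()].
#' @param epoch 0-based epoch index.
#' @return list(rates = named numeric (backbone, neck, head),
#'   momentum = numeric).
#' @export
lrAtEpoch <- function(cfg, epoch) {
  stopifnot(epoch >= 0)
  base <- c(backbone = cfg$lr_backbone, neck = cfg$lr_neck, head = cfg$lr_head)
  if (cfg$warmup_epochs > 0 && epoch < cfg$warmup_epochs) {
    a <- epoch / cfg$warmup_epochs
    f <- cfg$warmup_lr_factor + (1 - cfg$warmup_lr_factor) * a
    mom <- cfg$warmup_momentum + (cfg$momentum - cfg$warmup_momentum) * a
  } else {
    f <- cfg$decay_factor^(epoch %/% cfg$decay_every)
    mom <- cfg$momentum
  }
  list(rates = base * f, momentum = mom)
}

#' Inverse-frequency balanced sampling weights per image
#'
#' @param manifest manifest with a `class` column (or a named count
#'   vector).
#' @return per-image weights proportional to 1/count(class), normalized to
#'   sum 1 (expected per-class draw frequency is uniform).
#' @export
balancedSampleWeights <- function(manifest) {
  if (is.null(dim(manifest)) && !is.null(names(manifest))) {
    counts <- manifest
    cls <- rep(names(counts), counts)
  } else {
    cls <- manifest$class
    counts <- table(cls)
  }
  if (any(counts == 0)) stop("zero-count class in distribution")
  w <- 1 / as.numeric(counts[cls])
  w / sum(w)
}

#' Inverse-frequency class loss weights (mean 1)
#'
#' @param dist named per-class counts.
#' @return named weights proportional to 1/count, normalized to mean 1.
#' @export
classLossWeights <- function(dist) {
  if (any(dist == 0)) stop("zero-count class in distribution")
  w <- 1 / as.numeric(dist)
  w <- w / mean(w)
  names(w) <- names(dist)
  w
}

snapshot_model <- function(model) {
  list(
    values = get_param_values(model),
    states = lapply(model$states, function(st) {
      list(running_mean = st$running_mean, running_var = st$running_var)
    })
  )
}

restore_snapshot <- function(model, snap) {
  set_param_values(model, snap$values)
  for (nm in names(snap$states)) {
    model$states[[nm]]$running_mean <- snap$states[[nm]]$running_mean
    model$states[[nm]]$running_var <- snap$states[[nm]]$running_var
  }
  invisible(model)
}

# ---- optimizer ------------------------------------------------------------

adam_new <- function(groups, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- list()
  st$v <- list()
  st$t <- 0L
  st$beta2 <- beta2
  st$eps <- eps
  for (g in groups) {
    for (nm in names(g$params)) {
      p <- g$params[[nm]]
      st$m[[nm]] <- zeros_like(p$v)
      st$v[[nm]] <- zeros_like(p$v)
    }
  }
  st
}

adam_step <- function(st, groups, rates, beta1, weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    lr <- rates[[gi]]
    for (nm in names(g$params)) {
      p <- g$params[[nm]]
      if (is.null(p$g)) next
      grad <- p$g
      st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grad
      st$v[[nm]] <- st$beta2 * st$v[[nm]] + (1 - st$beta2) * grad^2
      p$v <- p$v - lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + st$eps)
      # decoupled decay, weight matrices only (never biases or norm gains)
      if (weight_decay > 0 && length(dim(p$v)) >= 2L) {
        p$v <- p$v * (1 - lr * weight_decay)
      }
    }
  }
  invisible(st)
}

# ---- data loading for training --------------------------------------------

load_training_image <- function(row, input_size) {
  li <- readVoc(row$xml, load_image = TRUE)
  if (is.null(li@image)) stop("missing raster for ", row$path)
  resize_labeled(li, input_size)
}

# nearest-neighbour resize of image + boxes to a square side
resize_labeled <- function(li, side) {
  H <- li@size[1]; W <- li@size[2]
  if (H == side && W == side) return(li)
  ri <- pmin(pmax(floor((seq_len(side) - 0.5) * H / side) + 1L, 1L), H)
  ci <- pmin(pmax(floor((seq_len(side) - 0.5) * W / side) + 1L, 1L), W)
  img <- li@image[ri, ci, , drop = FALSE]
  b <- li@boxes
  if (nrow(b) > 0) {
    b$xmin <- b$xmin * side / W; b$xmax <- b$xmax * side / W
    b$ymin <- b$ymin * side / H; b$ymax <- b$ymax * side / H
  }
  labeledImage(img, b)
}

#' Evaluate a model over a manifest (mAP at one threshold)
#'
#' @param model a [buildModel()] model.
#' @param manifest evaluation manifest.
#' @param classes class list.
#' @param input_size square input side.
#' @param iou_threshold matching threshold.
#' @param conf_threshold operating confidence threshold for P/R/F1.
#' @param decode_conf decoding confidence floor (kept low so the AP sweep
#'   sees the full confidence range).
#' @param nms_iou NMS threshold used when decoding.
#' @param tta flip test-time augmentation (see [detectImage()]).
#' @return the [EvalResult-class] for the threshold.
#' @export
evaluateModel <- function(model, manifest, classes, input_size = 96L,
                          iou_threshold = 0.5, conf_threshold = 0.25,
                          decode_conf = 0.01, nms_iou = 0.45, tta = FALSE) {
  dets <- list()
  gts <- list()
  for (i in seq_len(nrow(manifest))) {
    li <- load_training_image(manifest[i, ], input_size)
    ds <- detectImage(model, li@image, classes,
                      conf_threshold = decode_conf, nms_iou = nms_iou,
                      tta = tta)
    dets[[i]] <- ds@detections
    gts[[i]] <- li@boxes
  }
  evaluateDetections(dets, gts, iou_thresholds = iou_threshold,
                     conf_threshold = conf_threshold, classes = classes)[[1]]
}

#' Run one transfer-learning stage
#'
#' Optimizes the composite loss with the configured parameter groups,
#' schedule and balanced sampler; logs loss components and validation mAP
#' per epoch and retains the best-mAP parameter snapshot. Aborts on a
#' non-finite loss. Fully seeded: two runs with the same config produce
#' identical trajectories.
#'
#' @param model a [buildModel()] model (modified in place).
#' @param cfg a [stageConfig()].
#' @param train_manifest,val_manifest non-empty manifests.
#' @param classes class list.
#' @param input_size square training resolution.
#' @param use_mosaic compose each training sample from four drawn images
#'   via [mosaicCompose()] (input pipeline only; the model is untouched).
#' @param augment_transforms optional transform pool applied online: each
#'   drawn sample receives one random transform from this list with
#'   probability 1/2 (see [randomAugment()]); NULL disables.
#' @param balanced use inverse-frequency balanced sampling.
#' @param class_weighted apply inverse-frequency class loss weights.
#' @param eval_every evaluate on the validation set every this many epochs.
#' @param eval_nms_iou NMS threshold of the validation decoding protocol.
#' @param steps_per_epoch optional cap on steps per epoch.
#' @param restore_best load the best-validation-mAP snapshot back into the
#'   model after the last epoch (the retained checkpoint).
#' @param verbose print a line per epoch.
#' @return list(model, log = per-epoch data.frame, best = best snapshot,
#'   best_map).
#' @export
runStage <- function(model, cfg, train_manifest, val_manifest, classes,
                     input_size = 96L, use_mosaic = FALSE,
                     augment_transforms = c("hflip", "vflip"),
                     balanced = TRUE, class_weighted = TRUE, eval_every = 1L,
                     eval_nms_iou = 0.45, steps_per_epoch = NULL,
                     restore_best = TRUE, verbose = FALSE) {
  stopifnot(nrow(train_manifest) > 0, nrow(val_manifest) > 0)
  groups <- makeParamGroups(model, cfg)
  if (!is.null(cfg$dataset_scope)) {
    train_manifest <- train_manifest[train_manifest$class %in% cfg$dataset_scope, ,
                                     drop = FALSE]
    stopifnot(nrow(train_manifest) > 0)
  }
  withr::with_seed(cfg$seed, {
    imgs <- lapply(seq_len(nrow(train_manifest)), function(i) {
      load_training_image(train_manifest[i, ], input_size)
    })
    wts <- if (balanced) balancedSampleWeights(train_manifest) else
      rep(1 / nrow(train_manifest), nrow(train_manifest))
    cw <- if (class_weighted) {
      tab <- table(train_manifest$class)
      classLossWeights(stats::setNames(as.numeric(tab), names(tab)))
    } else NULL
    opt <- adam_new(groups)
    n <- length(imgs)
    bs <- min(cfg$batch_size, n)
    steps <- max(1L, n %/% bs)
    if (!is.null(steps_per_epoch)) steps <- min(steps, steps_per_epoch)
    log <- list()
    best <- NULL
    best_map <- -Inf
    for (epoch in seq_len(cfg$epochs) - 1L) {
      sched <- lrAtEpoch(cfg, epoch)
      ep_losses <- c(box = 0, cls = 0, obj = 0, total = 0)
      for (step in seq_len(steps)) {
        sel <- sample.int(n, bs, replace = TRUE, prob = wts)
        batch <- lapply(sel, function(i) {
          li <- if (use_mosaic) {
            others <- sample.int(n, 3L, replace = TRUE, prob = wts)
            mosaicCompose(c(imgs[i], imgs[others]), out_size = input_size,
                          seed = sample.int(1e6, 1))
          } else imgs[[i]]
          if (!is.null(augment_transforms) && stats::runif(1) < 0.5) {
            li <- randomAugment(li, seed = sample.int(1e6, 1),
                                transforms = augment_transforms)
            li <- resize_labeled(li, input_size) # border_expand may grow it
          }
          li
        })
        x <- array(0, c(3L, input_size, input_size, bs))
        for (bi in seq_len(bs)) {
          x[, , , bi] <- aperm(batch[[bi]]@image, c(3, 1, 2))
        }
        assigns <- lapply(batch, function(b) {
          assignTargets(b@boxes, c(input_size, input_size),
                        strides = model$strides)
        })
        gts <- lapply(batch, function(b) b@boxes)
        preds <- model$forward(agConst(x), train = TRUE)
        loss <- computeLoss(preds, assigns, gts, classes,
                            strides = model$strides, class_weights = cw)
        if (!is.finite(loss$total)) {
          stop(sprintf("divergence: non-finite loss at epoch %d step %d",
                       epoch, step))
        }
        agZeroGrad(unlist(lapply(groups, `[[`, "params"), use.names = FALSE))
        agBackward(loss$total_tensor)
        adam_step(opt, groups, sched$rates, beta1 = sched$momentum,
                  weight_decay = cfg$weight_decay)
        ep_losses <- ep_losses + c(loss$box_loss, loss$cls_loss,
                                   loss$obj_loss, loss$total)
      }
      ep_losses <- ep_losses / steps
      val_map <- NA_real_
      if (epoch %% eval_every == 0L || epoch == cfg$epochs - 1L) {
        ev <- evaluateModel(model, val_manifest, classes, input_size,
                            nms_iou = eval_nms_iou)
        val_map <- ev@mAP
        if (!is.na(val_map) && val_map >= best_map) {
          best_map <- val_map
          best <- snapshot_model(model)
        }
      }
      log[[epoch + 1L]] <- data.frame(
        epoch = epoch, box = ep_losses[1], cls = ep_losses[2],
        obj = ep_losses[3], total = ep_losses[4],
        lr_head = sched$rates[["head"]], val_map = val_map
      )
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f (box %.4f cls %.4f obj %.4f) val mAP %s",
                        epoch, ep_losses[4], ep_losses[1], ep_losses[2],
                        ep_losses[3],
                        if (is.na(val_map)) "-" else sprintf("%.3f", val_map)))
      }
    }
    log <- do.call(rbind, log)
    rownames(log) <- NULL
    if (restore_best && !is.null(best)) restore_snapshot(model, best)
    list(model = model, log = log, best = best, best_map = best_map)
  })
}
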