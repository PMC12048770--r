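test_that("parameter groups carry the published tiered rates per stage", {
  m <- tiny_model()
  g_init <- makeParamGroups(m, stageConfig("init"))
  expect_equal(vapply(g_init, `[[`, 1, "lr"),
               c(backbone = 3e-4, neck = 1e-3, head = 1e-3))
  g_div <- makeParamGroups(m, stageConfig("diversity"))
  expect_equal(vapply(g_div, `[[`, 1, "lr"),
               c(backbone = 1e-4, neck = 5e-4, head = 1e-3))
  # exhaustive, disjoint partition
  nms <- unlist(lapply(g_init, function(g) names(g$params)))
  expect_setequal(nms, names(m$params))
  expect_equal(anyDuplicated(nms), 0)
  # arrays outside the three partitions are rejected
  bad <- list(params = stats::setNames(list(vegdet:::agParam(1, "adapter.w")),
                              "adapter.w"))
  expect_error(makeParamGroups(bad, stageConfig("init")), "adapter")
})

test_that("stage transfer copies the right partitions and re-seeds the head", {
  src <- buildModel(2, width_multiple = 0.25, seed = 11)
  tgt <- buildModel(2, width_multiple = 0.25, seed = 99)
  transferWeights(src, tgt, "init")
  bk <- grep("^backbone", names(src$params), value = TRUE)
  hd <- grep("^head", names(src$params), value = TRUE)
  for (nm in bk) expect_identical(tgt$params[[nm]]$v, src$params[[nm]]$v)
  head_equal <- vapply(hd, function(nm) {
    identical(tgt$params[[nm]]$v, src$params[[nm]]$v)
  }, TRUE)
  expect_false(all(head_equal)) # head keeps its own random init

  # diversity stage: all arrays bitwise equal
  tgt2 <- buildModel(2, width_multiple = 0.25, seed = 98)
  transferWeights(src, tgt2, "diversity")
  for (nm in names(src$params)) {
    expect_identical(tgt2$params[[nm]]$v, src$params[[nm]]$v)
  }
  # pre-update forward outputs bit-match the source
  withr::with_seed(12, x <- array(runif(3 * 64 * 64), c(3, 64, 64)))
  ps <- vegdet:::agNoGrad(src$forward(x))
  pt <- vegdet:::agNoGrad(tgt2$forward(x))
  for (l in 1:3) {
    expect_identical(ps[[l]]$box$v, pt[[l]]$box$v)
    expect_identical(ps[[l]]$cls$v, pt[[l]]$cls$v)
  }
  # after an init transfer, backbone activations still match the source
  expect_error(transferWeights(src, buildModel(2, width_multiple = 0.5, seed = 1),
                               "init"), "mismatch|lacks")
})

test_that("the learning-rate schedule warms up then steps down by 0.8 every 30", {
  cfg <- stageConfig("init", lr_backbone = 1e-3, lr_neck = 1e-3, lr_head = 1e-3)
  # warm-up start: 0.1 x base, momentum 0.8
  e0 <- lrAtEpoch(cfg, 0)
  expect_equal(unname(e0$rates["head"]), 1e-4)
  expect_equal(e0$momentum, 0.8)
  # after warm-up: full rate, momentum 0.937
  e3 <- lrAtEpoch(cfg, 3)
  expect_equal(unname(e3$rates["head"]), 1e-3)
  expect_equal(e3$momentum, 0.937)
  # epoch 65: two decays, 0.001 x 0.8^2 = 0.00064
  expect_equal(unname(lrAtEpoch(cfg, 65)$rates["head"]), 0.00064)
  # monotone non-increasing after warm-up
  rates <- vapply(3:120, function(e) unname(lrAtEpoch(cfg, e)$rates["head"]), 1)
  expect_true(all(diff(rates) <= 1e-15))
  # the stepped coefficient of the alternative schedule is honoured
  cfg2 <- stageConfig("init", lr_head = 1e-3, decay_factor = 0.2)
  expect_equal(unname(lrAtEpoch(cfg2, 35)$rates["head"]), 2e-4)
})

test_that("balanced sampling weights invert class frequencies", {
  manifest <- data.frame(class = c(rep("A", 10), rep("B", 30)))
  w <- balancedSampleWeights(manifest)
  expect_equal(sum(w), 1)
  expect_equal(w[1] / w[11], 3) # each A image 3x the weight of a B image
  # expected class draw frequency is uniform
  expect_equal(sum(w[manifest$class == "A"]), 0.5)
  expect_equal(sum(w[manifest$class == "B"]), 0.5)
  # equal counts give uniform weights
  eq <- balancedSampleWeights(data.frame(class = rep(c("A", "B"), 5)))
  expect_true(all(abs(eq - 0.1) < 1e-12))
  expect_error(balancedSampleWeights(c(A = 0, B = 3)), "zero-count")

  cw <- classLossWeights(c(A = 10, B = 30))
  expect_equal(mean(cw), 1)
  expect_equal(unname(cw["A"] / cw["B"]), 3)
})

test_that("an overfit probe collapses the loss on eight images", {
  imgs <- fixture_overfit_set()
  model <- buildModel(2, width_multiple = 0.25, seed = 2)
  groups <- makeParamGroups(model, stageConfig(
    "init", lr_backbone = 1e-2, lr_neck = 1e-2, lr_head = 1e-2
  ))
  opt <- vegdet:::adam_new(groups)
  x <- array(0, c(3, 64, 64, 8))
  for (bi in 1:8) x[, , , bi] <- aperm(imgs[[bi]]@image, c(3, 1, 2))
  asg <- lapply(imgs, function(b) assignTargets(b@boxes, c(64, 64)))
  gts <- lapply(imgs, boxes)
  first <- NA
  for (step in 1:200) {
    preds <- model$forward(vegdet:::agConst(x), train = TRUE)
    loss <- computeLoss(preds, asg, gts, classes = c("a", "b"))
    if (step == 1) first <- loss$total
    vegdet:::agZeroGrad(model$params)
    vegdet:::agBackward(loss$total_tensor)
    vegdet:::adam_step(opt, groups, rep(1e-2, 3), beta1 = 0.9)
  }
  expect_lt(loss$total, 0.1 * first)
})

test_that("training runs are deterministic given the stage seed", {
  dir <- withr::local_tempdir()
  classes <- smoke_classes()[1:2]
  m <- generateDataset(stats::setNames(c(6L, 6L), classes), dir, seed = 31,
                       specDefaults = list(canvasSize = c(64L, 64L),
                                           lighting = "normal"))
  run_once <- function() {
    model <- buildModel(2, width_multiple = 0.25, seed = 5)
    cfg <- stageConfig("init", epochs = 2L, batch_size = 4L,
                       warmup_epochs = 1L, seed = 17L)
    runStage(model, cfg, m, m, classes, input_size = 64L,
             eval_every = 10L, verbose = FALSE)$log
  }
  l1 <- run_once()
  l2 <- run_once()
  expect_identical(l1$total, l2$total)
  expect_identical(l1$box, l2$box)
})

test_that("mosaic input composition leaves the model topology untouched", {
  dir <- withr::local_tempdir()
  classes <- smoke_classes()[1:2]
  m <- generateDataset(stats::setNames(c(4L, 4L), classes), dir, seed = 32,
                       specDefaults = list(canvasSize = c(64L, 64L)))
  model1 <- buildModel(2, width_multiple = 0.25, seed = 5)
  model2 <- buildModel(2, width_multiple = 0.25, seed = 5)
  cfg <- stageConfig("init", epochs = 1L, batch_size = 4L, seed = 3L)
  r1 <- runStage(model1, cfg, m, m, classes, input_size = 64L,
                 use_mosaic = FALSE, eval_every = 10L)
  r2 <- runStage(model2, cfg, m, m, classes, input_size = 64L,
                 use_mosaic = TRUE, eval_every = 10L)
  expect_identical(names(model1$params), names(model2$params))
  expect_identical(vapply(model1$params, function(p) dim(p$v)[1], 1),
                   vapply(model2$params, function(p) dim(p$v)[1], 1))
})

test_that("a non-finite loss aborts with a divergence diagnostic", {
  dir <- withr::local_tempdir()
  classes <- smoke_classes()[1]
  m <- generateDataset(stats::setNames(4L, classes), dir, seed = 33,
                       specDefaults = list(canvasSize = c(64L, 64L)))
  model <- buildModel(1, width_multiple = 0.25, seed = 5)
  # poison a weight so the forward pass produces NaN
  model$params[[1]]$v[1] <- NaN
  cfg <- stageConfig("init", epochs = 1L, batch_size = 2L, seed = 3L)
  expect_error(runStage(model, cfg, m, m, classes, input_size = 64L),
               "divergence|non-finite")
})

test_that("balanced sampling narrows the class recall gap under 10:1 imbalance", {
  classes <- smoke_classes()[1:2]
  gaps <- function(balanced, seed) {
    dir <- file.path(tempdir(), sprintf("bal_%d_%d", balanced, seed))
    unlink(dir, recursive = TRUE)
    sd <- list(canvasSize = c(64L, 64L), nLeaves = 1L,
               lesionsPerLeaf = c(1L, 1L), stage = "late",
               occlusionLevel = 0, lighting = "normal")
    tr <- generateDataset(stats::setNames(c(30L, 3L), classes), dir,
                          seed = seed, specDefaults = sd, classes = classes)
    va <- generateDataset(stats::setNames(c(8L, 8L), classes),
                          file.path(dir, "val"), seed = seed + 500L,
                          specDefaults = sd, classes = classes, split = "val")
    model <- buildModel(2, width_multiple = 0.25, seed = seed)
    cfg <- stageConfig("init", lr_backbone = 5e-3, lr_neck = 5e-3,
                       lr_head = 1e-2, epochs = 4L, warmup_epochs = 1L,
                       batch_size = 4L, seed = seed + 7L)
    res <- runStage(model, cfg, tr, va, classes, input_size = 64L,
                    balanced = balanced, class_weighted = balanced,
                    eval_every = 10L, restore_best = FALSE)
    ev <- evaluateModel(model, va, classes, input_size = 64L, nms_iou = 0.2)
    rec <- ev@perClass$recall
    abs(rec[1] - rec[2])
  }
  seeds <- c(41L, 42L, 43L)
  gap_bal <- mean(vapply(seeds, function(s) gaps(TRUE, s), 1))
  gap_unb <- mean(vapply(seeds, function(s) gaps(FALSE, s), 1))
  expect_lt(gap_bal, gap_unb)
})
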