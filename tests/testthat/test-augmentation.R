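test_that("offline augmentation planning follows the ceil-to-target rule", {
  # already balanced: nothing to do
  p0 <- planOfflineAugmentation(c(A = 100, B = 100), 100)
  expect_equal(unname(p0$copies_per_image), c(0, 0))
  expect_equal(unname(p0$delete_after), c(0, 0))

  # the study's extreme training counts: min 424, max 1344
  p1 <- planOfflineAugmentation(c(A = 424, B = 1344))
  expect_equal(p1$target_count, 1344)
  expect_equal(unname(p1$copies_per_image["A"]), 3) # 424 * 4 = 1696
  expect_equal(unname(p1$delete_after["A"]), 352)
  expect_equal(unname(p1$copies_per_image["B"]), 0)
  # exact-balance invariant
  n <- c(A = 424, B = 1344)
  expect_true(all(n * (1 + p1$copies_per_image) - p1$delete_after == 1344))

  # exact multiple: no deletions
  p2 <- planOfflineAugmentation(c(A = 50), 200)
  expect_equal(unname(p2$copies_per_image), 3)
  expect_equal(unname(p2$delete_after), 0)

  expect_error(planOfflineAugmentation(c(A = 100, B = 200), 150), "deleting")
})

test_that("flips map boxes through the same map as pixels and are involutions", {
  li <- fixture_stamped(10, 10, 20, 20, side = 100)
  h <- applyGeometric(li, "hflip")
  expect_equal(as.numeric(h@boxes[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(80, 10, 90, 20))
  hh <- applyGeometric(h, "hflip")
  expect_identical(hh@image, li@image)
  expect_equal(hh@boxes, li@boxes)
  vv <- applyGeometric(applyGeometric(li, "vflip"), "vflip")
  expect_identical(vv@image, li@image)
})

test_that("zero rotation is the identity and box transforms track pixel masks", {
  li <- fixture_stamped(24, 18, 44, 38, side = 64)
  r0 <- applyGeometric(li, "rotate", angle = 0)
  expect_identical(r0@image, li@image)
  expect_equal(r0@boxes$xmin, li@boxes$xmin, tolerance = 1e-10)

  # property: rendering the box as a mask, rotating it, and re-extracting
  # its extent matches the analytic box transform within 1 px
  for (ang in c(-20, 10, 33)) {
    mask <- array(0, c(64, 64, 3))
    mb <- li@boxes
    mask[(mb$ymin + 1):mb$ymax, (mb$xmin + 1):mb$xmax, ] <- 1
    mrot <- applyGeometric(labeledImage(mask, mb), "rotate", angle = ang)
    on <- which(mrot@image[, , 1] > 0.5, arr.ind = TRUE)
    analytic <- mrot@boxes
    expect_equal(min(on[, 2]) - 1, analytic$xmin, tolerance = 1.01)
    expect_equal(max(on[, 2]), analytic$xmax, tolerance = 1.01)
    expect_equal(min(on[, 1]) - 1, analytic$ymin, tolerance = 1.01)
    expect_equal(max(on[, 1]), analytic$ymax, tolerance = 1.01)
  }
})

test_that("border expansion shifts boxes and grows the canvas", {
  li <- fixture_stamped(10, 12, 30, 32, side = 64)
  e <- applyGeometric(li, "border_expand", pad = 8)
  expect_equal(e@size, c(80L, 80L))
  expect_equal(e@boxes$xmin, 18)
  expect_equal(e@boxes$ymax, 40)
  expect_identical(e@image[9:72, 9:72, ], li@image)
})

test_that("photometric transforms never move geometry", {
  li <- fixture_stamped(seed = 9)
  for (op in c("gamma", "contrast_stretch", "brightness", "gaussian_blur")) {
    out <- applyPhotometric(li, op, seed = 3)
    expect_identical(out@boxes, li@boxes)
    expect_true(all(out@image >= 0 & out@image <= 1))
  }
  expect_identical(applyPhotometric(li, "gamma", param = 1)@image, li@image)
  blur0 <- applyPhotometric(li, "gaussian_blur", param = 0.01)
  expect_equal(blur0@image, li@image, tolerance = 1e-8)
})

test_that("mosaic composes four sources with exact per-region pixel maps", {
  imgs <- lapply(1:4, function(i) {
    fixture_stamped(24, 24, 40, 40, side = 64, seed = i,
                    color = c(0.2 * i, 0.1, 0.9 - 0.2 * i))
  })
  mo <- mosaicCompose(imgs, out_size = 128, seed = 5)
  expect_equal(mo@size, c(128L, 128L))
  regions <- attr(mo, "regions")
  expect_length(regions, 4)
  # pixel oracle: map an interior pixel of each region back through the
  # region's affine transform and compare with the source pixel
  for (k in 1:4) {
    rg <- regions[[k]]$region
    s <- regions[[k]]$scale
    px <- floor((rg[1] + rg[3]) / 2)
    py <- floor((rg[2] + rg[4]) / 2)
    sx <- (px + 0.5 - regions[[k]]$ox) / s
    sy <- (py + 0.5 - regions[[k]]$oy) / s
    src <- imgs[[k]]@image[floor(sy) + 1, floor(sx) + 1, ]
    expect_equal(as.numeric(mo@image[py + 1, px + 1, ]), as.numeric(src))
  }
  # empty sources give an empty mosaic
  blank <- lapply(1:4, function(i) {
    labeledImage(array(0.5, c(64, 64, 3)), boxTable())
  })
  expect_equal(nrow(mosaicCompose(blank, 128, seed = 2)@boxes), 0)
  expect_error(mosaicCompose(imgs[1:3], 128), "4 images")
})

test_that("mosaic box area never exceeds the scaled source box area", {
  imgs <- lapply(1:4, function(i) fixture_stamped(10, 10, 50, 50, side = 64,
                                                  seed = i))
  for (sd in 1:5) {
    mo <- mosaicCompose(imgs, out_size = 96, seed = sd)
    regions <- attr(mo, "regions")
    total_src <- sum(vapply(1:4, function(k) {
      b <- imgs[[k]]@boxes
      sum((b$xmax - b$xmin) * (b$ymax - b$ymin)) * regions[[k]]$scale^2
    }, 1))
    b <- mo@boxes
    total_out <- sum((b$xmax - b$xmin) * (b$ymax - b$ymin))
    expect_lte(total_out, total_src + 1e-9)
  }
})

test_that("equalizing deletion removes only augmented images to exact balance", {
  plan <- planOfflineAugmentation(c(A = 424, B = 1344))
  manifest <- data.frame(
    path = c(sprintf("A%04d", 1:1696), sprintf("B%04d", 1:1344)),
    class = c(rep("A", 1696), rep("B", 1344)),
    augmented = c(rep(FALSE, 424), rep(TRUE, 1272), rep(FALSE, 1344)),
    stringsAsFactors = FALSE
  )
  out <- equalizeByDeletion(manifest, plan, seed = 6)
  expect_equal(unname(table(out$class)["A"]), 1344)
  expect_equal(unname(table(out$class)["B"]), 1344)
  expect_true(all(manifest$path[!manifest$augmented] %in% out$path))
  # deterministic
  expect_identical(out, equalizeByDeletion(manifest, plan, seed = 6))
  expect_false(identical(out, equalizeByDeletion(manifest, plan, seed = 7)))

  # zero-deletion plan leaves the manifest unchanged
  plan0 <- planOfflineAugmentation(c(A = 100), 100)
  m0 <- data.frame(path = sprintf("A%03d", 1:100), class = "A",
                   augmented = FALSE, stringsAsFactors = FALSE)
  expect_identical(equalizeByDeletion(m0, plan0, seed = 1), m0)
  # inconsistent manifest is an error
  expect_error(equalizeByDeletion(m0[1:50, ], plan0, seed = 1), "inconsistent")
})

test_that("the full offline pipeline equalizes a small imbalanced set on disk", {
  dir <- withr::local_tempdir()
  dist <- stats::setNames(c(6L, 2L), smoke_classes()[1:2])
  m <- generateDataset(dist, dir, seed = 3,
                       specDefaults = list(canvasSize = c(64L, 64L)))
  out <- augmentDataset(m, seed = 4)
  tab <- table(out$class)
  expect_true(all(tab == 6))
  expect_true(all(file.exists(out$path)))
  aug <- out[out$augmented, ]
  expect_gt(nrow(aug), 0)
  li <- readVoc(aug$xml[1])
  expect_s4_class(li, "LabeledImage")
})
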