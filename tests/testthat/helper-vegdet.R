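# Shared fixtures. Everything is generated in code at test time; the tiny
# model and scene sets are cached per test run to keep the suite fast.

smoke_classes <- function() {
  c("tomato_early_blight", "cucumber_downy_mildew",
    "pepper_black_spot", "squash_viral_disease")
}

# a small deterministic labelled image with one axis-aligned lesion
fixture_stamped <- function(x0 = 10, y0 = 10, x1 = 40, y1 = 40, side = 64L,
                            label = "a", color = c(0.9, 0.2, 0.1), seed = 1L) {
  withr::with_seed(seed, {
    img <- array(stats::runif(side * side * 3) * 0.2, c(side, side, 3))
    stampLesion(img, x0, y0, x1, y1, label = label, color = color)
  })
}

# eight stamped two-class images for overfit/determinism probes
fixture_overfit_set <- function(side = 64L) {
  lapply(1:8, function(i) {
    cls <- c("a", "b")[(i %% 2) + 1]
    col <- if (cls == "a") c(0.9, 0.2, 0.1) else c(0.1, 0.3, 0.9)
    withr::with_seed(i, {
      x0 <- sample(5:18, 1); y0 <- sample(5:18, 1)
      w <- sample(25:38, 1); h <- sample(25:38, 1)
    })
    fixture_stamped(x0, y0, min(x0 + w, side - 1), min(y0 + h, side - 1),
                    side = side, label = cls, color = col, seed = 100 + i)
  })
}

# tiny detector cached across tests
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildModel(4, width_multiple = 0.25, seed = 7)
    cache
  }
})

# random ground-truth boxes within an image
random_gt <- function(n, side = 64, classes = c("a", "b"), seed = 1) {
  withr::with_seed(seed, {
    x0 <- runif(n, 0, side - 12)
    y0 <- runif(n, 0, side - 12)
    w <- runif(n, 8, side / 2)
    h <- runif(n, 8, side / 2)
    boxTable(sample(classes, n, replace = TRUE),
             x0, y0, pmin(x0 + w, side), pmin(y0 + h, side))
  })
}

# random detections derived by jittering ground truth plus noise boxes
random_dets <- function(gt, side = 64, extra = 2, seed = 1) {
  withr::with_seed(seed, {
    d <- gt
    jit <- function(v) v + runif(length(v), -4, 4)
    d$xmin <- pmax(jit(d$xmin), 0); d$ymin <- pmax(jit(d$ymin), 0)
    d$xmax <- pmin(pmax(jit(d$xmax), d$xmin + 2), side)
    d$ymax <- pmin(pmax(jit(d$ymax), d$ymin + 2), side)
    d$confidence <- runif(nrow(d), 0.3, 1)
    if (extra > 0) {
      fp <- random_gt(extra, side, unique(gt$label), seed = seed + 99)
      fp$confidence <- runif(extra, 0.05, 0.9)
      d <- rbind(d, fp)
    }
    d
  })
}
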