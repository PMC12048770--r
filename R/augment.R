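# Class-balanced offline augmentation planning, the seven box-aware
# transforms, equalizing deletion, and online Mosaic composition.
#
# Fragment rule: any transform that clips a box drops it when the retained
# area falls below 15% of the pre-clipping box area, reusing the edge
# threshold of the annotation filters.

FRAGMENT_MIN_AREA <- 0.15

GEOMETRIC_OPS <- c("hflip", "vflip", "rotate", "border_expand")
PHOTOMETRIC_OPS <- c("gamma", "contrast_stretch", "brightness", "gaussian_blur")

#' Plan offline augmentation to equalize class counts
#'
#' Each class receives `ceiling(target / n) - 1` augmented copies per
#' original image (over-generating), then `n * (1 + copies) - target`
#' augmented images are deleted so final counts all equal the target
#' exactly. The default target is the largest class count.
#'
#' @param dist named integer vector of per-class image counts (> 0).
#' @param target_count integer target per class, or "max-class".
#' @return an `AugmentationPlan`: list(target_count, copies_per_image,
#'   delete_after) with the exact-balance invariant
#'   `n * (1 + copies) - delete == target` for every class.
#' @export
planOfflineAugmentation <- function(dist, target_count = "max-class") {
  stopifnot(!is.null(names(dist)), all(dist > 0))
  counts <- as.numeric(dist)
  names(counts) <- names(dist)
  target <- if (identical(target_count, "max-class") || identical(target_count, "max")) {
    max(counts)
  } else {
    as.numeric(target_count)
  }
  if (target < max(counts)) {
    stop(sprintf(
      "target (%d) below the largest class count (%d): would require deleting originals",
      target, max(counts)
    ))
  }
  copies <- ceiling(target / counts) - 1
  delete_after <- counts * (1 + copies) - target
  stopifnot(all(counts * (1 + copies) - delete_after == target),
            all(copies >= 0), all(delete_after >= 0))
  structure(
    list(target_count = target, copies_per_image = copies,
         delete_after = delete_after),
    class = "AugmentationPlan"
  )
}

#' @export
print.AugmentationPlan <- function(x, ...) {
  cat(sprintf("AugmentationPlan: target %d images/class\n", x$target_count))
  print(data.frame(copies = x$copies_per_image, delete = x$delete_after))
  invisible(x)
}

# ---- geometric transforms -------------------------------------------------

clip_boxes <- function(b, W, H, min_frac = FRAGMENT_MIN_AREA, ref_area = NULL) {
  if (nrow(b) == 0) return(b)
  if (is.null(ref_area)) ref_area <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
  b$xmin <- pmax(b$xmin, 0); b$ymin <- pmax(b$ymin, 0)
  b$xmax <- pmin(b$xmax, W); b$ymax <- pmin(b$ymax, H)
  w <- pmax(b$xmax - b$xmin, 0)
  h <- pmax(b$ymax - b$ymin, 0)
  frac <- (w * h) / ref_area
  if (!is.null(b$visible_frac)) b$visible_frac <- pmin(b$visible_frac, frac)
  keep <- w > 0 & h > 0 & frac >= min_frac
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# nearest-neighbour inverse warp with a 2x2 linear map about the centre;
# fwd maps source -> output coordinates (0-based continuous)
warp_nearest <- function(img, A_inv, c_out, c_src, out_size, fill = 0) {
  Ho <- out_size[1]; Wo <- out_size[2]
  H <- dim(img)[1]; W <- dim(img)[2]
  g <- pix_grid(Ho, Wo)
  dx <- g$X - c_out[1]
  dy <- g$Y - c_out[2]
  sx <- A_inv[1, 1] * dx + A_inv[1, 2] * dy + c_src[1]
  sy <- A_inv[2, 1] * dx + A_inv[2, 2] * dy + c_src[2]
  ci <- floor(sx) + 1L
  ri <- floor(sy) + 1L
  ok <- ci >= 1L & ci <= W & ri >= 1L & ri <= H
  out <- array(fill, c(Ho, Wo, 3L))
  idx_ok <- which(ok)
  src_idx <- (ci[idx_ok] - 1L) * H + ri[idx_ok]
  for (ch in 1:3) {
    plane <- matrix(fill, Ho, Wo)
    srcp <- img[, , ch]
    plane[idx_ok] <- srcp[src_idx]
    out[, , ch] <- plane
  }
  out
}

transform_boxes_affine <- function(b, A, c_src, c_out) {
  if (nrow(b) == 0) return(b)
  for (i in seq_len(nrow(b))) {
    xs <- c(b$xmin[i], b$xmax[i], b$xmin[i], b$xmax[i]) - c_src[1]
    ys <- c(b$ymin[i], b$ymin[i], b$ymax[i], b$ymax[i]) - c_src[2]
    tx <- A[1, 1] * xs + A[1, 2] * ys + c_out[1]
    ty <- A[2, 1] * xs + A[2, 2] * ys + c_out[2]
    b$xmin[i] <- min(tx); b$xmax[i] <- max(tx)
    b$ymin[i] <- min(ty); b$ymax[i] <- max(ty)
  }
  b
}

#' Apply a geometric, box-aware augmentation
#'
#' Boxes follow the same affine map as the pixels; clipped fragments
#' retaining under 15% of their area are dropped.
#'
#' @param img a [LabeledImage-class] (raster required).
#' @param op "hflip", "vflip", "rotate" or "border_expand".
#' @param angle rotation angle in degrees (rotate only); drawn from
#'   [-25, 25] when NULL.
#' @param pad border padding in pixels (border_expand only); drawn from
#'   [4, 24] when NULL.
#' @param seed integer seed for drawn parameters.
#' @return the transformed [LabeledImage-class].
#' @export
applyGeometric <- function(img, op = GEOMETRIC_OPS, angle = NULL, pad = NULL,
                           seed = 1L) {
  op <- match.arg(op)
  stopifnot(!is.null(img@image))
  H <- img@size[1]; W <- img@size[2]
  b <- img@boxes
  im <- img@image
  if (op == "hflip") {
    out <- im[, W:1, , drop = FALSE]
    if (nrow(b) > 0) {
      x0 <- b$xmin
      b$xmin <- W - b$xmax
      b$xmax <- W - x0
    }
    return(labeledImage(out, b))
  }
  if (op == "vflip") {
    out <- im[H:1, , , drop = FALSE]
    if (nrow(b) > 0) {
      y0 <- b$ymin
      b$ymin <- H - b$ymax
      b$ymax <- H - y0
    }
    return(labeledImage(out, b))
  }
  if (op == "rotate") {
    if (is.null(angle)) {
      angle <- withr::with_seed(as.integer(seed), stats::runif(1, -25, 25))
    }
    th <- angle * pi / 180
    A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    ctr <- c(W / 2, H / 2)
    out <- warp_nearest(im, solve(A), ctr, ctr, c(H, W))
    b2 <- transform_boxes_affine(b, A, ctr, ctr)
    b2 <- clip_boxes(b2, W, H)
    return(labeledImage(out, b2))
  }
  # border_expand
  if (is.null(pad)) {
    pad <- withr::with_seed(as.integer(seed), sample(4:24, 1))
  }
  pad <- as.integer(pad)
  stopifnot(pad >= 0)
  ri <- c(rep(1L, pad), seq_len(H), rep(H, pad))
  ci <- c(rep(1L, pad), seq_len(W), rep(W, pad))
  out <- im[ri, ci, , drop = FALSE]
  if (nrow(b) > 0) {
    b$xmin <- b$xmin + pad; b$xmax <- b$xmax + pad
    b$ymin <- b$ymin + pad; b$ymax <- b$ymax + pad
  }
  labeledImage(out, b)
}

#' Apply a photometric augmentation (geometry-preserving)
#'
#' Boxes are returned unchanged; pixel values stay clipped to [0, 1].
#'
#' @param img a [LabeledImage-class].
#' @param op "gamma", "contrast_stretch", "brightness" or "gaussian_blur".
#' @param param operation parameter (gamma exponent, brightness factor or
#'   blur sigma); a seeded draw from the default range when NULL.
#' @param seed integer seed.
#' @return the adjusted [LabeledImage-class].
#' @export
applyPhotometric <- function(img, op = PHOTOMETRIC_OPS, param = NULL, seed = 1L) {
  op <- match.arg(op)
  stopifnot(!is.null(img@image))
  im <- img@image
  draw <- function(lo, hi) {
    if (!is.null(param)) param else withr::with_seed(as.integer(seed), stats::runif(1, lo, hi))
  }
  out <- switch(op,
    gamma = pmin(pmax(im, 0), 1)^draw(0.6, 1.5),
    contrast_stretch = {
      lo <- stats::quantile(im, 0.02)
      hi <- stats::quantile(im, 0.98)
      if (hi - lo < 1e-8) im else pmin(pmax((im - lo) / (hi - lo), 0), 1)
    },
    brightness = pmin(im * draw(0.7, 1.4), 1),
    gaussian_blur = {
      s <- draw(0.5, 1.5)
      if (s < 0.05) im else {
        blurred <- EBImage::gblur(im, sigma = s)
        pmin(pmax(blurred, 0), 1)
      }
    }
  )
  labeledImage(out, img@boxes)
}

#' Apply one randomly chosen transform out of the seven
#'
#' The offline augmentation policy: each augmented copy receives a single
#' seeded transform drawn uniformly from the configured list.
#'
#' @param img a [LabeledImage-class].
#' @param seed integer seed (chooses the transform and its parameters).
#' @param transforms candidate transform names.
#' @return augmented [LabeledImage-class].
#' @export
randomAugment <- function(img, seed = 1L,
                          transforms = c(GEOMETRIC_OPS, PHOTOMETRIC_OPS)) {
  op <- withr::with_seed(as.integer(seed), sample(transforms, 1))
  if (op %in% GEOMETRIC_OPS) {
    applyGeometric(img, op, seed = seed + 1L)
  } else {
    applyPhotometric(img, op, seed = seed + 1L)
  }
}

# ---- Mosaic ---------------------------------------------------------------

#' Mosaic composition of four labelled images
#'
#' A seeded centre point splits the output canvas into four regions; each
#' source image is scaled (uniformly, covering its region) with a random
#' overshoot, randomly positioned, and cropped to the region. Boxes map
#' through each region's affine transform, are clipped to the region, and
#' fragments under the 15% retained-area rule are dropped.
#'
#' @param imgs list of exactly 4 [LabeledImage-class] objects with rasters.
#' @param out_size output canvas side (square).
#' @param center_jitter centre location range as a fraction of out_size.
#' @param seed integer seed.
#' @return a [LabeledImage-class]; attribute "regions" carries each
#'   region's crop window and affine map (sx, sy, ox, oy).
#' @export
mosaicCompose <- function(imgs, out_size = 256L, center_jitter = c(0.3, 0.7),
                          seed = 1L) {
  if (length(imgs) != 4L) stop("mosaic requires exactly 4 images")
  stopifnot(all(vapply(imgs, function(x) !is.null(x@image), TRUE)))
  S <- as.integer(out_size)
  withr::with_seed(as.integer(seed), {
    cx <- round(stats::runif(1, center_jitter[1], center_jitter[2]) * S)
    cy <- round(stats::runif(1, center_jitter[1], center_jitter[2]) * S)
    cx <- min(max(cx, 2L), S - 2L)
    cy <- min(max(cy, 2L), S - 2L)
    # regions as 0-based half-open windows (x0, y0, x1, y1)
    regions <- list(
      c(0, 0, cx, cy), c(cx, 0, S, cy), c(0, cy, cx, S), c(cx, cy, S, S)
    )
    out <- array(0, c(S, S, 3L))
    all_boxes <- boxTable()
    meta <- list()
    for (k in 1:4) {
      rg <- regions[[k]]
      rw <- rg[3] - rg[1]; rh <- rg[4] - rg[2]
      src <- imgs[[k]]
      H <- src@size[1]; W <- src@size[2]
      s <- max(rw / W, rh / H) * stats::runif(1, 1.0, 1.4)
      # random placement of the scaled image so that it covers the region
      ox <- rg[1] - stats::runif(1, 0, max(W * s - rw, 0))
      oy <- rg[2] - stats::runif(1, 0, max(H * s - rh, 0))
      # output pixel (x, y) in region samples source ((x - ox)/s, (y - oy)/s)
      rows <- (rg[2] + 1L):rg[4]
      cols <- (rg[1] + 1L):rg[3]
      gx <- (cols - 0.5 - ox) / s
      gy <- (rows - 0.5 - oy) / s
      ci <- pmin(pmax(floor(gx) + 1L, 1L), W)
      ri <- pmin(pmax(floor(gy) + 1L, 1L), H)
      for (ch in 1:3) {
        out[rows, cols, ch] <- src@image[ri, ci, ch]
      }
      b <- src@boxes
      if (nrow(b) > 0) {
        ref_area <- (b$xmax - b$xmin) * (b$ymax - b$ymin) * s * s
        b$xmin <- b$xmin * s + ox; b$xmax <- b$xmax * s + ox
        b$ymin <- b$ymin * s + oy; b$ymax <- b$ymax * s + oy
        # clip to the region window
        b$xmin <- pmax(b$xmin, rg[1]); b$ymin <- pmax(b$ymin, rg[2])
        b$xmax <- pmin(b$xmax, rg[3]); b$ymax <- pmin(b$ymax, rg[4])
        w <- pmax(b$xmax - b$xmin, 0)
        h <- pmax(b$ymax - b$ymin, 0)
        keep <- w > 0 & h > 0 & (w * h) / ref_area >= FRAGMENT_MIN_AREA
        b <- b[keep, , drop = FALSE]
        all_boxes <- rbind(all_boxes, b)
      }
      meta[[k]] <- list(region = rg, scale = s, ox = ox, oy = oy)
    }
    rownames(all_boxes) <- NULL
    res <- labeledImage(out, all_boxes)
    attr(res, "regions") <- meta
    res
  })
}

# ---- deletion and the offline pipeline ------------------------------------

#' Delete augmented images to equalize final class counts
#'
#' Only augmented images are ever deleted; originals are untouchable. After
#' deletion every class has exactly `plan$target_count` images.
#'
#' @param manifest manifest with `class` and logical `augmented` columns.
#' @param plan an [planOfflineAugmentation()] plan.
#' @param seed integer seed for the random deletion draw.
#' @return the reduced manifest.
#' @export
equalizeByDeletion <- function(manifest, plan, seed = 1L) {
  stopifnot(inherits(plan, "AugmentationPlan"), "augmented" %in% names(manifest))
  drop_idx <- integer()
  withr::with_seed(as.integer(seed), {
    for (cls in names(plan$delete_after)) {
      nd <- plan$delete_after[[cls]]
      have <- sum(manifest$class == cls)
      if (have != plan$target_count + nd) {
        stop(sprintf(
          "plan inconsistent with manifest for class '%s': %d images, expected %d",
          cls, have, plan$target_count + nd
        ))
      }
      if (nd == 0) next
      aug_idx <- which(manifest$class == cls & manifest$augmented)
      if (length(aug_idx) < nd) {
        stop(sprintf("class '%s' has only %d augmented images, %d deletions needed",
                     cls, length(aug_idx), nd))
      }
      drop_idx <- c(drop_idx, aug_idx[sample.int(length(aug_idx), nd)])
    }
  })
  out <- if (length(drop_idx)) manifest[-drop_idx, , drop = FALSE] else manifest
  rownames(out) <- NULL
  out
}

#' Run the offline augmentation pipeline on a dataset
#'
#' Generates the planned augmented copies (one random transform each),
#' writes them next to the originals, then deletes the over-generated
#' surplus so that final class counts are exactly equal.
#'
#' @param manifest manifest of original images (path, xml, class columns).
#' @param plan augmentation plan; computed from the manifest when NULL.
#' @param outDir directory for augmented files (defaults to the source dir).
#' @param seed integer seed.
#' @param transforms transform pool for [randomAugment()].
#' @return the balanced manifest including surviving augmented rows.
#' @export
augmentDataset <- function(manifest, plan = NULL, outDir = NULL, seed = 1L,
                           transforms = c(GEOMETRIC_OPS, PHOTOMETRIC_OPS)) {
  counts <- table(manifest$class)
  if (is.null(plan)) {
    plan <- planOfflineAugmentation(stats::setNames(as.integer(counts), names(counts)))
  }
  rows <- list(manifest)
  n_new <- 0L
  for (i in seq_len(nrow(manifest))) {
    cls <- manifest$class[i]
    nc <- plan$copies_per_image[[cls]]
    if (nc == 0) next
    li <- readVoc(manifest$xml[i], load_image = TRUE)
    dir <- if (is.null(outDir)) dirname(manifest$path[i]) else outDir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (j in seq_len(nc)) {
      n_new <- n_new + 1L
      aug_seed <- as.integer((as.integer(seed) * 7L + n_new * 13L) %% .Machine$integer.max)
      ai <- randomAugment(li, seed = aug_seed, transforms = transforms)
      stem <- sprintf("%s_aug%d", sub("\\.xml$", "", basename(manifest$xml[i])), j)
      ipath <- file.path(dir, paste0(stem, ".png"))
      xpath <- file.path(dir, paste0(stem, ".xml"))
      png::writePNG(ai@image, ipath)
      writeVoc(ai, xpath, image_path = ipath)
      rows[[length(rows) + 1L]] <- data.frame(
        path = ipath, xml = xpath, class = cls,
        split = manifest$split[i], seed = aug_seed, augmented = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  full <- do.call(rbind, rows)
  equalizeByDeletion(full, plan, seed = seed)
}
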