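# Synthetic greenhouse scenes with exact ground truth.
#
# Scenes emulate the conditions of protected-vegetable imagery: textured
# soil background, overlapping leaves, disease lesions whose size relative
# to the leaf follows the early/mid/late progression, partial occlusion by
# foreground foliage, and four lighting regimes (normal / low / strong
# direct / specular reflection). Lesion colour encodes the disease class so
# that detectors have a learnable class signal; no attempt is made at
# photorealism or pathogen-specific morphology.

#' Lesion-area stage fractions (of leaf area)
#'
#' Qualitative early/mid/late progression made quantitative: early lesions
#' occupy at most 5% of the leaf, mid 5-40%, late over 40%.
#' @export
stageFractions <- function() {
  list(early = c(0.005, 0.05), mid = c(0.05, 0.40), late = c(0.40, 0.85))
}

#' The default 30-class label space (5 vegetables, health + diseases)
#'
#' Mirrors the composition of the study's label space: tomato carries nine
#' diseases plus a healthy class, the other four vegetables four diseases
#' plus healthy each. Label sets are fully configurable everywhere; this is
#' only the default.
#' @export
defaultClassList <- function() {
  c(
    "tomato_health", "tomato_gray_mold", "tomato_gray_leaf_spot",
    "tomato_black_spot", "tomato_late_blight", "tomato_brown_rot",
    "tomato_bacterial_canker", "tomato_early_blight", "tomato_bacterial_spot",
    "tomato_leaf_mold",
    "cucumber_health", "cucumber_target_spot", "cucumber_powdery_mildew",
    "cucumber_angular_spot", "cucumber_downy_mildew",
    "pepper_health", "pepper_leaf_spot", "pepper_powdery_mildew",
    "pepper_black_spot", "pepper_early_blight",
    "eggplant_health", "eggplant_yellow_wilt", "eggplant_brown_spot",
    "eggplant_angular_spot", "eggplant_brown_rot",
    "squash_health", "squash_viral_disease", "squash_silver_leaf",
    "squash_downy_mildew", "squash_brown_rot"
  )
}

is_healthy_label <- function(label) grepl("health", label, fixed = TRUE)

#' Deterministic distinct lesion colours per class
#'
#' Hues are spread over the colour circle skipping the leaf-green band so
#' lesions remain distinguishable from foliage.
#' @param classes character vector of class labels.
#' @return named 3-column matrix of RGB values in [0, 1].
#' @export
classPalette <- function(classes) {
  n <- length(classes)
  raw <- (seq_len(n) - 1) / max(n, 1) * 0.77
  hue <- ifelse(raw < 0.22, raw, raw + 0.23)
  cols <- t(grDevices::col2rgb(grDevices::hsv(hue, 0.85, 0.72)) / 255)
  rownames(cols) <- classes
  cols
}

#' Scene specification for the synthetic generator
#'
#' @slot canvasSize integer (height, width), at least 64 x 64.
#' @slot nLeaves number of leaves.
#' @slot lesionsPerLeaf integer (min, max) lesions per leaf.
#' @slot stage "early", "mid", "late" (lesion-to-leaf area fraction band)
#'   or "random".
#' @slot occlusionLevel target occluded fraction per lesion in [0, 1].
#' @slot lighting "normal", "low", "direct", "reflection" or "random".
#' @slot classLabel disease class (a *_health label gives a lesion-free
#'   scene).
#' @slot classes the full label space (drives the colour palette).
#' @slot seed integer; fully determines the scene.
#' @export
setClass("SceneSpec", representation(
  canvasSize = "integer", nLeaves = "integer", lesionsPerLeaf = "integer",
  stage = "character", occlusionLevel = "numeric", lighting = "character",
  classLabel = "character", classes = "character", seed = "integer"
), validity = function(object) {
  if (any(object@canvasSize < 64L)) return("canvas must be at least 64x64")
  if (!object@stage %in% c(names(stageFractions()), "random")) {
    return(sprintf("invalid stage '%s'", object@stage))
  }
  if (!object@lighting %in% c("normal", "low", "direct", "reflection", "random")) {
    return(sprintf("invalid lighting '%s'", object@lighting))
  }
  if (object@occlusionLevel < 0 || object@occlusionLevel > 1) {
    return("occlusionLevel must be in [0, 1]")
  }
  if (!object@classLabel %in% object@classes) {
    return(sprintf("classLabel '%s' not in class list", object@classLabel))
  }
  TRUE
})

#' Create a SceneSpec
#'
#' Defaults describe the study-like regime: a few overlapping leaves,
#' random disease stage, moderate occlusion and randomly drawn lighting.
#'
#' @param classLabel disease class label.
#' @param canvasSize (height, width) in pixels.
#' @param nLeaves leaf count.
#' @param lesionsPerLeaf (min, max) lesions per diseased leaf.
#' @param stage lesion development stage or "random".
#' @param occlusionLevel target per-lesion occluded fraction.
#' @param lighting lighting condition or "random".
#' @param classes full label space.
#' @param seed integer seed; same spec (incl. seed) gives a bit-identical
#'   scene.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(classLabel, canvasSize = c(128L, 128L), nLeaves = 3L,
                      lesionsPerLeaf = c(1L, 3L), stage = "random",
                      occlusionLevel = 0.15, lighting = "random",
                      classes = defaultClassList(), seed = 1L) {
  new("SceneSpec", canvasSize = as.integer(canvasSize),
      nLeaves = as.integer(nLeaves), lesionsPerLeaf = as.integer(lesionsPerLeaf),
      stage = stage, occlusionLevel = occlusionLevel, lighting = lighting,
      classLabel = classLabel, classes = classes, seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec %dx%d class=%s stage=%s lighting=%s occl=%.2f seed=%d\n",
              object@canvasSize[1], object@canvasSize[2], object@classLabel,
              object@stage, object@lighting, object@occlusionLevel, object@seed))
})

# ---- drawing primitives ---------------------------------------------------

# pixel-centre coordinate grids (0-based continuous): pixel (r, c) has
# centre (x, y) = (c - 0.5, r - 0.5)
pix_grid <- function(H, W) {
  list(
    X = matrix(rep(seq_len(W) - 0.5, each = H), H, W),
    Y = matrix(rep(seq_len(H) - 0.5, W), H, W)
  )
}

ellipse_mask <- function(grid, cx, cy, a, b, theta) {
  dx <- grid$X - cx
  dy <- grid$Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

paint_mask <- function(img, mask, color, texture_sd = 0) {
  idx <- which(mask)
  if (length(idx) == 0) return(img)
  tex <- if (texture_sd > 0) stats::rnorm(length(idx), 0, texture_sd) else 0
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- pmin(pmax(color[ch] + tex, 0), 1)
    img[, , ch] <- plane
  }
  img
}

# bounding half-extents of a rotated ellipse
ellipse_box_halfwidths <- function(a, b, theta) {
  c(
    sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
    sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  )
}

#' Stamp a single rectangular-extent lesion onto an image
#'
#' Draws the ellipse inscribed in the given rectangle (so the drawn extent
#' equals the rectangle) and returns the image with exactly that box.
#' Mostly a testing aid for the box-extent contract.
#'
#' @param image H x W x 3 array.
#' @param xmin,ymin,xmax,ymax rectangle (0-based half-open pixels).
#' @param label class label for the box.
#' @param color RGB triple.
#' @return a [LabeledImage-class] with one box.
#' @export
stampLesion <- function(image, xmin, ymin, xmax, ymax, label = "lesion",
                        color = c(0.45, 0.2, 0.1)) {
  d <- dim(image)
  grid <- pix_grid(d[1], d[2])
  cx <- (xmin + xmax) / 2
  cy <- (ymin + ymax) / 2
  mask <- ellipse_mask(grid, cx, cy, (xmax - xmin) / 2, (ymax - ymin) / 2, 0)
  image <- paint_mask(image, mask, color)
  labeledImage(image, boxTable(label, xmin, ymin, xmax, ymax))
}

# ---- lighting -------------------------------------------------------------

#' Apply a lighting condition to an image raster
#'
#' normal is the identity; low scales brightness down; direct scales up with
#' clipping; reflection adds seeded specular highlight blobs. Ground-truth
#' boxes are unaffected by lighting.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param mode one of "normal", "low", "direct", "reflection".
#' @param seed integer seed (used by "reflection" blob placement).
#' @return the adjusted image array.
#' @export
applyLighting <- function(img, mode = c("normal", "low", "direct", "reflection"),
                          seed = 1L) {
  mode <- match.arg(mode)
  switch(mode,
    normal = img,
    low = img * 0.45,
    direct = pmin(img * 1.6, 1),
    reflection = withr::with_seed(as.integer(seed), {
      d <- dim(img)
      grid <- pix_grid(d[1], d[2])
      nb <- sample(2:4, 1)
      add <- matrix(0, d[1], d[2])
      for (i in seq_len(nb)) {
        cx <- stats::runif(1, 0, d[2])
        cy <- stats::runif(1, 0, d[1])
        sg <- stats::runif(1, 0.03, 0.09) * min(d[1:2])
        amp <- stats::runif(1, 0.35, 0.7)
        add <- add + amp * exp(-((grid$X - cx)^2 + (grid$Y - cy)^2) / (2 * sg^2))
      }
      out <- img
      for (ch in 1:3) out[, , ch] <- pmin(img[, , ch] + add, 1)
      out
    })
  )
}

# ---- scene generation -----------------------------------------------------

#' Generate one synthetic greenhouse scene with ground truth
#'
#' @param spec a [sceneSpec()].
#' @return a [LabeledImage-class]; healthy classes carry zero boxes, every
#'   lesion box records the exact occlusion fraction applied and the
#'   fraction of its extent left inside the canvas.
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  withr::with_seed(spec@seed, {
    H <- spec@canvasSize[1]; W <- spec@canvasSize[2]
    grid <- pix_grid(H, W)
    palette <- classPalette(spec@classes)
    stage <- if (spec@stage == "random") sample(names(stageFractions()), 1) else spec@stage
    lighting <- if (spec@lighting == "random") {
      sample(c("normal", "low", "direct", "reflection"), 1)
    } else spec@lighting

    # soil background with pixel noise
    img <- array(0, c(H, W, 3))
    base <- c(0.34, 0.25, 0.16)
    for (ch in 1:3) {
      img[, , ch] <- pmin(pmax(base[ch] + stats::rnorm(H * W, 0, 0.04), 0), 1)
    }

    # leaves
    leaves <- list()
    for (i in seq_len(spec@nLeaves)) {
      al <- stats::runif(1, 0.16, 0.30) * min(H, W)
      bl <- al * stats::runif(1, 0.55, 0.9)
      cx <- stats::runif(1, 0.2 * W, 0.8 * W)
      cy <- stats::runif(1, 0.2 * H, 0.8 * H)
      th <- stats::runif(1, 0, pi)
      green <- c(stats::runif(1, 0.10, 0.22), stats::runif(1, 0.40, 0.60),
                 stats::runif(1, 0.08, 0.20))
      img <- paint_mask(img, ellipse_mask(grid, cx, cy, al, bl, th), green,
                        texture_sd = 0.03)
      leaves[[i]] <- list(cx = cx, cy = cy, a = al, b = bl, theta = th,
                          area = pi * al * bl, color = green)
    }

    boxes <- boxTable()
    lesion_masks <- list()
    leaf_areas <- numeric()
    if (!is_healthy_label(spec@classLabel)) {
      frac_range <- stageFractions()[[stage]]
      color <- palette[spec@classLabel, ]
      for (leaf in leaves) {
        k <- sample(seq.int(spec@lesionsPerLeaf[1], spec@lesionsPerLeaf[2]), 1)
        for (j in seq_len(k)) {
          f <- stats::runif(1, frac_range[1], frac_range[2])
          asp <- stats::runif(1, 1, 1.8)
          th <- stats::runif(1, 0, pi)
          hw0 <- ellipse_box_halfwidths(asp, 1 / asp, th)
          scale <- sqrt(f * leaf$area / (4 * hw0[1] * hw0[2]))
          a <- asp * scale
          b <- scale / asp
          # lesion centre inside the central part of the leaf
          r <- sqrt(stats::runif(1)) * 0.7
          phi <- stats::runif(1, 0, 2 * pi)
          u <- r * leaf$a * cos(phi)
          v <- r * leaf$b * sin(phi)
          cx <- leaf$cx + u * cos(leaf$theta) - v * sin(leaf$theta)
          cy <- leaf$cy + u * sin(leaf$theta) + v * cos(leaf$theta)
          mask <- ellipse_mask(grid, cx, cy, a, b, th)
          img <- paint_mask(img, mask, color, texture_sd = 0.025)
          # darker interior speckles (do not change the extent)
          nd <- sample(0:2, 1)
          for (s in seq_len(nd)) {
            ds <- min(a, b) * stats::runif(1, 0.15, 0.35)
            ox <- stats::runif(1, -0.4, 0.4) * a
            oy <- stats::runif(1, -0.4, 0.4) * b
            img <- paint_mask(
              img,
              ellipse_mask(grid, cx + ox, cy + oy, ds, ds, 0) & mask,
              color * 0.6
            )
          }
          hw <- ellipse_box_halfwidths(a, b, th)
          full <- c(cx - hw[1], cy - hw[2], cx + hw[1], cy + hw[2])
          clip <- c(max(full[1], 0), max(full[2], 0), min(full[3], W), min(full[4], H))
          if (clip[1] >= clip[3] - 1 || clip[2] >= clip[4] - 1) next
          vis <- ((clip[3] - clip[1]) * (clip[4] - clip[2])) /
            ((full[3] - full[1]) * (full[4] - full[2]))
          boxes <- rbind(boxes, boxTable(spec@classLabel, clip[1], clip[2],
                                         clip[3], clip[4], occlusion = 0,
                                         visible_frac = vis))
          lesion_masks[[nrow(boxes)]] <- mask
          leaf_areas[nrow(boxes)] <- leaf$area
        }
      }
    }

    # occlusion: overdraw foreground leaf-coloured blobs over lesions and
    # record the exactly measured covered fraction per lesion
    if (spec@occlusionLevel > 0 && nrow(boxes) > 0) {
      occ_mask <- matrix(FALSE, H, W)
      for (bi in seq_len(nrow(boxes))) {
        m <- lesion_masks[[bi]]
        npx <- sum(m)
        if (npx == 0) next
        idx <- which(m)
        ctr <- idx[sample.int(length(idx), 1)]
        ocy <- (ctr - 1) %% H + 0.5
        ocx <- (ctr - 1) %/% H + 0.5
        oa <- sqrt(spec@occlusionLevel * npx / pi) * stats::runif(1, 0.9, 1.3)
        fg <- c(stats::runif(1, 0.12, 0.2), stats::runif(1, 0.45, 0.6),
                stats::runif(1, 0.1, 0.18))
        om <- ellipse_mask(grid, ocx, ocy, oa, oa * stats::runif(1, 0.7, 1), 0)
        img <- paint_mask(img, om, fg, texture_sd = 0.03)
        occ_mask <- occ_mask | om
      }
      for (bi in seq_len(nrow(boxes))) {
        m <- lesion_masks[[bi]]
        boxes$occlusion[bi] <- sum(m & occ_mask) / max(sum(m), 1)
      }
    }

    img <- applyLighting(img, lighting, seed = spec@seed + 7919L)
    out <- labeledImage(img, boxes)
    attr(out, "leaf_area") <- leaf_areas
    attr(out, "stage") <- stage
    attr(out, "lighting") <- lighting
    out
  })
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes one PNG + VOC XML per image and a JSON-lines manifest. Per-class
#' image counts match `dist` exactly; the whole tree is a deterministic
#' function of `seed`.
#'
#' @param dist named integer vector: images per class.
#' @param outDir output directory (created if needed).
#' @param seed integer master seed.
#' @param specDefaults named list of [sceneSpec()] arguments applied to all
#'   scenes (e.g. canvasSize, stage, occlusionLevel, lighting).
#' @param classes full label space (defaults to the names of `dist`).
#' @param split split tag recorded in the manifest ("train" by default).
#' @return the manifest data.frame (invisibly written to
#'   `<outDir>/manifest.jsonl`).
#' @export
generateDataset <- function(dist, outDir, seed = 1L, specDefaults = list(),
                            classes = NULL, split = "train") {
  stopifnot(all(dist >= 0), !is.null(names(dist)))
  if (is.null(classes)) classes <- names(dist)
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  }
  if (file.access(outDir, 2) != 0) stop("output directory not writable: ", outDir)
  rows <- list()
  idx <- 0L
  seed0 <- as.integer(seed) %% 20000L
  for (cls in names(dist)) {
    for (i in seq_len(dist[[cls]])) {
      idx <- idx + 1L
      img_seed <- seed0 * 100000L + idx
      args <- c(list(classLabel = cls, classes = classes, seed = img_seed),
                specDefaults)
      spec <- do.call(sceneSpec, args)
      li <- generateScene(spec)
      stem <- sprintf("%s_%04d", cls, i)
      img_path <- file.path(outDir, paste0(stem, ".png"))
      xml_path <- file.path(outDir, paste0(stem, ".xml"))
      png::writePNG(li@image, img_path)
      writeVoc(li, xml_path, image_path = img_path)
      rows[[idx]] <- data.frame(path = img_path, xml = xml_path, class = cls,
                                split = split, seed = img_seed,
                                augmented = FALSE, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) {
    manifest <- data.frame(path = character(), xml = character(),
                           class = character(), split = character(),
                           seed = integer(), augmented = logical())
  }
  writeManifest(manifest, file.path(outDir, "manifest.jsonl"))
  manifest
}
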