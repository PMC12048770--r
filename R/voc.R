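# PASCAL-VOC annotation I/O (LabelImg dialect), the study's labelling
# filters, and stratified dataset partitioning.
#
# Internal coordinates are 0-based half-open pixel intervals; the XML on
# disk uses the 1-based inclusive convention of LabelImg, so a box covering
# pixels 10..19 (0-based) is stored as xmin=11, xmax=20.

#' Write a VOC XML annotation
#'
#' @param img a [LabeledImage-class].
#' @param xml_path output path.
#' @param image_path path recorded in the `<path>`/`<filename>` fields.
#' @return `xml_path` invisibly.
#' @export
writeVoc <- function(img, xml_path, image_path = img@sourcePath) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", dirname(image_path))
  xml2::xml_add_child(doc, "filename", basename(image_path))
  xml2::xml_add_child(doc, "path", image_path)
  src <- xml2::xml_add_child(doc, "source")
  xml2::xml_add_child(src, "database", "Unknown")
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(img@size[2]))
  xml2::xml_add_child(size, "height", as.character(img@size[1]))
  xml2::xml_add_child(size, "depth", "3")
  xml2::xml_add_child(doc, "segmented", "0")
  b <- img@boxes
  for (i in seq_len(nrow(b))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", b$label[i])
    xml2::xml_add_child(ob, "pose", "Unspecified")
    xml2::xml_add_child(ob, "truncated",
                        if (isTRUE(b$visible_frac[i] < 1)) "1" else "0")
    xml2::xml_add_child(ob, "difficult", if (isTRUE(b$difficult[i])) "1" else "0")
    if (!is.null(b$occlusion)) {
      xml2::xml_add_child(ob, "occlusion_fraction", format(b$occlusion[i], digits = 6))
    }
    if (!is.null(b$visible_frac)) {
      xml2::xml_add_child(ob, "visible_fraction", format(b$visible_frac[i], digits = 6))
    }
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(round(b$xmin[i]) + 1L))
    xml2::xml_add_child(bb, "ymin", as.character(round(b$ymin[i]) + 1L))
    xml2::xml_add_child(bb, "xmax", as.character(round(b$xmax[i])))
    xml2::xml_add_child(bb, "ymax", as.character(round(b$ymax[i])))
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

#' Read a VOC XML annotation
#'
#' @param xml_path annotation path.
#' @param load_image load the referenced raster when the file exists
#'   (PNG only).
#' @return a [LabeledImage-class]; `image` is NULL when not loaded.
#' @export
readVoc <- function(xml_path, load_image = TRUE) {
  if (!file.exists(xml_path)) stop("annotation file not found: ", xml_path)
  doc <- tryCatch(xml2::read_xml(xml_path), error = function(e) {
    stop(sprintf("malformed VOC XML in '%s': %s", xml_path, conditionMessage(e)))
  })
  size <- xml2::xml_find_first(doc, "size")
  W <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "width")))
  H <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "height")))
  objs <- xml2::xml_find_all(doc, "object")
  txt1 <- function(node, xp, default = NA_character_) {
    n <- xml2::xml_find_first(node, xp)
    if (inherits(n, "xml_missing")) default else xml2::xml_text(n)
  }
  b <- boxTable()
  for (ob in objs) {
    xmin <- as.numeric(txt1(ob, "bndbox/xmin")) - 1
    ymin <- as.numeric(txt1(ob, "bndbox/ymin")) - 1
    xmax <- as.numeric(txt1(ob, "bndbox/xmax"))
    ymax <- as.numeric(txt1(ob, "bndbox/ymax"))
    if (any(is.na(c(xmin, ymin, xmax, ymax)))) {
      stop(sprintf("missing bndbox coordinates in '%s'", xml_path))
    }
    if (xmin >= xmax || ymin >= ymax) {
      stop(sprintf("invalid box in '%s': xmin/ymin must be < xmax/ymax", xml_path))
    }
    occl <- suppressWarnings(as.numeric(txt1(ob, "occlusion_fraction", "0")))
    vis <- suppressWarnings(as.numeric(txt1(ob, "visible_fraction", "1")))
    b <- rbind(b, boxTable(txt1(ob, "name"), xmin, ymin, xmax, ymax,
                           occlusion = if (is.na(occl)) 0 else occl,
                           visible_frac = if (is.na(vis)) 1 else vis,
                           difficult = identical(txt1(ob, "difficult", "0"), "1")))
  }
  img_path <- txt1(doc, "path", "")
  if (is.na(img_path) || !nzchar(img_path) || !file.exists(img_path)) {
    cand <- file.path(dirname(xml_path), txt1(doc, "filename", ""))
    if (file.exists(cand)) img_path <- cand
  }
  image <- NULL
  if (load_image && !is.na(img_path) && nzchar(img_path) && file.exists(img_path)) {
    image <- png::readPNG(img_path)
    if (length(dim(image)) == 2L) image <- array(rep(image, 3), c(dim(image), 3L))
    if (dim(image)[3] > 3L) image <- image[, , 1:3, drop = FALSE]
  }
  labeledImage(image, b, sourcePath = if (is.na(img_path)) "" else img_path,
               size = c(H, W))
}

#' Apply the study's annotation-retention filters
#'
#' Drops targets whose occluded fraction exceeds `occlusion_max` and
#' border-touching targets retaining less than `edge_min_area` of their full
#' extent inside the image. Defaults are the published thresholds
#' (occlusion > 85%, edge-retained area < 15%). Idempotent.
#'
#' @param img a [LabeledImage-class].
#' @param occlusion_max occlusion fraction above which a target is dropped.
#' @param edge_min_area minimum retained area fraction for border boxes.
#' @return the filtered [LabeledImage-class].
#' @export
filterAnnotations <- function(img, occlusion_max = 0.85, edge_min_area = 0.15) {
  stopifnot(occlusion_max >= 0, occlusion_max <= 1,
            edge_min_area >= 0, edge_min_area <= 1)
  b <- img@boxes
  if (nrow(b) == 0) return(img)
  H <- img@size[1]; W <- img@size[2]
  occl <- if (is.null(b$occlusion)) rep(0, nrow(b)) else b$occlusion
  vis <- if (is.null(b$visible_frac)) rep(1, nrow(b)) else b$visible_frac
  at_edge <- b$xmin <= 0 | b$ymin <= 0 | b$xmax >= W | b$ymax >= H
  keep <- !(occl > occlusion_max) & !(at_edge & vis < edge_min_area)
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  methods::initialize(img, boxes = out)
}

# ---- manifests ------------------------------------------------------------

#' Write a dataset manifest as JSON-lines
#' @param manifest data.frame with at least path, class, split columns.
#' @param path output file.
#' @export
writeManifest <- function(manifest, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(manifest, con, verbose = FALSE)
  invisible(path)
}

#' Read a JSON-lines dataset manifest
#' @param path manifest file.
#' @export
readManifest <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  jsonlite::stream_in(con, verbose = FALSE)
}

#' Read a class list (plain text, one label per line, or a YAML file with a
#' `names` entry)
#' @param path file path.
#' @export
readClassList <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$names)) as.character(y$names) else as.character(unlist(y))
  } else {
    readLines(path, warn = FALSE)
  }
}

# largest-remainder apportionment of n items to fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Partitions a manifest into disjoint splits whose per-class sizes follow
#' the requested fractions to within one image (largest-remainder rounding
#' per class).
#'
#' @param manifest data.frame with a `class` column.
#' @param fractions numeric length 3 (train, val, test) summing to 1.
#' @param seed integer seed.
#' @return named list of three manifests (train, val, test) with `split`
#'   tags rewritten.
#' @export
splitDataset <- function(manifest, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  names(fractions) <- c("train", "val", "test")
  if (nrow(manifest) == 0) {
    if (any(fractions > 0)) warning("empty manifest with nonzero fractions")
    return(list(train = manifest, val = manifest, test = manifest))
  }
  assigned <- rep(NA_character_, nrow(manifest))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(manifest$class)) {
      idx <- which(manifest$class == cls)
      idx <- idx[sample.int(length(idx))]
      sizes <- apportion(length(idx), fractions)
      lab <- rep(names(fractions), times = sizes)
      assigned[idx] <- lab
    }
  })
  out <- lapply(names(fractions), function(s) {
    m <- manifest[assigned == s, , drop = FALSE]
    if (nrow(m) > 0) m$split <- s
    rownames(m) <- NULL
    m
  })
  names(out) <- names(fractions)
  out
}
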