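#' @import methods
NULL

# Box tables ----------------------------------------------------------------
#
# Ground-truth and detection boxes travel as data.frames with a fixed schema.
# Coordinates are 0-based half-open pixel intervals [xmin, xmax) x
# [ymin, ymax) in array coordinates (x = column, y = row); the VOC XML writer
# converts to the 1-based inclusive LabelImg dialect on disk.

#' Construct a bounding-box table
#'
#' @param label character vector of class labels.
#' @param xmin,ymin,xmax,ymax numeric pixel coordinates (0-based, half-open).
#' @param occlusion fraction of each target occluded by foreground clutter
#'   (known exactly for synthetic scenes; 0 when unknown).
#' @param visible_frac fraction of the full target extent that lies inside
#'   the image (below 1 only for border-clipped targets).
#' @param difficult logical difficulty flag (VOC convention).
#' @param confidence optional detection confidence in [0, 1].
#' @return a data.frame with one row per box.
#' @export
boxTable <- function(label = character(), xmin = numeric(), ymin = numeric(),
                     xmax = numeric(), ymax = numeric(),
                     occlusion = 0, visible_frac = 1, difficult = FALSE,
                     confidence = NULL) {
  n <- length(xmin)
  df <- data.frame(
    label = as.character(label),
    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
    xmax = as.numeric(xmax), ymax = as.numeric(ymax),
    occlusion = rep_len(as.numeric(occlusion), n),
    visible_frac = rep_len(as.numeric(visible_frac), n),
    difficult = rep_len(as.logical(difficult), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(confidence)) df$confidence <- rep_len(as.numeric(confidence), n)
  df
}

validate_boxes <- function(boxes, width = NULL, height = NULL) {
  req <- c("label", "xmin", "ymin", "xmax", "ymax")
  if (!all(req %in% names(boxes))) {
    return(sprintf("box table must have columns %s", paste(req, collapse = ", ")))
  }
  if (nrow(boxes) == 0) return(TRUE)
  if (any(boxes$xmin >= boxes$xmax) || any(boxes$ymin >= boxes$ymax)) {
    return("boxes must satisfy xmin < xmax and ymin < ymax")
  }
  if (!is.null(width) &&
      (any(boxes$xmin < 0) || any(boxes$xmax > width) ||
       any(boxes$ymin < 0) || any(boxes$ymax > height))) {
    return("boxes must lie within the image extent")
  }
  TRUE
}

# LabeledImage ---------------------------------------------------------------

#' An image raster with its ground-truth boxes
#'
#' @slot image numeric H x W x 3 array in [0, 1], or NULL when only the
#'   annotation is loaded.
#' @slot boxes bounding-box table (see [boxTable()]).
#' @slot sourcePath path of the image/annotation on disk ("" if in-memory).
#' @slot size integer (height, width); authoritative when image is NULL.
#' @export
setClass("LabeledImage", representation(
  image = "ANY", boxes = "data.frame", sourcePath = "character",
  size = "integer"
), validity = function(object) {
  if (!is.null(object@image)) {
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L) return("image must be H x W x 3")
    if (!all(d[1:2] == object@size)) return("size must match image dims")
  }
  validate_boxes(object@boxes, width = object@size[2], height = object@size[1])
})

#' Create a LabeledImage
#' @param image H x W x 3 array in [0,1] (or NULL).
#' @param boxes a [boxTable()].
#' @param sourcePath optional origin path.
#' @param size integer (height, width); taken from `image` when present.
#' @return a [LabeledImage-class] object.
#' @export
labeledImage <- function(image, boxes = boxTable(), sourcePath = "",
                         size = NULL) {
  if (is.null(size)) {
    stopifnot(!is.null(image))
    size <- dim(image)[1:2]
  }
  new("LabeledImage", image = image, boxes = boxes,
      sourcePath = sourcePath, size = as.integer(size))
}

#' @describeIn LabeledImage image raster accessor
#' @param x a LabeledImage.
#' @export
imageData <- function(x) x@image

#' @describeIn LabeledImage ground-truth box table accessor
#' @export
boxes <- function(x) x@boxes

setMethod("show", "LabeledImage", function(object) {
  cat(sprintf("LabeledImage %dx%d, %d box(es)%s\n",
              object@size[1], object@size[2], nrow(object@boxes),
              if (nzchar(object@sourcePath)) paste0(" [", object@sourcePath, "]") else ""))
  if (nrow(object@boxes) > 0) {
    print(utils::head(object@boxes, 5))
    if (nrow(object@boxes) > 5) cat("...\n")
  }
})

# FeatureMap -----------------------------------------------------------------

#' A C x H x W activation array with its downsampling stride
#' @slot values numeric C x H x W array.
#' @slot stride integer downsampling factor relative to the input image.
#' @export
setClass("FeatureMap", representation(values = "array", stride = "integer"),
         validity = function(object) {
           d <- dim(object@values)
           if (length(d) != 3L || any(d < 1L)) return("values must be C x H x W with positive dims")
           if (!all(is.finite(object@values))) return("values must be finite")
           if (object@stride < 1L) return("stride must be >= 1")
           TRUE
         })

#' Create a FeatureMap
#' @param values C x H x W numeric array.
#' @param stride downsampling factor.
#' @export
featureMap <- function(values, stride = 1L) {
  new("FeatureMap", values = values, stride = as.integer(stride))
}

setMethod("show", "FeatureMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureMap C=%d H=%d W=%d (stride %d)\n", d[1], d[2], d[3], object@stride))
})

#' @describeIn FeatureMap raw array accessor
#' @param x a FeatureMap.
#' @export
featureValues <- function(x) x@values

# DetectionSet ---------------------------------------------------------------

#' Decoded, NMS-filtered detections for one image
#' @slot detections box table with a confidence column, sorted by
#'   confidence descending.
#' @slot size integer (height, width) of the source image.
#' @export
setClass("DetectionSet", representation(detections = "data.frame", size = "integer"),
         validity = function(object) {
           d <- object@detections
           if (nrow(d) == 0) return(TRUE)
           if (!"confidence" %in% names(d)) return("detections need a confidence column")
           if (any(d$confidence < 0 | d$confidence > 1)) return("confidence must be in [0, 1]")
           if (is.unsorted(rev(d$confidence))) return("detections must be sorted by confidence descending")
           validate_boxes(d)
         })

#' Create a DetectionSet
#' @param detections box table with confidence column.
#' @param size integer (height, width).
#' @export
detectionSet <- function(detections, size) {
  if (nrow(detections) > 0) {
    detections <- detections[order(-detections$confidence), , drop = FALSE]
    rownames(detections) <- NULL
  }
  new("DetectionSet", detections = detections, size = as.integer(size))
}

#' @describeIn DetectionSet detection table accessor
#' @param x a DetectionSet.
#' @export
detections <- function(x) x@detections

setMethod("show", "DetectionSet", function(object) {
  cat(sprintf("DetectionSet: %d detection(s) on a %dx%d image\n",
              nrow(object@detections), object@size[1], object@size[2]))
  if (nrow(object@detections) > 0) print(utils::head(object@detections, 5))
})

# EvalResult -----------------------------------------------------------------

#' Detection evaluation result at one IoU threshold
#' @slot perClass data.frame: class, n_gt, tp, fp, fn, precision, recall,
#'   ap, f1.
#' @slot mAP unweighted mean of per-class APs (classes with >= 1 GT).
#' @slot iouThreshold matching threshold used.
#' @slot confThreshold operating confidence threshold for P/R/F1.
#' @export
setClass("EvalResult", representation(
  perClass = "data.frame", mAP = "numeric", iouThreshold = "numeric",
  confThreshold = "numeric"
), validity = function(object) {
  m <- c(object@mAP, object@perClass$ap, object@perClass$precision,
         object@perClass$recall)
  m <- m[!is.na(m)]
  if (length(m) && (any(m < -1e-12) || any(m > 1 + 1e-12))) {
    return("metrics must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult @ IoU %.2f (conf %.2f): mAP = %.4f over %d class(es)\n",
              object@iouThreshold, object@confThreshold, object@mAP,
              nrow(object@perClass)))
  print(object@perClass)
})

#' @describeIn EvalResult per-class metric table
#' @param x an EvalResult.
#' @export
perClassMetrics <- function(x) x@perClass

#' @describeIn EvalResult mean average precision
#' @export
meanAP <- function(x) x@mAP
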