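# Instance stage: the pipeline's first stage produces one binary mask per
# animal. A classical stand-in segmenter (intensity threshold + distance
# transform watershed) serves synthetic scenes; masks predicted by any real
# instance segmentation model can be fed in through COCO-style JSON.

#' Stand-in segmenter settings
#'
#' @param threshold absolute-deviation threshold on the grey image; `NULL`
#'   selects it by Otsu's method.
#' @param min_area_frac components smaller than this fraction of the image
#'   area are discarded (speckle filter).
#' @param ws_tolerance watershed tolerance (minimum object-height separation
#'   in the distance map before two catchment basins are split).
#' @return list of settings.
#' @export
segmenter_params <- function(threshold = NULL, min_area_frac = 1e-4,
                             ws_tolerance = 1.5) {
  list(threshold = threshold, min_area_frac = min_area_frac,
       ws_tolerance = ws_tolerance)
}

new_detection_result <- function(masks, scores) {
  boxes <- if (length(masks))
    do.call(rbind, lapply(masks, mask_bbox)) else
    matrix(integer(0), 0, 4)
  colnames(boxes) <- c("r0", "c0", "r1", "c1")
  structure(list(masks = masks, scores = as.numeric(scores), boxes = boxes),
            class = "shrimp_detections")
}

#' @export
print.shrimp_detections <- function(x, ...) {
  cat(sprintf("<shrimp_detections> %d masks\n", length(x$masks)))
  invisible(x)
}

#' Segment instances with the classical stand-in
#'
#' Foreground is taken where the grey image deviates from the background
#' (the image-wide median) by more than a threshold; touching bodies are
#' split by a distance-transform watershed; small components are removed.
#' Scores are normalized component areas and are not calibrated confidences.
#' An empty result (no instances) is a valid return.
#'
#' @param image H x W x 3 array (values in `[0, 1]` or 8-bit).
#' @param params a [segmenter_params()] list.
#' @return `shrimp_detections`: `masks` (list of binary matrices), `scores`,
#'   and tight 0-based half-open `boxes` (r0, c0, r1, c1).
#' @export
segment_instances <- function(image, params = segmenter_params()) {
  assert_image(image)
  image <- normalize01(image)
  grey <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  dev <- abs(grey - median(grey))
  thr <- params$threshold %||% EBImage::otsu(EBImage::Image(dev),
                                             range = c(0, max(dev, 1e-8)))
  fg <- dev > thr
  if (!any(fg)) return(new_detection_result(list(), numeric(0)))
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  lab <- EBImage::watershed(dm, tolerance = params$ws_tolerance, ext = 1)
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  if (n == 0) return(new_detection_result(list(), numeric(0)))
  min_area <- params$min_area_frac * length(grey)
  masks <- list()
  for (k in seq_len(n)) {
    m <- matrix(0L, nrow(grey), ncol(grey))
    m[lab == k] <- 1L
    if (sum(m) >= min_area) masks[[length(masks) + 1]] <- m
  }
  if (!length(masks)) return(new_detection_result(list(), numeric(0)))
  areas <- vapply(masks, sum, 1)
  new_detection_result(masks, areas / max(areas))
}

#' Load externally predicted masks
#'
#' Reads a COCO-style annotation/prediction file (the integration point for a
#' real instance segmentation model) and decodes polygon/RLE segmentations to
#' binary masks. Records without a `score` field get score 1.0.
#'
#' @param path COCO JSON file.
#' @param image_id optional image id (default: first image record).
#' @return `shrimp_detections`.
#' @export
load_external_masks <- function(path, image_id = NULL) {
  cc <- read_coco(path, image_id)
  new_detection_result(cc$masks, cc$scores)
}
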