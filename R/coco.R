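# COCO-style mask I/O: uncompressed RLE (column-major counts, starting with
# the number of leading zeros) and polygon segmentations, scene export/import
# with a centerline sidecar JSON.

#' Encode a binary mask as COCO uncompressed RLE
#'
#' Counts runs of the column-major (Fortran-order) flattened mask, starting
#' with the zero run (possibly of length 0).
#'
#' @param mask binary matrix.
#' @return integer vector of run counts.
#' @export
rle_encode_mask <- function(mask) {
  assert_mask(mask)
  v <- as.integer(as.vector(mask))
  r <- rle(v)
  counts <- r$lengths
  if (length(v) == 0) return(integer(0))
  if (r$values[1] != 0) counts <- c(0L, counts)
  as.integer(counts)
}

#' Decode COCO uncompressed RLE to a binary mask
#'
#' @param counts integer run counts (first run is zeros).
#' @param h,w mask dimensions.
#' @return binary integer matrix.
#' @export
rle_decode_mask <- function(counts, h, w) {
  counts <- as.integer(counts)
  if (sum(counts) != h * w)
    stop(sprintf("RLE counts sum to %d, expected %d", sum(counts), h * w))
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  matrix(vals, nrow = h, ncol = w)
}

# Rasterize one COCO polygon ([x1, y1, x2, y2, ...], x = column, y = row,
# origin at the top-left image corner) with the even-odd rule evaluated at
# pixel centres (x = c - 0.5, y = r - 0.5 for 1-based (r, c)).
polygon_to_mask <- function(xy, h, w) {
  xy <- as.numeric(xy)
  if (length(xy) < 6 || length(xy) %% 2 != 0)
    stop("polygon must hold >= 3 (x, y) pairs")
  px <- xy[seq(1, length(xy), 2)]
  py <- xy[seq(2, length(xy), 2)]
  n <- length(px)
  m <- matrix(0L, h, w)
  yc <- seq_len(h) - 0.5
  for (r in seq_len(h)) {
    y <- yc[r]
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((py[i] > y) != (py[j] > y)) {
        xs <- c(xs, px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i]))
      }
      j <- i
    }
    if (length(xs)) {
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        c0 <- ceiling(xs[k] + 0.5)
        c1 <- floor(xs[k + 1] + 0.5)
        if (c1 >= c0) m[r, max(1, c0):min(w, c1)] <- 1L
      }
    }
  }
  m
}

decode_segmentation <- function(seg, h, w) {
  if (is.list(seg) && !is.null(seg$counts)) {
    sz <- as.integer(unlist(seg$size))
    if (length(sz) == 2 && (sz[1] != h || sz[2] != w))
      stop("RLE size does not match declared image size")
    return(rle_decode_mask(unlist(seg$counts), h, w))
  }
  # polygon dialect: list of coordinate vectors, union of parts
  polys <- if (is.list(seg)) seg else list(seg)
  m <- matrix(0L, h, w)
  for (p in polys) m <- pmax(m, polygon_to_mask(unlist(p), h, w))
  m
}

#' Write masks to a COCO-style annotation file
#'
#' One image record plus one annotation per mask, with uncompressed RLE
#' segmentations, area, tight bbox (`[x, y, width, height]`) and optional
#' scores.
#'
#' @param masks list of binary matrices (all H x W).
#' @param path output JSON path.
#' @param scores optional numeric vector of confidences.
#' @param image_id,file_name image record fields.
#' @return `path`, invisibly.
#' @export
write_coco <- function(masks, path, scores = NULL, image_id = 1L,
                       file_name = "scene.png") {
  stopifnot(length(masks) >= 0)
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  anns <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    bb <- mask_bbox(m)  # (r0, c0, r1, c1) 0-based half-open
    a <- list(id = i, image_id = image_id, category_id = 1L,
              segmentation = list(size = c(h, w),
                                  counts = rle_encode_mask(m)),
              area = sum(m),
              bbox = c(bb[2], bb[1], bb[4] - bb[2], bb[3] - bb[1]),
              iscrowd = 0L)
    if (!is.null(scores)) a$score <- scores[i]
    a
  })
  obj <- list(
    images = list(list(id = image_id, file_name = file_name,
                       height = h, width = w)),
    annotations = anns,
    categories = list(list(id = 1L, name = "shrimp")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO-style annotation/prediction file
#'
#' Decodes polygon or uncompressed-RLE segmentations to binary masks.
#'
#' @param path JSON file.
#' @param image_id restrict to one image id (default: the first image record).
#' @return list with `masks`, `scores` (1.0 where absent) and `image`
#'   (the image record).
#' @export
read_coco <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path)
  if (is.null(obj$images) || is.null(obj$annotations))
    stop("malformed COCO file (missing images/annotations): ", path)
  imgs <- obj$images
  ids <- vapply(imgs, function(i) as.integer(i$id), 1L)
  if (is.null(image_id)) image_id <- ids[1]
  img <- imgs[[match(image_id, ids)]]
  h <- as.integer(img$height); w <- as.integer(img$width)
  anns <- Filter(function(a) as.integer(a$image_id) == image_id,
                 obj$annotations)
  masks <- lapply(anns, function(a) decode_segmentation(a$segmentation, h, w))
  scores <- vapply(anns, function(a)
    if (is.null(a$score)) 1.0 else as.numeric(a$score), 1.0)
  list(masks = masks, scores = scores, image = img)
}

#' Export a scene to disk
#'
#' Writes the image as an 8-bit PNG, the instance masks as a COCO-style JSON
#' (uncompressed RLE) and the centerline ground truth as a sidecar JSON with
#' one record `{instance_id, polyline, length_px, length_mm}` per instance.
#' [import_scene()] reproduces the masks bit-identically.
#'
#' @param scene a `shrimp_scene`.
#' @param dir writable output directory (created if missing).
#' @param stem file-name stem.
#' @return manifest list with the written paths.
#' @export
export_scene <- function(scene, dir, stem = "scene") {
  stopifnot(inherits(scene, "shrimp_scene"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  img_path <- file.path(dir, paste0(stem, ".png"))
  coco_path <- file.path(dir, paste0(stem, "_coco.json"))
  side_path <- file.path(dir, paste0(stem, "_centerlines.json"))
  ok <- tryCatch({
    png::writePNG(scene$image, img_path)
    TRUE
  }, error = function(e) stop("failed writing ", img_path, ": ",
                              conditionMessage(e)))
  write_coco(lapply(scene$instances, `[[`, "mask"), coco_path,
             file_name = basename(img_path))
  side <- lapply(scene$instances, function(i) list(
    instance_id = i$id,
    polyline = unname(apply(i$centerline_polyline, 1, function(p) c(p[1], p[2]),
                            simplify = FALSE)),
    length_px = i$true_length_px,
    length_mm = i$true_length_mm))
  jsonlite::write_json(list(mm_per_px = scene$config$mm_per_px,
                            instances = side),
                       side_path, auto_unbox = TRUE, digits = NA)
  list(image = img_path, coco = coco_path, centerlines = side_path)
}

#' Import a scene written by [export_scene()]
#'
#' @param dir directory holding the exported files.
#' @param stem file-name stem used at export time.
#' @return list with `image`, `masks`, `polylines`, `lengths_px`,
#'   `lengths_mm`, `mm_per_px`.
#' @export
import_scene <- function(dir, stem = "scene") {
  img_path <- file.path(dir, paste0(stem, ".png"))
  if (!file.exists(img_path)) stop("no such file: ", img_path)
  image <- png::readPNG(img_path)
  cc <- read_coco(file.path(dir, paste0(stem, "_coco.json")))
  side <- jsonlite::read_json(file.path(dir, paste0(stem,
                                                    "_centerlines.json")))
  polylines <- lapply(side$instances, function(i)
    do.call(rbind, lapply(i$polyline, function(p) as.numeric(unlist(p)))))
  list(image = image,
       masks = cc$masks,
       polylines = polylines,
       lengths_px = vapply(side$instances, function(i)
         as.numeric(i$length_px), 1.0),
       lengths_mm = vapply(side$instances, function(i)
         as.numeric(i$length_mm), 1.0),
       mm_per_px = as.numeric(side$mm_per_px))
}
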