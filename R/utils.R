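# Shared internal helpers. Coordinates are 1-based (row, col) throughout the
# R API; masks are integer {0,1} matrices; polylines are n x 2 matrices of
# floating-point (row, col) pairs ordered head to tail.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("'%s' must be a matrix", arg))
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1))) stop(sprintf("'%s' must be binary {0,1}", arg))
  invisible(TRUE)
}

assert_image <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L))
    stop("'image' must be an H x W x 3 array")
  invisible(TRUE)
}

# Scale an 8-bit image to [0,1] if needed.
normalize01 <- function(image) {
  if (max(image) > 1) image / 255 else image
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Arc length of a polyline
#'
#' Sum of Euclidean distances between consecutive points of an ordered
#' `(row, col)` polyline.
#'
#' @param polyline numeric matrix with two columns (row, col).
#' @return numeric scalar, length in pixels (0 for a single point).
#' @export
polyline_length <- function(polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) return(0)
  d <- diff(polyline)
  sum(sqrt(rowSums(d^2)))
}

# Resample a polyline at (approximately) fixed arc-length steps; keeps the
# endpoints exactly.
resample_polyline <- function(polyline, step = 0.4) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) return(polyline)
  d <- sqrt(rowSums(diff(polyline)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total == 0) return(polyline[1, , drop = FALSE])
  n <- max(2L, ceiling(total / step) + 1L)
  at <- seq(0, total, length.out = n)
  cbind(approx_at(s, polyline[, 1], at), approx_at(s, polyline[, 2], at))
}

approx_at <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, ties = "ordered")$y
}

#' Rasterize a polyline to an 8-connected one-pixel curve
#'
#' The polyline is densely resampled, points are rounded to the pixel grid and
#' consecutive duplicates dropped, producing an 8-connected chain of pixels.
#'
#' @param polyline numeric matrix of (row, col) points.
#' @param shape integer vector `c(H, W)`.
#' @return binary H x W matrix.
#' @export
rasterize_polyline <- function(polyline, shape) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) == 0) stop("empty polyline")
  pts <- resample_polyline(polyline, step = 0.4)
  rc <- round(pts)
  rc[, 1] <- clamp(rc[, 1], 1, shape[1])
  rc[, 2] <- clamp(rc[, 2], 1, shape[2])
  m <- matrix(0L, shape[1], shape[2])
  m[cbind(rc[, 1], rc[, 2])] <- 1L
  m
}

# Intersection-over-union of two binary masks.
mask_iou <- function(a, b) {
  i <- sum(a & b)
  u <- sum(a | b)
  if (u == 0) return(0)
  i / u
}

# Tight bounding box of a mask as 0-based half-open (r0, c0, r1, c1).
mask_bbox <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (nrow(w) == 0) return(c(0L, 0L, 0L, 0L))
  c(min(w[, 1]) - 1L, min(w[, 2]) - 1L, max(w[, 1]), max(w[, 2]))
}

# Reflect-pad an (H, W, C) array on the bottom/right to the target dims.
pad_reflect <- function(x, H2, W2) {
  d <- dim(x)
  if (d[1] == H2 && d[2] == W2) return(x)
  ri <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(H2)]
  ci <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(W2)]
  x[ri, ci, , drop = FALSE]
}
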