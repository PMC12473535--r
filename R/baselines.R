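# Comparative centerline extractors: polynomial curve fitting after moment
# alignment (PCFM), a Voronoi-type medial axis with longest-path burr pruning
# (VDBM), and the plain morphological skeleton. All three are measured through
# the same thinning/arc-length/calibration code path as the learned method;
# only the centerline source differs.

#' PCFM settings
#'
#' @param degree polynomial order (>= 1; the classic choice is 3).
#' @param n_samples points sampled along the fitted curve (>= 2).
#' @return list of settings.
#' @export
pcfm_config <- function(degree = 3L, n_samples = 200L) {
  if (degree < 1 || n_samples < 2) stop("invalid PCFM configuration")
  list(degree = as.integer(degree), n_samples = as.integer(n_samples))
}

#' Polynomial curve-fitting centerline (PCFM)
#'
#' Rotates the mask pixel coordinates so the principal axis (from
#' second-order central image moments,
#' `theta = atan2(2*mu11, mu20 - mu02) / 2`) is horizontal, fits a
#' least-squares polynomial of the configured degree to the aligned
#' coordinates, samples it across the mask's extent, rotates back and clips
#' the sampled polyline to the mask support. Fails by construction on bodies
#' whose centerline is not a function of the aligned abscissa (S shapes).
#'
#' @param mask non-empty single-component binary mask.
#' @param cfg a [pcfm_config()].
#' @return list with `polyline` (the fitted curve clipped to the mask
#'   support, used for the length), `curve` (the full sampled fitted curve,
#'   before clipping), `length_px`, `method`.
#' @export
pcfm_centerline <- function(mask, cfg = pcfm_config()) {
  assert_mask(mask)
  px <- which(mask != 0, arr.ind = TRUE)
  if (nrow(px) < cfg$degree + 1)
    stop("mask has fewer pixels than degree + 1")
  y <- px[, 1]; x <- px[, 2]
  xb <- mean(x); yb <- mean(y)
  mu20 <- mean((x - xb)^2); mu02 <- mean((y - yb)^2)
  mu11 <- mean((x - xb) * (y - yb))
  theta <- if (mu20 == mu02 && mu11 == 0) 0 else
    0.5 * atan2(2 * mu11, mu20 - mu02)
  ct <- cos(theta); st <- sin(theta)
  u <- ct * (x - xb) + st * (y - yb)
  v <- -st * (x - xb) + ct * (y - yb)
  X <- outer(u, 0:cfg$degree, `^`)
  beta <- qr.solve(X, v)
  us <- seq(min(u), max(u), length.out = cfg$n_samples)
  vs <- drop(outer(us, 0:cfg$degree, `^`) %*% beta)
  rr <- yb + st * us + ct * vs
  cc <- xb + ct * us - st * vs
  inside <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  inside[inside] <- mask[cbind(round(rr[inside]), round(cc[inside]))] == 1
  # longest contiguous run of samples supported by the mask
  runs <- rle(inside)
  if (!any(runs$values)) stop("fitted curve misses the mask entirely")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  k <- which(runs$values)[which.max(runs$lengths[runs$values])]
  keep <- starts[k]:ends[k]
  polyline <- cbind(rr[keep], cc[keep])
  list(polyline = polyline, curve = cbind(rr, cc),
       length_px = polyline_length(polyline), method = "pcfm")
}

#' Medial-axis centerline with longest-path pruning (VDBM)
#'
#' Realizes the boundary-Voronoi medial axis through its distance-transform
#' formulation on the raster: every foreground pixel stores its nearest
#' boundary point (feature transform); pixels where the feature point jumps
#' discontinuously between 4-neighbours lie on the medial axis (they are
#' centres of maximal disks touching two distinct boundary arcs). The medial
#' set is thinned to one pixel and pruned to the longest
#' endpoint-to-endpoint geodesic path. On a capsule the medial axis falls
#' short of each tip by the cap radius, the characteristic head/tail
#' shortening of this family of methods; boundary noise produces spurious
#' branches ("burrs") which the pruning removes.
#'
#' @param mask non-empty single-component binary mask.
#' @return list with `skeleton` (pruned `shrimp_skeleton`), `polyline`,
#'   `medial_mask` (unpruned medial set), `length_px`, `method`.
#' @export
vdbm_centerline <- function(mask) {
  assert_mask(mask)
  if (sum(mask) == 0) stop("empty mask")
  storage.mode(mask) <- "integer"
  ft <- cpp_nearest_bg(mask)
  H <- nrow(mask); W <- ncol(mask)
  D <- ft$dist
  # object-angle criterion: p lies on the medial axis when its own nearest
  # boundary point and a neighbour's subtend an angle > 90 degrees at p --
  # the disk at p touches two opposing boundary arcs (the separation angle
  # of the boundary-Voronoi construction). Vectorized over the 8 offsets.
  medial <- matrix(0L, H, W)
  ar <- ft$fr - row(ft$fr)  # vector from p to its feature point
  ac <- ft$fc - col(ft$fc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- max(1, 1 - dr):min(H, H - dr)
    c1 <- max(1, 1 - dc):min(W, W - dc)
    r2 <- r1 + dr; c2 <- c1 + dc
    # vector from p to the neighbour's feature point
    br <- ft$fr[r2, c2, drop = FALSE] - r1
    bc <- ft$fc[r2, c2, drop = FALSE] -
      matrix(c1, length(r1), length(c1), byrow = TRUE)
    dot <- ar[r1, c1, drop = FALSE] * br + ac[r1, c1, drop = FALSE] * bc
    # the two feature points must come from distinct boundary arcs: their
    # separation must be of the order of the disk diameter (the lambda
    # filter of medial-axis extraction), not a one-pixel boundary jag
    jump <- (ft$fr[r1, c1, drop = FALSE] - ft$fr[r2, c2, drop = FALSE])^2 +
            (ft$fc[r1, c1, drop = FALSE] - ft$fc[r2, c2, drop = FALSE])^2
    sep <- pmax(2.5, 0.55 * (D[r1, c1, drop = FALSE] + D[r2, c2, drop = FALSE]))
    hit <- mask[r1, c1, drop = FALSE] == 1 &
      mask[r2, c2, drop = FALSE] == 1 & dot < 0 & jump > sep^2
    sub <- medial[r1, c1, drop = FALSE]; sub[hit] <- 1L
    medial[r1, c1] <- sub
  }
  if (sum(medial) == 0) {
    # radially symmetric shapes: degenerate axis at the deepest point
    dmax <- which(D == max(D), arr.ind = TRUE)[1, , drop = FALSE]
    medial[dmax] <- 1L
  }
  path <- skeleton_to_path(zhang_suen_thin(medial))
  list(skeleton = path, polyline = path$pixels, medial_mask = medial,
       length_px = arc_length_px(path), method = "vdbm")
}

#' Morphological-skeleton centerline
#'
#' Zhang-Suen thinning of the full body mask (not a learned band) followed by
#' the same longest-path pruning as every other route.
#'
#' @param mask non-empty binary mask.
#' @return list with `skeleton`, `polyline`, `length_px`, `method`.
#' @export
morph_skeleton_centerline <- function(mask) {
  assert_mask(mask)
  if (sum(mask) == 0) stop("empty mask")
  path <- skeleton_to_path(zhang_suen_thin(mask))
  list(skeleton = path, polyline = path$pixels,
       length_px = arc_length_px(path), method = "morph")
}

# Maximum deviation of an extracted centerline from the true polyline:
# max over extracted points of the distance to the (densely resampled) truth.
centerline_deviation <- function(polyline, truth) {
  truth <- resample_polyline(truth, step = 0.25)
  max(vapply(seq_len(nrow(polyline)), function(i) {
    min(sqrt((truth[, 1] - polyline[i, 1])^2 +
             (truth[, 2] - polyline[i, 2])^2))
  }, 1.0))
}
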