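# Synthetic scene generator. Emulates top-down container scenes of curved,
# translucent, elongated bodies with exact per-instance ground truth (mask,
# sub-pixel centerline polyline, arc length), so that every downstream stage
# is testable without any external dataset.

#' Scene configuration
#'
#' Defaults emulate the study conditions: a 480 x 848 top-down view of a
#' container holding 10-18 animals of 4-11 cm equivalent length, imaged at a
#' fixed height (about 0.5 mm per pixel).
#'
#' @param image_height,image_width scene size in pixels.
#' @param n_instances number of bodies (>= 1).
#' @param body_length_range_mm min/max true body (centerline) length in mm.
#' @param body_width_px_range min/max maximum body width in pixels.
#' @param curvature_range dimensionless spline-bend parameter range; 0 gives a
#'   straight body, values around 0.3 give strongly curved ones.
#' @param mm_per_px calibration scalar (> 0).
#' @param allow_overlap if `FALSE`, bodies are placed without mask overlap
#'   (placement fails with an error after a bounded number of attempts).
#' @param background_style `"plain"` or `"textured"`.
#' @param noise_sigma additive Gaussian pixel noise, in 8-bit intensity units.
#' @param occlusion_mode `"amodal"` (each stored mask is the full, unoccluded
#'   body mask) or `"visible"` (pixels covered by later-drawn bodies are
#'   removed; such masks may be split by the occluder).
#' @param seed integer seed; scenes are bit-reproducible for a fixed config.
#' @return object of class `shrimp_scene_config`.
#' @export
scene_config <- function(image_height = 480L, image_width = 848L,
                         n_instances = 12L,
                         body_length_range_mm = c(40, 110),
                         body_width_px_range = c(5, 11),
                         curvature_range = c(0.05, 0.3),
                         mm_per_px = 0.5,
                         allow_overlap = FALSE,
                         background_style = c("plain", "textured"),
                         noise_sigma = 2,
                         occlusion_mode = c("amodal", "visible"),
                         seed = 1L) {
  background_style <- match.arg(background_style)
  occlusion_mode <- match.arg(occlusion_mode)
  if (n_instances < 1) stop("'n_instances' must be >= 1")
  if (mm_per_px <= 0) stop("'mm_per_px' must be > 0")
  if (length(curvature_range) == 1) curvature_range <- rep(curvature_range, 2)
  stopifnot(length(body_length_range_mm) == 2,
            diff(body_length_range_mm) >= 0,
            length(body_width_px_range) == 2,
            body_width_px_range[1] >= 2,
            curvature_range[1] >= 0,
            noise_sigma >= 0)
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_instances = as.integer(n_instances),
                 body_length_range_mm = as.numeric(body_length_range_mm),
                 body_width_px_range = as.numeric(body_width_px_range),
                 curvature_range = as.numeric(curvature_range),
                 mm_per_px = as.numeric(mm_per_px),
                 allow_overlap = isTRUE(allow_overlap),
                 background_style = background_style,
                 noise_sigma = as.numeric(noise_sigma),
                 occlusion_mode = occlusion_mode,
                 seed = as.integer(seed)),
            class = "shrimp_scene_config")
}

# Geometric validity of a centerline for a body of width `width`: the spine
# of a real animal cannot bend tighter than about its own width (the flank
# would fold into itself), and two stretches far apart along the body cannot
# come closer than the body width (the body would self-overlap). Checked on
# a fixed-step resampling; the bend radius is the circumradius of
# consecutive point triplets.
centerline_is_valid <- function(polyline, width) {
  pts <- resample_polyline(polyline, step = 2)
  n <- nrow(pts)
  if (n < 4) return(TRUE)
  a <- pts[1:(n - 2), , drop = FALSE]
  b <- pts[2:(n - 1), , drop = FALSE]
  c_ <- pts[3:n, , drop = FALSE]
  la <- sqrt(rowSums((b - c_)^2))
  lb <- sqrt(rowSums((a - c_)^2))
  lc <- sqrt(rowSums((a - b)^2))
  cross <- (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
           (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1])
  r_bend <- ifelse(abs(cross) < 1e-9, Inf, la * lb * lc / (2 * abs(cross)))
  if (min(r_bend) < width) return(FALSE)
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  dmat <- as.matrix(stats::dist(pts))
  arc <- abs(outer(s, s, `-`))
  clearance <- width + 4
  !any(dmat < clearance & arc > 3 * width)
}

# Random smooth centerline of exact arc length `length_px`, centred at the
# origin. Returns a dense (row, col) polyline.
random_centerline <- function(length_px, curvature) {
  n_ctrl <- sample(4:6, 1)
  theta <- runif(1, 0, pi)
  u <- seq(-0.5, 0.5, length.out = n_ctrl) * length_px
  v <- curvature * length_px * runif(n_ctrl, -1, 1)
  tt <- seq(1, n_ctrl, length.out = 400)
  fu <- stats::splinefun(seq_len(n_ctrl), u, method = "natural")
  fv <- stats::splinefun(seq_len(n_ctrl), v, method = "natural")
  x <- fu(tt); y <- fv(tt)
  # rotate into scene orientation: (row, col)
  r <- sin(theta) * x + cos(theta) * y
  c_ <- cos(theta) * x - sin(theta) * y
  pl <- cbind(r, c_)
  pl <- sweep(pl, 2, colMeans(pl))
  len <- polyline_length(pl)
  if (len <= 0) stop("degenerate centerline")
  pl * (length_px / len)
}

#' Body mask swept along a centerline
#'
#' Renders the body as a disk of varying radius swept along the polyline. The
#' radius profile is `r(t) = r_max * (0.35 + 0.65 * sin(pi * t))`, `t` the
#' arc-length fraction, tapering towards head and tail; `taper = FALSE` uses a
#' constant radius (a capsule when the polyline is straight).
#'
#' @param polyline (row, col) matrix in scene coordinates (1-based pixels).
#' @param width_px maximum body width in pixels (`r_max = width_px / 2`).
#' @param shape `c(H, W)` of the mask.
#' @param taper taper the radius towards the two ends?
#' @return binary integer H x W matrix.
#' @export
body_mask_from_polyline <- function(polyline, width_px, shape, taper = TRUE) {
  pts <- resample_polyline(polyline, step = 0.4)
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  tfrac <- if (max(s) > 0) s / max(s) else rep(0.5, nrow(pts))
  r_max <- width_px / 2
  rad <- if (taper) r_max * (0.35 + 0.65 * sin(pi * tfrac)) else
    rep(r_max, nrow(pts))
  H <- shape[1]; W <- shape[2]
  m <- matrix(0L, H, W)
  for (i in seq_len(nrow(pts))) {
    r0 <- pts[i, 1]; c0 <- pts[i, 2]; rr <- rad[i]
    ri <- max(1, floor(r0 - rr)):min(H, ceiling(r0 + rr))
    ci <- max(1, floor(c0 - rr)):min(W, ceiling(c0 + rr))
    if (length(ri) == 0 || length(ci) == 0) next
    dr2 <- (ri - r0)^2
    dc2 <- (ci - c0)^2
    hit <- outer(dr2, dc2, `+`) <= rr^2
    m[ri, ci][hit] <- 1L
  }
  m
}

#' Capsule mask (rectangle with half-disk caps)
#'
#' Pixels within `radius` of the segment from `p0` to `p1`. The exact medial
#' axis of this shape is the segment itself, shorter than the overall body by
#' twice the cap radius -- a useful closed-form test shape.
#'
#' @param shape `c(H, W)`.
#' @param p0,p1 (row, col) endpoints of the central segment.
#' @param radius cap radius in pixels.
#' @return binary integer matrix.
#' @export
capsule_mask <- function(shape, p0, p1, radius) {
  H <- shape[1]; W <- shape[2]
  rs <- matrix(rep(seq_len(H), W), H, W)
  cs <- matrix(rep(seq_len(W), each = H), H, W)
  v <- c(p1[1] - p0[1], p1[2] - p0[2])
  L2 <- sum(v^2)
  t <- if (L2 > 0) ((rs - p0[1]) * v[1] + (cs - p0[2]) * v[2]) / L2 else 0
  t <- clamp(t, 0, 1)
  d2 <- (rs - (p0[1] + t * v[1]))^2 + (cs - (p0[2] + t * v[2]))^2
  m <- matrix(0L, H, W)
  m[d2 <= radius^2] <- 1L
  m
}

#' Generate a synthetic scene
#'
#' Places `n_instances` curved bodies (cubic-spline centerlines swept with a
#' tapered disk) on a container-like background, renders them
#' semi-translucently (alpha 0.5-0.9), adds Gaussian noise and quantizes to
#' 8 bits. Deterministic for a fixed config (the seed lives in the config).
#'
#' @param config a [scene_config()].
#' @return object of class `shrimp_scene`: list with `image` (H x W x 3 array
#'   in `[0, 1]`, 8-bit quantized), `instances` (list of per-instance truth:
#'   `id`, `mask`, `centerline_polyline`, `true_length_px`, `true_length_mm`)
#'   and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "shrimp_scene_config"))
  set.seed(config$seed)
  H <- config$image_height; W <- config$image_width
  occupancy <- matrix(FALSE, H, W)
  instances <- vector("list", config$n_instances)
  for (k in seq_len(config$n_instances)) {
    placed <- FALSE
    for (attempt in seq_len(300)) {
      len_mm <- runif(1, config$body_length_range_mm[1],
                      config$body_length_range_mm[2])
      len_px <- len_mm / config$mm_per_px
      width <- runif(1, config$body_width_px_range[1],
                     config$body_width_px_range[2])
      curv <- runif(1, config$curvature_range[1], config$curvature_range[2])
      pl0 <- random_centerline(len_px, curv)
      # reject centerlines whose swept body would fold onto itself
      if (!centerline_is_valid(pl0, width)) next
      margin <- width / 2 + 2
      rlo <- 1 + margin - min(pl0[, 1]); rhi <- H - margin - max(pl0[, 1])
      clo <- 1 + margin - min(pl0[, 2]); chi <- W - margin - max(pl0[, 2])
      if (rhi <= rlo || chi <= clo) next  # body does not fit; redraw geometry
      ok <- FALSE
      for (p in seq_len(20)) {
        off <- c(runif(1, rlo, rhi), runif(1, clo, chi))
        pl <- sweep(pl0, 2, -off)
        mask <- body_mask_from_polyline(pl, width, c(H, W), taper = TRUE)
        if (config$allow_overlap || !any(mask & occupancy)) { ok <- TRUE; break }
      }
      if (!ok) next
      occupancy <- occupancy | (mask == 1)
      stored <- resample_polyline(pl, step = 0.5)
      instances[[k]] <- list(
        id = k,
        mask = mask,
        centerline_polyline = stored,
        true_length_px = polyline_length(stored),
        true_length_mm = polyline_length(stored) * config$mm_per_px,
        width_px = width)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(
        "could not place instance %d without overlap after bounded attempts", k))
  }
  image <- render_scene_image(instances, config)
  if (config$occlusion_mode == "visible" && config$n_instances > 1) {
    for (k in seq_len(config$n_instances - 1)) {
      cover <- Reduce(`|`, lapply(instances[(k + 1):config$n_instances],
                                  function(i) i$mask == 1))
      instances[[k]]$mask[cover] <- 0L
    }
  }
  structure(list(image = image, instances = instances, config = config),
            class = "shrimp_scene")
}

render_scene_image <- function(instances, config) {
  H <- config$image_height; W <- config$image_width
  bg <- 0.80
  base <- array(rep(bg, H * W * 3), dim = c(H, W, 3))
  if (config$background_style == "textured") {
    ph <- runif(4, 0, 2 * pi)
    fr <- runif(2, 1.5, 4); fc <- runif(2, 1.5, 4)
    field <- outer(sin(2 * pi * fr[1] * seq_len(H) / H + ph[1]),
                   sin(2 * pi * fc[1] * seq_len(W) / W + ph[2])) +
             outer(sin(2 * pi * fr[2] * seq_len(H) / H + ph[3]),
                   sin(2 * pi * fc[2] * seq_len(W) / W + ph[4]))
    for (ch in 1:3) base[, , ch] <- base[, , ch] + 0.04 * field
  }
  for (inst in instances) {
    # translucency increases towards the tail: the cephalothorax is clearly
    # visible while the rear segments blend into the light container floor
    # (body tone sits close to the background, as for live grey shrimp)
    a_head <- runif(1, 0.75, 0.90)
    a_tail <- runif(1, 0.15, 0.30)
    col <- clamp(c(0.62, 0.58, 0.57) + rnorm(3, 0, 0.03), 0, 1)
    idx <- which(inst$mask == 1, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    # arc-length fraction of the nearest centerline point per mask pixel
    pts <- resample_polyline(inst$centerline_polyline, step = 1)
    s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    tfrac <- if (max(s) > 0) s / max(s) else rep(0.5, nrow(pts))
    near <- vapply(seq_len(nrow(idx)), function(j) {
      which.min((pts[, 1] - idx[j, 1])^2 + (pts[, 2] - idx[j, 2])^2)
    }, 1L)
    alpha <- a_head + (a_tail - a_head) * tfrac[near]
    for (ch in 1:3) {
      plane <- base[, , ch]
      plane[idx] <- (1 - alpha) * plane[idx] + alpha * col[ch]
      base[, , ch] <- plane
    }
  }
  if (config$noise_sigma > 0)
    base <- base + array(rnorm(H * W * 3, 0, config$noise_sigma / 255),
                         dim = c(H, W, 3))
  round(clamp(base, 0, 1) * 255) / 255
}

#' Generate several scenes with derived seeds
#'
#' @param config base [scene_config()]; scene `i` uses seed
#'   `config$seed + i - 1`.
#' @param n_scenes number of scenes.
#' @return list of `shrimp_scene`.
#' @export
generate_scenes <- function(config, n_scenes) {
  lapply(seq_len(n_scenes), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    generate_scene(cfg)
  })
}

#' @export
print.shrimp_scene <- function(x, ...) {
  cat(sprintf("<shrimp_scene> %dx%d, %d instances, %.3g mm/px, seed %d\n",
              x$config$image_height, x$config$image_width,
              length(x$instances), x$config$mm_per_px, x$config$seed))
  invisible(x)
}
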