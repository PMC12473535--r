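# Centerline predictive module: RGB+mask fusion (1x1 conv), a small
# encoder/ASPP/skip-fusion segmentation network, the Dice+BCE composite loss,
# 3-px centerline targets, and seeded momentum-SGD training. Forward and
# backward passes are written out layer by layer over Rcpp/Armadillo
# convolution kernels; no deep-learning framework is involved.

#' Model configuration
#'
#' @param encoder_depth number of 2x downsampling encoder stages (>= 2).
#' @param base_channels channels of the first encoder stage; stage `i` uses
#'   `base_channels * 2^(i-1)`.
#' @param aspp_rates strictly increasing dilation rates of the parallel atrous
#'   convolutions; the first rate must be 1.
#' @param decoder_channels channels per decoder stage (deepest first);
#'   defaults to mirroring the encoder.
#' @param inject_downsampled_input concatenate a downsampled copy of the fused
#'   input with the deepest encoder features before the ASPP?
#' @return object of class `centerline_model_config`.
#' @export
model_config <- function(encoder_depth = 2L, base_channels = 8L,
                         aspp_rates = c(1L, 2L, 4L),
                         decoder_channels = NULL,
                         inject_downsampled_input = TRUE) {
  if (encoder_depth < 2) stop("'encoder_depth' must be >= 2")
  if (aspp_rates[1] != 1 || any(diff(aspp_rates) <= 0))
    stop("'aspp_rates' must be strictly increasing and start at 1")
  enc_ch <- base_channels * 2^(seq_len(encoder_depth) - 1)
  if (is.null(decoder_channels)) decoder_channels <- rev(rev(enc_ch))
  if (length(decoder_channels) != encoder_depth)
    stop("'decoder_channels' must have one entry per encoder stage")
  structure(list(encoder_depth = as.integer(encoder_depth),
                 base_channels = as.integer(base_channels),
                 aspp_rates = as.integer(aspp_rates),
                 decoder_channels = as.integer(decoder_channels),
                 inject_downsampled_input = isTRUE(inject_downsampled_input)),
            class = "centerline_model_config")
}

#' Training configuration
#'
#' Defaults follow the training recipe used for the centerline module:
#' momentum SGD, initial learning rate 0.02, 40 epochs with a multi-step
#' learning-rate schedule.
#'
#' @param epochs training epochs.
#' @param lr initial learning rate (> 0).
#' @param momentum SGD momentum in `[0, 1)`.
#' @param lr_milestones epochs after which the learning rate is multiplied by
#'   `lr_gamma`.
#' @param lr_gamma multiplicative decay factor.
#' @param beta weight of the BCE term in the composite loss (>= 0).
#' @param eps numerical-stability constant shared by the Dice and BCE terms.
#' @param batch_size minibatch size.
#' @param augment apply a random flip/right-angle rotation to each sample in
#'   each epoch (dihedral group; rotations by 90 degrees only for square
#'   inputs)?
#' @param seed one integer controlling weight initialization, data order and
#'   augmentation draws.
#' @return object of class `centerline_train_config`.
#' @export
train_config <- function(epochs = 40L, lr = 0.02, momentum = 0.9,
                         lr_milestones = c(24L, 34L), lr_gamma = 0.1,
                         beta = 1, eps = 1e-6, batch_size = 4L,
                         augment = TRUE, seed = 1L) {
  stopifnot(lr > 0, momentum >= 0, momentum < 1, beta >= 0, eps > 0,
            epochs >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 lr_milestones = as.integer(lr_milestones),
                 lr_gamma = lr_gamma, beta = beta, eps = eps,
                 batch_size = as.integer(batch_size),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "centerline_train_config")
}

# random dihedral transform of one training sample (flips always; the
# transpose element only when the frame is square)
augment_sample <- function(smp) {
  H <- dim(smp$image)[1]; W <- dim(smp$image)[2]
  fliph <- runif(1) < 0.5
  flipv <- runif(1) < 0.5
  tr <- H == W && runif(1) < 0.5
  f3 <- function(x) {
    if (fliph) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    if (flipv) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
    if (tr) x <- aperm(x, c(2, 1, 3))
    x
  }
  f2 <- function(x) {
    if (fliph) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
    if (flipv) x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
    if (tr) x <- t(x)
    x
  }
  list(image = f3(smp$image), mask = f2(smp$mask), target = f2(smp$target))
}

#' Fuse an RGB image with one instance mask
#'
#' The image (scaled to `[0, 1]`) and the binary mask are concatenated along
#' the channel dimension and reduced back to three channels by a 1x1
#' convolution: `out[r, c, k] = b[k] + sum_j W[j, k] * concat[r, c, j]`. The
#' fusion kernel is a learned part of the model.
#'
#' @param image H x W x 3 array.
#' @param mask binary H x W matrix.
#' @param fusion_weights list with `W` (4 x 3 matrix) and `b` (length 3).
#' @return H x W x 3 fused array.
#' @export
fuse_inputs <- function(image, mask, fusion_weights) {
  assert_image(image)
  assert_mask(mask)
  if (!all(dim(mask) == dim(image)[1:2]))
    stop("image and mask spatial dimensions differ")
  image <- normalize01(image)
  d <- dim(image)
  concat <- array(c(image, as.numeric(mask)), dim = c(d[1], d[2], 4L))
  M <- matrix(concat, ncol = 4L)
  out <- M %*% fusion_weights$W
  out <- sweep(out, 2, fusion_weights$b, `+`)
  array(out, dim = c(d[1], d[2], 3L))
}

# ---- layer primitives -------------------------------------------------------

new_conv <- function(cin, cout, k = 3L, dil = 1L, sd = NULL, bias0 = 0) {
  fan_in <- k * k * cin
  sd <- sd %||% sqrt(2 / fan_in)  # He initialization
  list(W = matrix(rnorm(fan_in * cout, 0, sd), fan_in, cout),
       b = rep(bias0, cout), k = as.integer(k), dil = as.integer(dil))
}

conv_fwd <- function(x, ly) {
  y <- cpp_conv2d_fwd(x, ly$W, ly$b, ly$k, ly$dil)
  array(y, dim = c(dim(x)[1], dim(x)[2], ncol(ly$W)))
}

conv_bwd <- function(x, ly, gy) {
  r <- cpp_conv2d_bwd(x, ly$W, matrix(gy, ncol = dim(gy)[3]), ly$k, ly$dil)
  list(gx = array(r$gx, dim = dim(x)), gW = r$gW, gb = as.numeric(r$gb))
}

cat3 <- function(a, b) {
  d <- dim(a)
  array(c(a, b), dim = c(d[1], d[2], d[3] + dim(b)[3]))
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

upsample2_bwd <- function(g) {
  d <- dim(g)
  ro <- seq(1, d[1], 2); re <- seq(2, d[1], 2)
  co <- seq(1, d[2], 2); ce <- seq(2, d[2], 2)
  g[ro, co, , drop = FALSE] + g[re, co, , drop = FALSE] +
    g[ro, ce, , drop = FALSE] + g[re, ce, , drop = FALSE]
}

avgpool_f <- function(x, f) {
  d <- dim(x)
  acc <- 0
  for (i in seq_len(f)) for (j in seq_len(f))
    acc <- acc + x[seq(i, d[1], f), seq(j, d[2], f), , drop = FALSE]
  acc / f^2
}

avgpool_f_bwd <- function(g, f, H, W) {
  d <- dim(g)
  gx <- array(0, dim = c(H, W, d[3]))
  for (i in seq_len(f)) for (j in seq_len(f))
    gx[seq(i, H, f), seq(j, W, f), ] <- g / f^2
  gx
}

# ---- model ------------------------------------------------------------------

#' Initialize a centerline model
#'
#' He-initialized weights for the fusion convolution, encoder, ASPP, decoder
#' and final 1x1 head. The head bias starts negative so that the initial
#' probability map reflects the foreground scarcity of thin-structure targets.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the weight draw.
#' @return object of class `centerline_model` (weights + config).
#' @export
init_centerline_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "centerline_model_config"))
  set.seed(seed)
  d <- config$encoder_depth
  enc_ch <- config$base_channels * 2^(seq_len(d) - 1)
  w <- list()
  w$fuse <- list(W = matrix(rnorm(12, 0, sqrt(2 / 4)), 4, 3), b = rep(0, 3))
  w$enc <- vector("list", d)
  cin <- 3L
  for (i in seq_len(d)) {
    w$enc[[i]] <- list(c1 = new_conv(cin, enc_ch[i]),
                       c2 = new_conv(enc_ch[i], enc_ch[i]))
    cin <- enc_ch[i]
  }
  aspp_in <- enc_ch[d] + if (config$inject_downsampled_input) 3L else 0L
  A <- enc_ch[d]
  w$aspp <- lapply(config$aspp_rates, function(r)
    new_conv(aspp_in, A, k = 3L, dil = r))
  w$aspp_merge <- new_conv(length(config$aspp_rates) * A, A, k = 1L)
  w$dec <- vector("list", d)
  prev <- A
  for (i in rev(seq_len(d))) {  # deepest decoder stage first in forward order
    w$dec[[i]] <- new_conv(prev + enc_ch[i], config$decoder_channels[i])
    prev <- config$decoder_channels[i]
  }
  w$final <- new_conv(prev, 1L, k = 1L, sd = 0.01, bias0 = -2)
  structure(list(config = config, weights = w), class = "centerline_model")
}

#' @export
print.centerline_model <- function(x, ...) {
  np <- sum(rapply(x$weights, length, how = "unlist"))
  cat(sprintf(
    "<centerline_model> depth %d, base %d, ASPP rates {%s}, %d parameters%s\n",
    x$config$encoder_depth, x$config$base_channels,
    paste(x$config$aspp_rates, collapse = ","), np,
    if (is.null(x$history)) " (untrained)" else
      sprintf(", trained %d epochs", length(x$history))))
  invisible(x)
}

# Forward pass on a fused input. Returns the probability map; with
# `keep_cache = TRUE` also every intermediate needed by nn_backward (in that
# case the spatial dims must already be divisible by 2^depth).
nn_forward <- function(model, fused, keep_cache = FALSE) {
  cfg <- model$config
  w <- model$weights
  d <- cfg$encoder_depth
  f <- 2^d
  H <- dim(fused)[1]; W <- dim(fused)[2]
  H2 <- ceiling(H / f) * f; W2 <- ceiling(W / f) * f
  if (keep_cache && (H2 != H || W2 != W))
    stop("training inputs must have dims divisible by 2^encoder_depth")
  xp <- pad_reflect(fused, H2, W2)
  cache <- list(fused_p = xp)
  x <- xp
  skips <- vector("list", d)
  idxs <- vector("list", d)
  enc_in <- vector("list", d)
  enc_mid <- vector("list", d)
  for (i in seq_len(d)) {
    enc_in[[i]] <- x
    y1 <- pmax(conv_fwd(x, w$enc[[i]]$c1), 0)
    enc_mid[[i]] <- y1
    y2 <- pmax(conv_fwd(y1, w$enc[[i]]$c2), 0)
    skips[[i]] <- y2
    mp <- cpp_maxpool2_fwd(y2)
    x <- mp$y
    idxs[[i]] <- mp$idx
  }
  xa <- if (cfg$inject_downsampled_input) cat3(x, avgpool_f(xp, f)) else x
  aspp_out <- lapply(w$aspp, function(ly) pmax(conv_fwd(xa, ly), 0))
  acat <- Reduce(cat3, aspp_out)
  am <- pmax(conv_fwd(acat, w$aspp_merge), 0)
  dec_in <- vector("list", d)
  dec_out <- vector("list", d)
  x <- am
  for (i in rev(seq_len(d))) {
    xu <- upsample2(x)
    xc <- cat3(xu, skips[[i]])
    dec_in[[i]] <- xc
    x <- pmax(conv_fwd(xc, w$dec[[i]]), 0)
    dec_out[[i]] <- x
  }
  z <- conv_fwd(x, w$final)[seq_len(H), seq_len(W), 1]
  prob <- 1 / (1 + exp(-z))
  if (!keep_cache) return(list(prob = prob))
  cache$pooled <- x  # decoder top output (input of the final conv)
  cache$skips <- skips
  cache$idxs <- idxs
  cache$enc_in <- enc_in
  cache$enc_mid <- enc_mid
  cache$xa <- xa
  cache$aspp_out <- aspp_out
  cache$acat <- acat
  cache$am <- am
  cache$dec_in <- dec_in
  cache$dec_out <- dec_out
  list(prob = prob, cache = cache)
}

# Backward pass: gz is dL/dz (H x W, z the pre-sigmoid logit map).
# Returns a gradient tree mirroring model$weights.
nn_backward <- function(model, cache, gz) {
  cfg <- model$config
  w <- model$weights
  d <- cfg$encoder_depth
  f <- 2^d
  H <- dim(cache$fused_p)[1]; W <- dim(cache$fused_p)[2]
  g <- list()
  gz3 <- array(gz, dim = c(H, W, 1L))
  bf <- conv_bwd(cache$pooled, w$final, gz3)
  g$final <- list(W = bf$gW, b = bf$gb)
  gx <- bf$gx
  g$dec <- vector("list", d)
  for (i in seq_len(d)) {  # reverse of forward's d..1 order
    gpre <- gx * (cache$dec_out[[i]] > 0)
    bd <- conv_bwd(cache$dec_in[[i]], w$dec[[i]], gpre)
    g$dec[[i]] <- list(W = bd$gW, b = bd$gb)
    cu <- dim(bd$gx)[3] - dim(cache$skips[[i]])[3]
    gskip_i <- bd$gx[, , (cu + 1):dim(bd$gx)[3], drop = FALSE]
    cache$gskip[[i]] <- gskip_i
    gx <- upsample2_bwd(bd$gx[, , seq_len(cu), drop = FALSE])
  }
  gpre <- gx * (cache$am > 0)
  bm <- conv_bwd(cache$acat, w$aspp_merge, gpre)
  g$aspp_merge <- list(W = bm$gW, b = bm$gb)
  A <- dim(cache$aspp_out[[1]])[3]
  g$aspp <- vector("list", length(w$aspp))
  gxa <- 0
  for (j in seq_along(w$aspp)) {
    gj <- bm$gx[, , ((j - 1) * A + 1):(j * A), drop = FALSE]
    gj <- gj * (cache$aspp_out[[j]] > 0)
    ba <- conv_bwd(cache$xa, w$aspp[[j]], gj)
    g$aspp[[j]] <- list(W = ba$gW, b = ba$gb)
    gxa <- gxa + ba$gx
  }
  g_fused_p <- 0
  if (cfg$inject_downsampled_input) {
    cenc <- dim(cache$xa)[3] - 3L
    g_fused_p <- avgpool_f_bwd(gxa[, , (cenc + 1):(cenc + 3), drop = FALSE],
                               f, H, W)
    gx <- gxa[, , seq_len(cenc), drop = FALSE]
  } else gx <- gxa
  g$enc <- vector("list", d)
  for (i in rev(seq_len(d))) {
    gy2 <- array(0, dim = dim(cache$skips[[i]]))
    gy2[cache$idxs[[i]]] <- as.vector(gx)
    gy2 <- gy2 + cache$gskip[[i]]
    gy2 <- gy2 * (cache$skips[[i]] > 0)
    b2 <- conv_bwd(cache$enc_mid[[i]], w$enc[[i]]$c2, gy2)
    gy1 <- b2$gx * (cache$enc_mid[[i]] > 0)
    b1 <- conv_bwd(cache$enc_in[[i]], w$enc[[i]]$c1, gy1)
    g$enc[[i]] <- list(c1 = list(W = b1$gW, b = b1$gb),
                       c2 = list(W = b2$gW, b = b2$gb))
    gx <- b1$gx
  }
  g_fused_p <- g_fused_p + gx
  # fusion conv backward (input gradient not needed)
  M <- matrix(cache$concat, ncol = 4L)
  G <- matrix(g_fused_p, ncol = 3L)
  g$fuse <- list(W = t(M) %*% G, b = colSums(G))
  g
}

#' Forward pass of the centerline model
#'
#' Runs the encoder/ASPP/skip-fusion network and returns the per-pixel
#' centerline probability map (all values in `[0, 1]`). Either supply `image`
#' and `mask` (fusion uses the model's learned 1x1 kernel) or a pre-fused
#' H x W x 3 input. Inputs whose spatial dims are not divisible by
#' `2^encoder_depth` are reflect-padded and the output cropped back.
#'
#' @param model a `centerline_model`.
#' @param image,mask RGB array and binary instance mask.
#' @param fused optional pre-fused input (overrides `image`/`mask`).
#' @return H x W probability matrix.
#' @export
centerline_forward <- function(model, image = NULL, mask = NULL,
                               fused = NULL) {
  stopifnot(inherits(model, "centerline_model"))
  if (is.null(fused)) {
    if (is.null(image) || is.null(mask))
      stop("supply either 'fused' or both 'image' and 'mask'")
    fused <- fuse_inputs(image, mask, model$weights$fuse)
  }
  nn_forward(model, fused)$prob
}

#' Composite Dice + BCE segmentation loss
#'
#' `L = L_Dice + beta * L_BCE` with
#' `L_Dice = 1 - (2 * sum(Y * P) + eps) / (sum(Y) + sum(P) + eps)` and
#' `L_BCE = -mean(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))`. The Dice
#' term counters the extreme foreground/background imbalance of thin
#' centerline targets; `eps` is shared by both terms. Finite for all
#' predictions in `[0, 1]`; non-negative; reduces to the Dice term when
#' `beta = 0`.
#'
#' @param pred probability matrix in `[0, 1]`.
#' @param target binary matrix of the same size.
#' @param beta BCE weight.
#' @param eps stability constant.
#' @return scalar loss.
#' @export
dice_bce_loss <- function(pred, target, beta = 1, eps = 1e-6) {
  if (!all(dim(pred) == dim(target))) stop("pred/target shape mismatch")
  p <- as.numeric(pred); y <- as.numeric(target)
  sY <- sum(y); sP <- sum(p); inter <- sum(y * p)
  dice <- 1 - (2 * inter + eps) / (sY + sP + eps)
  bce <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  dice + beta * bce
}

# Loss value plus gradient with respect to the probabilities.
dice_bce_grad <- function(pred, target, beta, eps) {
  p <- pred; y <- target
  sY <- sum(y); sP <- sum(p); inter <- sum(y * p)
  den <- sY + sP + eps
  dice <- 1 - (2 * inter + eps) / den
  bce <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  gdice <- -(2 * y * den - (2 * inter + eps)) / den^2
  gbce <- -(y / (p + eps) - (1 - y) / (1 - p + eps)) / length(p)
  list(loss = dice + beta * bce, gprob = gdice + beta * gbce)
}

#' Rasterize a centerline polyline into a 3-px-wide training target
#'
#' The polyline is rasterized to an 8-connected one-pixel curve and dilated
#' once with a 3x3 square structuring element, giving the three-pixel-wide
#' band used as ground truth (wider targets improve gradient flow for thin
#' structures).
#'
#' @param polyline (row, col) point matrix inside the frame.
#' @param shape `c(H, W)`.
#' @return binary integer matrix with attribute `source_polyline`.
#' @export
make_target <- function(polyline, shape) {
  thin <- rasterize_polyline(polyline, shape)
  out <- EBImage::imageData(EBImage::dilate(EBImage::Image(thin),
                                            EBImage::makeBrush(3, "box")))
  out <- matrix(as.integer(out > 0), shape[1], shape[2])
  attr(out, "source_polyline") <- polyline
  out
}

# ---- weight-tree arithmetic -------------------------------------------------

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

tree_op <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nms) && nzchar(nms[i]) && !is.null(names(b)))
        b[[nms[i]]] else b[[i]]
      out[[i]] <- tree_op(a[[i]], bi, f)
    }
    return(out)
  }
  f(a, b)
}

# gradients carry only W/b leaves; merge them into the weight tree shape
grad_tree_op <- function(w, g, f) {
  if (is.list(w) && !is.null(w$W)) {
    w$W <- f(w$W, g$W)
    w$b <- f(w$b, g$b)
    return(w)
  }
  if (is.list(w)) {
    for (nm in names(w)) if (!(nm %in% c("k", "dil")))
      w[[nm]] <- grad_tree_op(w[[nm]], g[[nm]], f)
    return(w)
  }
  w
}

zero_like_weights <- function(w) {
  if (is.list(w) && !is.null(w$W)) return(list(W = w$W * 0, b = w$b * 0))
  if (is.list(w)) {
    out <- list()
    for (nm in names(w)) if (!(nm %in% c("k", "dil")))
      out[[nm]] <- zero_like_weights(w[[nm]])
    return(out)
  }
  w
}

#' Build a training set from synthetic scenes
#'
#' One sample per instance: the scene image, an instance mask, and the
#' 3-px-wide centerline target rasterized from the ground-truth polyline.
#' With `masks = "detected"` the input mask comes from the stand-in
#' segmenter (best-IoU match to the instance, IoU >= 0.5), while the target
#' stays the full ground-truth centerline -- the training distribution then
#' matches inference, where the model must complete the centerline across
#' weakly segmented (translucent) body parts.
#'
#' @param scenes list of `shrimp_scene` (typically single-instance crops).
#' @param masks `"truth"` or `"detected"`.
#' @param segmenter settings for the stand-in when `masks = "detected"`.
#' @return list of samples for [train_centerline_model()].
#' @export
centerline_dataset <- function(scenes, masks = c("truth", "detected"),
                               segmenter = segmenter_params()) {
  masks <- match.arg(masks)
  if (inherits(scenes, "shrimp_scene")) scenes <- list(scenes)
  out <- list()
  for (sc in scenes) {
    det <- if (masks == "detected") segment_instances(sc$image, segmenter)
    for (inst in sc$instances) {
      m <- inst$mask
      if (masks == "detected") {
        if (!length(det$masks)) next
        iou <- vapply(det$masks, function(d) mask_iou(d, inst$mask), 1.0)
        if (max(iou) < 0.5) next
        m <- det$masks[[which.max(iou)]]
      }
      out[[length(out) + 1]] <- list(
        image = sc$image,
        mask = m,
        target = make_target(inst$centerline_polyline, dim(inst$mask)),
        polyline = inst$centerline_polyline,
        true_length_px = inst$true_length_px)
    }
  }
  out
}

#' Train the centerline model
#'
#' Momentum SGD with a multi-step learning-rate schedule on the Dice+BCE
#' loss. One integer seed controls weight initialization and the per-epoch
#' data order, so repeated runs are bit-identical. Training aborts with the
#' epoch index if the loss becomes non-finite.
#'
#' @param dataset non-empty list of samples, each a list with `image`
#'   (H x W x 3), `mask` (binary H x W) and `target` (binary H x W, see
#'   [make_target()]). Spatial dims must be divisible by `2^encoder_depth`.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param verbose print the per-epoch mean loss?
#' @return a trained `centerline_model` with `$history`, the per-epoch mean
#'   loss.
#' @export
train_centerline_model <- function(dataset, model_cfg = model_config(),
                                   train_cfg = train_config(),
                                   verbose = FALSE) {
  if (!length(dataset)) stop("'dataset' must be non-empty")
  stopifnot(inherits(train_cfg, "centerline_train_config"))
  model <- init_centerline_model(model_cfg, seed = train_cfg$seed)
  set.seed(train_cfg$seed + 1L)
  vel <- zero_like_weights(model$weights)
  n <- length(dataset)
  history <- numeric(train_cfg$epochs)
  for (epoch in seq_len(train_cfg$epochs)) {
    lr_e <- train_cfg$lr *
      train_cfg$lr_gamma^sum(epoch > train_cfg$lr_milestones)
    ord <- sample.int(n)
    losses <- numeric(n)
    b0 <- 1
    while (b0 <= n) {
      bidx <- ord[b0:min(n, b0 + train_cfg$batch_size - 1)]
      gacc <- NULL
      for (s in bidx) {
        smp <- dataset[[s]]
        if (train_cfg$augment) smp <- augment_sample(smp)
        fused <- fuse_inputs(smp$image, smp$mask, model$weights$fuse)
        fw <- nn_forward(model, fused, keep_cache = TRUE)
        lg <- dice_bce_grad(fw$prob, smp$target, train_cfg$beta,
                            train_cfg$eps)
        losses[match(s, ord)] <- lg$loss
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d",
                       epoch))
        gz <- lg$gprob * fw$prob * (1 - fw$prob)
        img <- normalize01(smp$image)
        dd <- dim(img)
        fw$cache$concat <- array(c(img, as.numeric(smp$mask)),
                                 dim = c(dd[1], dd[2], 4L))
        g <- nn_backward(model, fw$cache, gz)
        gacc <- if (is.null(gacc)) g else
          grad_tree_op(gacc, g, function(a, b) a + b)
      }
      gacc <- grad_tree_op(gacc, gacc, function(a, b) a / length(bidx))
      vel <- tree_op(vel, strip_grads(gacc),
                     function(v, gr) train_cfg$momentum * v - lr_e * gr)
      model$weights <- add_velocity(model$weights, vel)
      b0 <- b0 + train_cfg$batch_size
    }
    history[epoch] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %3d  lr %.4g  loss %.5f", epoch, lr_e,
                      history[epoch]))
  }
  model$history <- history
  model$train_config <- train_cfg
  model
}

# gradient trees have the same nesting as zero_like_weights output
strip_grads <- function(g) g

add_velocity <- function(w, v) {
  if (is.list(w) && !is.null(w$W)) {
    w$W <- w$W + v$W
    w$b <- w$b + v$b
    return(w)
  }
  if (is.list(w)) {
    for (nm in names(w)) if (!(nm %in% c("k", "dil")))
      w[[nm]] <- add_velocity(w[[nm]], v[[nm]])
    return(w)
  }
  w
}

#' Predict the centerline band for one instance
#'
#' Fuse, run the network, binarize at `threshold`: the returned foreground is
#' exactly the set of pixels whose probability is `>= threshold`.
#'
#' @param image H x W x 3 array.
#' @param mask binary instance mask.
#' @param model trained `centerline_model`.
#' @param threshold binarization threshold in (0, 1).
#' @return binary integer matrix (the band to be thinned downstream).
#' @export
predict_instance <- function(image, mask, model, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0,1)")
  prob <- centerline_forward(model, image, mask)
  matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
}

#' Hysteresis binarization of a probability map
#'
#' Canny-style double thresholding for thin uncertain structures: the
#' returned band consists of all pixels with probability `>= lo` that are
#' 8-connected to at least one pixel with probability `>= hi`. Compared with
#' a single cut at `hi` this extends the band through low-confidence
#' stretches (faint body parts, tips) without admitting isolated noise.
#'
#' @param prob probability matrix in `[0, 1]`.
#' @param hi strong threshold (seeds).
#' @param lo weak threshold (extension), `lo <= hi`.
#' @return binary integer matrix.
#' @export
hysteresis_band <- function(prob, hi = 0.5, lo = 0.25) {
  if (lo > hi) stop("'lo' must be <= 'hi'")
  weak <- prob >= lo
  if (!any(weak)) return(matrix(0L, nrow(prob), ncol(prob)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(weak * 1)))
  keep <- unique(lab[prob >= hi])
  keep <- keep[keep > 0]
  matrix(as.integer(lab %in% keep), nrow(prob), ncol(prob))
}

#' Save / load a trained centerline model
#'
#' The model (weights, configs, loss history) is serialized as a single
#' archive with a versioned schema tag.
#'
#' @param model a `centerline_model`.
#' @param path file path.
#' @return `path` (save) or the restored `centerline_model` (load).
#' @export
save_centerline_model <- function(model, path) {
  stopifnot(inherits(model, "centerline_model"))
  saveRDS(list(schema = "shrimpline/centerline-model", version = 1L,
               model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_centerline_model
#' @export
load_centerline_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "shrimpline/centerline-model"))
    stop("not a centerline model archive: ", path)
  structure(obj$model, class = "centerline_model")
}
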