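# Fusion, centerline targets, composite loss, and the forward pass.

test_that("fusion with an identity kernel reproduces the RGB image", {
  img <- array(runif(6 * 8 * 3), dim = c(6, 8, 3))
  mask <- matrix(rbinom(48, 1, 0.4), 6, 8)
  w_id <- list(W = rbind(diag(3), 0), b = rep(0, 3))
  expect_equal(fuse_inputs(img, mask, w_id), img)
})

test_that("an all-zero mask makes the output independent of the mask column", {
  img <- array(runif(5 * 5 * 3), dim = c(5, 5, 3))
  mask <- matrix(0L, 5, 5)
  W1 <- matrix(rnorm(12), 4, 3)
  W2 <- W1; W2[4, ] <- rnorm(3)
  b <- rnorm(3)
  expect_equal(fuse_inputs(img, mask, list(W = W1, b = b)),
               fuse_inputs(img, mask, list(W = W2, b = b)))
})

test_that("fusion matches a hand-computed weighted sum on a 2x2 image", {
  img <- array(c(0.1, 0.2, 0.3, 0.4,    # R
                 0.5, 0.6, 0.7, 0.8,    # G
                 0.9, 1.0, 0.0, 0.2),   # B
               dim = c(2, 2, 3))
  mask <- matrix(c(1L, 0L, 1L, 1L), 2, 2)
  W <- matrix(c(0.5, -1, 2, 0.25,
                1, 1, 1, 1,
                0, 0.5, -0.5, 2), 4, 3)
  b <- c(0.1, -0.2, 0)
  out <- fuse_inputs(img, mask, list(W = W, b = b))
  for (r in 1:2) for (cc in 1:2) for (k in 1:3) {
    v <- c(img[r, cc, ], mask[r, cc])
    expect_equal(out[r, cc, k], sum(v * W[, k]) + b[k], tolerance = 1e-12)
  }
  expect_error(fuse_inputs(img, matrix(0L, 3, 3), list(W = W, b = b)),
               "dimensions")
})

test_that("targets are 3-px bands built by 3x3 dilation of the rasterized polyline", {
  # single point -> 3x3 block
  t1 <- make_target(cbind(10, 10), c(20, 20))
  expect_equal(sum(t1), 9)
  expect_true(all(t1[9:11, 9:11] == 1))
  # border clipping
  t2 <- make_target(cbind(1, 1), c(20, 20))
  expect_equal(sum(t2), 4)
  # horizontal segment of length 20 px: 21 raster px dilated to 23 x 3
  t3 <- make_target(cbind(rep(10, 2), c(5, 25)), c(20, 40))
  expect_equal(sum(t3), 23 * 3)
  # dilation is a superset of the 1-px rasterization
  pl <- cbind(5 + 10 * seq(0, 1, 0.05), 6 + 20 * seq(0, 1, 0.05))
  ras <- rasterize_polyline(pl, c(30, 30))
  tg <- make_target(pl, c(30, 30))
  expect_true(all(tg[ras == 1] == 1))
  expect_error(make_target(matrix(numeric(0), 0, 2), c(10, 10)), "empty")
})

test_that("dice+bce loss matches direct formula evaluation on small fixtures", {
  ref_loss <- function(p, y, beta, eps) {
    dice <- 1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)
    bce <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    dice + beta * bce
  }
  p22 <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2)
  y22 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(dice_bce_loss(p22, y22, beta = 1, eps = 1e-6),
               ref_loss(p22, y22, 1, 1e-6), tolerance = 1e-9)
  set.seed(1)
  p33 <- matrix(runif(9), 3, 3)
  y33 <- matrix(rbinom(9, 1, 0.3), 3, 3)
  for (beta in c(0, 0.5, 2))
    expect_equal(dice_bce_loss(p33, y33, beta = beta, eps = 1e-6),
                 ref_loss(p33, y33, beta, 1e-6), tolerance = 1e-9)
})

test_that("loss limits: perfect prediction near zero, disjoint prediction near one", {
  y <- matrix(c(1, 0, 0, 1, 0, 0, 1, 0, 0), 3, 3)
  expect_lt(dice_bce_loss(y, y, beta = 1, eps = 1e-6), 1e-4)
  p <- 1 - y
  dice_term <- dice_bce_loss(p, y, beta = 0, eps = 1e-6)
  expect_gt(dice_term, 1 - 1e-5)
  expect_lte(dice_term, 1)
  expect_error(dice_bce_loss(matrix(0.5, 2, 2), matrix(0L, 3, 3)), "mismatch")
})

test_that("loss is non-negative, reduces to Dice at beta 0, and is permutation invariant", {
  set.seed(42)
  for (k in 1:20) {
    p <- matrix(runif(64), 8, 8)
    y <- matrix(rbinom(64, 1, 0.2), 8, 8)
    L <- dice_bce_loss(p, y)
    expect_gte(L, 0)
    # beta = 0 leaves exactly the Dice term
    eps <- 1e-6
    expect_equal(dice_bce_loss(p, y, beta = 0),
                 1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps),
                 tolerance = 1e-12)
    perm <- sample(64)
    expect_equal(dice_bce_loss(matrix(p[perm], 8, 8), matrix(y[perm], 8, 8)),
                 L, tolerance = 1e-12)
  }
})

test_that("forward pass returns probabilities of the input shape, deterministically", {
  model <- init_centerline_model(model_config(), seed = 3)
  img <- array(runif(48 * 48 * 3), dim = c(48, 48, 3))
  mask <- matrix(0L, 48, 48); mask[10:30, 15:35] <- 1L
  a <- centerline_forward(model, img, mask)
  b <- centerline_forward(model, img, mask)
  expect_identical(dim(a), c(48L, 48L))
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(a, b)
})

test_that("non-divisible inputs are padded and cropped back transparently", {
  model <- init_centerline_model(model_config(), seed = 3)
  img <- array(runif(45 * 51 * 3), dim = c(45, 51, 3))
  mask <- matrix(1L, 45, 51)
  out <- centerline_forward(model, img, mask)
  expect_identical(dim(out), c(45L, 51L))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("a randomly initialized model maps constant input to near-constant output", {
  model <- init_centerline_model(model_config(), seed = 11)
  fused <- array(0.5, dim = c(64, 64, 3))
  out <- centerline_forward(model, fused = fused)
  expect_lt(max(out) - min(out), 0.2)
})

test_that("backpropagation agrees with finite differences", {
  # spot-check a handful of weights in every layer family on a tiny model
  cfg <- model_config(base_channels = 4, aspp_rates = c(1, 2))
  model <- init_centerline_model(cfg, seed = 2)
  set.seed(5)
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  mask <- matrix(rbinom(256, 1, 0.5), 16, 16)
  target <- matrix(rbinom(256, 1, 0.1), 16, 16)
  lossfun <- function(m) {
    fused <- fuse_inputs(img, mask, m$weights$fuse)
    dice_bce_loss(shrimpline:::nn_forward(m, fused)$prob, target)
  }
  fused <- fuse_inputs(img, mask, model$weights$fuse)
  fw <- shrimpline:::nn_forward(model, fused, keep_cache = TRUE)
  lg <- shrimpline:::dice_bce_grad(fw$prob, target, 1, 1e-6)
  gz <- lg$gprob * fw$prob * (1 - fw$prob)
  fw$cache$concat <- array(c(img, as.numeric(mask)), dim = c(16, 16, 4))
  g <- shrimpline:::nn_backward(model, fw$cache, gz)
  eps <- 1e-5
  check <- function(path_get, path_set, gval, idx) {
    m2 <- model
    w <- path_get(m2)
    w[idx] <- w[idx] + eps
    m2 <- path_set(m2, w)
    num <- (lossfun(m2) - lossfun(model)) / eps
    expect_lt(abs(gval[idx] - num), max(1e-5, 0.02 * abs(num)))
  }
  check(function(m) m$weights$final$W,
        function(m, w) { m$weights$final$W <- w; m }, g$final$W, 1)
  check(function(m) m$weights$fuse$W,
        function(m, w) { m$weights$fuse$W <- w; m }, g$fuse$W, 2)
  check(function(m) m$weights$enc[[1]]$c1$W,
        function(m, w) { m$weights$enc[[1]]$c1$W <- w; m }, g$enc[[1]]$c1$W, 5)
  check(function(m) m$weights$aspp[[2]]$W,
        function(m, w) { m$weights$aspp[[2]]$W <- w; m }, g$aspp[[2]]$W, 3)
  check(function(m) m$weights$dec[[2]]$W,
        function(m, w) { m$weights$dec[[2]]$W <- w; m }, g$dec[[2]]$W, 4)
  check(function(m) m$weights$aspp_merge$b,
        function(m, w) { m$weights$aspp_merge$b <- w; m }, g$aspp_merge$b, 1)
})

test_that("threshold semantics of predict_instance are exact", {
  model <- init_centerline_model(model_config(), seed = 1)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  mask <- matrix(1L, 32, 32)
  prob <- centerline_forward(model, img, mask)
  band <- predict_instance(img, mask, model, threshold = 0.5)
  expect_identical(band == 1, prob >= 0.5)
  # a map strictly below the threshold gives an empty band
  thr_hi <- max(prob) + 1e-9
  if (thr_hi < 1) {
    band2 <- predict_instance(img, mask, model, threshold = thr_hi)
    expect_equal(sum(band2), 0)
  }
  expect_error(predict_instance(img, mask, model, threshold = 1.2), "threshold")
})

test_that("hysteresis banding keeps weak pixels only when connected to strong ones", {
  prob <- matrix(0, 10, 20)
  prob[5, 3:8] <- 0.9          # strong segment
  prob[5, 9:12] <- 0.3         # weak continuation
  prob[2, 16:18] <- 0.3        # isolated weak blob
  band <- hysteresis_band(prob, hi = 0.5, lo = 0.25)
  expect_true(all(band[5, 3:12] == 1))
  expect_true(all(band[2, 16:18] == 0))
})

test_that("models serialize and restore exactly", {
  model <- init_centerline_model(model_config(), seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_centerline_model(model, path)
  back <- load_centerline_model(path)
  expect_equal(back$weights, model$weights)
  expect_equal(back$config, model$config)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(schema = "other"), bad)
  expect_error(load_centerline_model(bad), "archive")
})
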