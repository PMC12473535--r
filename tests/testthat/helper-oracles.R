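# Independent oracles used across the suite. Each is written against the
# published definition, not against the package code paths it checks.

# Reference two-subiteration thinning, vectorized over shifted copies of the
# image (a deliberately different formulation from the package's C++ loop).
reference_thin <- function(img) {
  a <- img != 0
  H <- nrow(a); W <- ncol(a)
  pad <- function(m) {
    z <- matrix(FALSE, H + 2, W + 2)
    z[2:(H + 1), 2:(W + 1)] <- m
    z
  }
  shift <- function(p, dr, dc) p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  repeat {
    removed_any <- FALSE
    for (sub in 1:2) {
      p <- pad(a)
      n <- list(p2 = shift(p, -1, 0), p3 = shift(p, -1, 1),
                p4 = shift(p, 0, 1), p5 = shift(p, 1, 1),
                p6 = shift(p, 1, 0), p7 = shift(p, 1, -1),
                p8 = shift(p, 0, -1), p9 = shift(p, -1, -1))
      B <- Reduce(`+`, n)
      ring <- c(n, n["p2"])
      A <- Reduce(`+`, lapply(1:8, function(i) !ring[[i]] & ring[[i + 1]]))
      cond <- a & B >= 2 & B <= 6 & A == 1
      if (sub == 1) {
        cond <- cond & !(n$p2 & n$p4 & n$p6) & !(n$p4 & n$p6 & n$p8)
      } else {
        cond <- cond & !(n$p2 & n$p4 & n$p8) & !(n$p2 & n$p6 & n$p8)
      }
      if (any(cond)) {
        a[cond] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  matrix(as.integer(a), H, W)
}

# Seeded random blob: union of discs and axis-aligned rectangles.
random_blob <- function(seed, H = 48, W = 48) {
  set.seed(seed)
  m <- matrix(0L, H, W)
  for (k in seq_len(sample(2:5, 1))) {
    if (runif(1) < 0.5) {
      r0 <- runif(1, 8, H - 8); c0 <- runif(1, 8, W - 8)
      rad <- runif(1, 3, 9)
      rs <- matrix(rep(seq_len(H), W), H, W)
      cs <- matrix(rep(seq_len(W), each = H), H, W)
      m[(rs - r0)^2 + (cs - c0)^2 <= rad^2] <- 1L
    } else {
      r0 <- sample(3:(H - 10), 1); c0 <- sample(3:(W - 10), 1)
      m[r0:(r0 + sample(3:8, 1)), c0:(c0 + sample(3:8, 1))] <- 1L
    }
  }
  m
}

# 8-connected component count by union-find (EBImage::bwlabel is
# 4-connected and would split diagonal chains).
n_components <- function(mask) {
  px <- which(mask != 0, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 0) return(0L)
  H <- nrow(mask)
  id <- seq_len(n)
  find <- function(i) { while (id[i] != i) { id[i] <<- id[id[i]]; i <- id[i] }; i }
  key <- px[, 1] + H * (px[, 2] - 1)
  lookup <- new.env(hash = TRUE)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  for (i in seq_len(n)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- px[i, 1] + dr; c <- px[i, 2] + dc
      if (r < 1 || r > H || c < 1 || c > ncol(mask)) next
      j <- mget(as.character(r + H * (c - 1)), envir = lookup,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) id[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# Brute-force average precision for one image at one IoU threshold:
# explicit greedy matching plus direct 101-point PR interpolation, written
# independently of the package implementation.
bruteforce_ap <- function(pred_masks, scores, truth_masks, thr) {
  ord <- order(-scores)
  matched <- rep(FALSE, length(truth_masks))
  tp <- fp <- numeric(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    best_iou <- -1; best_j <- 0
    for (j in seq_along(truth_masks)) {
      if (matched[j]) next
      inter <- sum(pred_masks[[i]] & truth_masks[[j]])
      uni <- sum(pred_masks[[i]] | truth_masks[[j]])
      iou <- if (uni > 0) inter / uni else 0
      if (iou >= thr && iou > best_iou) { best_iou <- iou; best_j <- j }
    }
    if (best_j > 0) { matched[best_j] <- TRUE; tp[k] <- 1 } else fp[k] <- 1
  }
  if (length(truth_masks) == 0) return(NA_real_)
  if (length(ord) == 0) return(0)
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  rec <- ctp / length(truth_masks)
  prec <- ctp / (ctp + cfp)
  for (i in rev(seq_len(length(prec) - 1))) prec[i] <- max(prec[i], prec[i + 1])
  mean(vapply(seq(0, 1, 0.01), function(r) {
    ok <- which(rec >= r)
    if (length(ok)) prec[ok[1]] else 0
  }, 1.0))
}

# Maximum distance from each point of `polyline` to the reference curve.
max_deviation <- function(polyline, truth) {
  steps <- diff(truth)
  dense <- truth
  # densify the reference
  lens <- sqrt(rowSums(steps^2))
  s <- c(0, cumsum(lens))
  at <- seq(0, max(s), by = 0.25)
  dense <- cbind(stats::approx(s, truth[, 1], at, ties = "ordered")$y,
                 stats::approx(s, truth[, 2], at, ties = "ordered")$y)
  max(vapply(seq_len(nrow(polyline)), function(i) {
    min(sqrt((dense[, 1] - polyline[i, 1])^2 +
             (dense[, 2] - polyline[i, 2])^2))
  }, 1.0))
}
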