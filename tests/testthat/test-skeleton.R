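# Thinning, path resolution, arc length and calibration.

test_that("neighbourhood codes follow the clockwise-from-north convention", {
  w0 <- matrix(0, 3, 3)
  expect_equal(neighborhood_code(w0), 0)
  w1 <- matrix(1, 3, 3)
  expect_equal(neighborhood_code(w1), 255)
  wn <- matrix(0, 3, 3); wn[1, 2] <- 1     # north only -> bit 0
  expect_equal(neighborhood_code(wn), 1)
  we <- matrix(0, 3, 3); we[2, 3] <- 1     # east -> bit 2
  expect_equal(neighborhood_code(we), 4)
  wnw <- matrix(0, 3, 3); wnw[1, 1] <- 1   # north-west -> bit 7
  expect_equal(neighborhood_code(wnw), 128)
  # centre value is ignored
  wc <- matrix(0, 3, 3); wc[2, 2] <- 1
  expect_equal(neighborhood_code(wc), 0)
})

test_that("thinning leaves degenerate and already-thin inputs unchanged", {
  m <- matrix(0L, 10, 10); m[5, 5] <- 1L
  expect_identical(zhang_suen_thin(m), m)
  expect_identical(zhang_suen_thin(matrix(0L, 5, 5)), matrix(0L, 5, 5))
  horiz <- matrix(0L, 7, 20); horiz[4, 3:18] <- 1L
  expect_identical(zhang_suen_thin(horiz), horiz)
  diag <- matrix(0L, 20, 20); diag[cbind(3:17, 3:17)] <- 1L
  expect_identical(zhang_suen_thin(diag), diag)
})

test_that("a filled rectangle thins to a one-pixel horizontal line", {
  m <- matrix(0L, 15, 50); m[6:10, 6:45] <- 1L
  th <- zhang_suen_thin(m)
  expect_identical(th, reference_thin(m))
  # one-pixel wide: every column of the original interior has <= 1 pixel
  expect_true(all(colSums(th) <= 1))
  expect_equal(n_components(th), 1L)
})

test_that("thinning matches the independent reference implementation on random blobs", {
  for (s in 1:30) {
    m <- random_blob(s)
    expect_identical(zhang_suen_thin(m), reference_thin(m),
                     label = sprintf("blob seed %d", s))
  }
})

test_that("thinning is a contraction and idempotent", {
  for (s in 31:40) {
    m <- random_blob(s)
    th <- zhang_suen_thin(m)
    expect_true(all(th <= m))
    expect_identical(zhang_suen_thin(th), th)
  }
})

test_that("skeleton paths resolve branches by the longest geodesic", {
  # Y-shape: arms of 10, 10 and 3 pixels from a junction
  m <- matrix(0L, 40, 40)
  m[20, 5:15] <- 1L                         # west arm (11 px incl junction)
  m[20, 15:25] <- 1L                        # east arm
  m[cbind(17:19, rep(15, 3))] <- 1L         # short north stub
  p <- skeleton_to_path(m)
  # the path spans the two long arms and drops the stub
  expect_equal(nrow(p$pixels), 21)
  expect_equal(arc_length_px(p), 20)
  expect_false(p$disconnected)
  # exhaustive check: no endpoint pair gives a longer geodesic
  ends <- rbind(c(20, 5), c(20, 25), c(17, 15))
  d <- function(a, b) sum(abs(a - b))  # arms are straight: city-block works
  pairlens <- combn(3, 2, function(ij) d(ends[ij[1], ], ends[ij[2], ]))
  expect_equal(arc_length_px(p), max(pairlens))
})

test_that("degenerate skeleton inputs are handled", {
  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  p <- skeleton_to_path(single)
  expect_equal(nrow(p$pixels), 1)
  expect_equal(arc_length_px(p), 0)
  expect_error(skeleton_to_path(matrix(0L, 4, 4)), "empty")
  # disconnected input: largest component used and flagged
  m <- matrix(0L, 20, 30)
  m[5, 2:20] <- 1L
  m[15, 2:5] <- 1L
  p2 <- skeleton_to_path(m)
  expect_true(p2$disconnected)
  expect_equal(p2$n_components, 2L)
  expect_equal(nrow(p2$pixels), 19)
})

test_that("arc length follows the documented step weights", {
  horiz <- cbind(rep(4, 11), 3:13)
  expect_equal(arc_length_px(horiz), 10)
  diag <- cbind(3:13, 3:13)
  expect_equal(arc_length_px(diag), 10 * sqrt(2))
  # L-path: 5 orthogonal then 4 diagonal steps
  lpath <- rbind(cbind(rep(2, 6), 2:7), cbind(3:6, 8:11))
  expect_equal(arc_length_px(lpath), 5 + 4 * sqrt(2))
  # calibrated estimator uses the unbiased chain-code weights
  expect_equal(arc_length_px(horiz, "calibrated"), 10 * 0.948)
  expect_equal(arc_length_px(diag, "calibrated"), 10 * 1.340)
})

test_that("straight-band arc length is rotation consistent", {
  base <- capsule_mask(c(120, 120), c(60, 20), c(60, 100), 1.6)
  l0 <- arc_length_px(skeleton_to_path(zhang_suen_thin(base)))
  rot90 <- capsule_mask(c(120, 120), c(20, 60), c(100, 60), 1.6)
  l90 <- arc_length_px(skeleton_to_path(zhang_suen_thin(rot90)))
  expect_lt(abs(l90 - l0) / l0, 0.05)
  d <- 80 / sqrt(2) / 2
  rot45 <- capsule_mask(c(120, 120), c(60 - d, 60 - d), c(60 + d, 60 + d), 1.6)
  l45 <- arc_length_px(skeleton_to_path(zhang_suen_thin(rot45)))
  expect_lt(abs(l45 - l0) / l0, 0.08)
})

test_that("pixel-to-mm conversion is a plain product with a valid calibration", {
  expect_equal(to_mm(123.4, calibration(1)), 123.4)
  expect_equal(to_mm(100, 0.5), 50)
  expect_equal(to_mm(19.44, 10.23 / 19.44), 10.23)
  expect_error(calibration(0), "positive")
  expect_error(calibration(-1), "positive")
  expect_error(to_mm(-5, 1), ">= 0")
})

test_that("measuring an empty band returns NA rather than failing", {
  out <- measure_band(matrix(0L, 10, 10), 1, "learned", 7)
  expect_true(is.na(out$length_px))
  expect_equal(out$instance_id, 7)
})
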