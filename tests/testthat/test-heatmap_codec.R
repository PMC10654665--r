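# helper: landmark set in a 128x128 input space with chosen heatmap-space
# coordinates (heatmap = input / 4, so the grid is 32x32)
ls_at_hm <- function(hm_xy) {
  p <- matrix(rep(hm_xy * 4, each = 23), 23, 2)
  landmark_set(p, image_space(128, 128))
}

test_that("encode evaluates the normalised Gaussian exactly", {
  # sigma 1, landmark on a grid node: peak value 1/(2*pi)
  hs <- hm_encode(ls_at_hm(c(10, 20)), sigma = 1, r = 4)
  expect_equal(hs$maps[21, 11, 1], 1 / (2 * pi), tolerance = 1e-12)
  # peak-1 variant: center value exactly 1
  hs1 <- hm_encode(ls_at_hm(c(10, 20)), sigma = 2.7, r = 4, normalized = FALSE)
  expect_equal(hs1$maps[21, 11, 5], 1)
  # sigma 1.5, value 3 px right of center: (1/(2*pi*2.25)) * exp(-9/4.5)
  hs2 <- hm_encode(ls_at_hm(c(10, 20)), sigma = 1.5, r = 4)
  expect_equal(hs2$maps[21, 14, 3], exp(-9 / 4.5) / (2 * pi * 2.25), tolerance = 1e-12)
  expect_error(hm_encode(ls_at_hm(c(10, 20)), sigma = 0), "parameter error")
})

test_that("normalised channels have unit mass away from borders", {
  hs <- hm_encode(ls_at_hm(c(8.37, 7.12)), sigma = 1.5, r = 4)
  expect_lt(abs(sum(hs$maps[, , 1]) - 1), 1e-3)
})

test_that("encode is translation-equivariant for interior landmarks", {
  a <- hm_encode(ls_at_hm(c(5.3, 6.7)), sigma = 1.5, r = 4)$maps[, , 1]
  b <- hm_encode(ls_at_hm(c(8.3, 6.7)), sigma = 1.5, r = 4)$maps[, , 1]
  expect_equal(b[, 4:16], a[, 1:13], tolerance = 1e-12)
})

test_that("off-grid landmarks encode as truncated tails, not errors", {
  p <- matrix(5, 23, 2); p[1, ] <- c(-40, 30); p[2, ] <- c(500, 500)
  hs <- hm_encode(landmark_set(p, image_space(64, 64)), sigma = 1.5, r = 4)
  expect_true(all(is.finite(hs$maps)))
  expect_lt(max(hs$maps[, , 2]), max(hs$maps[, , 3]))  # far outside: tiny tail
})

test_that("decode maps the argmax through the reduction factor", {
  maps <- array(0, c(32, 32, 23))
  maps[21, 11, ] <- 1                       # (x, y) = (10, 20) in heatmap space
  hs <- heatmap_stack(maps, 1.5, crop_transform(scale = 1 / 4))
  dec <- hm_decode(hs, offset = FALSE)
  expect_equal(unname(dec$coords[, 1]), rep(40, 23))
  expect_equal(unname(dec$coords[, 2]), rep(80, 23))
  expect_identical(dec$role, "stage1")
})

test_that("offset rule: none at symmetric peaks, quarter px toward larger neighbour", {
  on_node <- hm_decode(hm_encode(ls_at_hm(c(10, 20)), sigma = 1.5, r = 4))
  expect_equal(unname(on_node$coords[1, ]), c(40, 80))
  shifted <- hm_decode(hm_encode(ls_at_hm(c(10.3, 20)), sigma = 1.5, r = 4))
  expect_equal(unname(shifted$coords[1, ]), c((10.25) * 4, 80))
  shifted_y <- hm_decode(hm_encode(ls_at_hm(c(10, 19.7)), sigma = 1.5, r = 4))
  expect_equal(unname(shifted_y$coords[1, ]), c(40, (19.75) * 4))
})

test_that("all-equal channels are a decode error naming the channel", {
  maps <- array(0, c(16, 16, 23)); maps[3, 3, -7] <- 1
  hs <- heatmap_stack(maps, 1.5, crop_transform(scale = 1 / 4))
  expect_error(hm_decode(hs), "channel 7")
})

test_that("heatmap L2 loss matches a brute-force loop", {
  set.seed(11)
  a <- array(stats::rnorm(16 * 16 * 23), c(16, 16, 23))
  b <- array(stats::rnorm(16 * 16 * 23), c(16, 16, 23))
  brute <- 0
  for (i in 1:16) for (j in 1:16) for (k in 1:23) brute <- brute + (a[i, j, k] - b[i, j, k])^2
  expect_equal(hm_l2_loss(a, b), brute, tolerance = 1e-12)
  expect_equal(hm_l2_loss(a, a), 0)
  z <- array(0, c(16, 16, 23)); p <- z; p[4, 4, 1] <- 2
  expect_equal(hm_l2_loss(z, p), 4)
  expect_error(hm_l2_loss(a, array(0, c(8, 8, 23))), "contract error")
})

test_that("round trip recovers in-grid landmarks within half a heatmap pixel", {
  set.seed(5)
  worst <- 0
  for (rep in 1:20) {
    p <- matrix(stats::runif(46, 8, 56), 23, 2)
    ls <- landmark_set(p, image_space(64, 64))
    dec <- hm_decode(hm_encode(ls, sigma = 1.5, r = 4))
    err_hm <- sqrt(rowSums((dec$coords - p)^2)) / 4
    worst <- max(worst, max(err_hm))
  }
  expect_lt(worst, 0.5)
})
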