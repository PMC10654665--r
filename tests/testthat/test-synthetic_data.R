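test_that("zero-variance model reproduces the template exactly and seeds are stable", {
  m0 <- shape_model(mode_sd = numeric(0), jitter_sd = 0)
  s <- sample_landmarks(m0, 2, seed = 4)
  expect_equal(unname(s[[1]]$coords), unname(s[[2]]$coords))
  m <- shape_model()
  a <- sample_landmarks(m, 3, seed = 9)
  b <- sample_landmarks(m, 3, seed = 9)
  expect_identical(lapply(a, `[[`, "coords"), lapply(b, `[[`, "coords"))
  c2 <- sample_landmarks(m, 3, seed = 10)
  expect_false(identical(a[[1]]$coords, c2[[1]]$coords))
})

test_that("template geometry: 23 in-bounds points, y-spread exceeds x-spread", {
  t <- sample_landmarks(shape_model(mode_sd = numeric(0), jitter_sd = 0), 1, 1)[[1]]
  p <- t$coords
  expect_identical(dim(p), c(23L, 2L))
  expect_true(all(p >= 0 & p < 1200))
  expect_gt(diff(range(p[, 2])), diff(range(p[, 1])))
})

test_that("sampled landmark means converge to the template (law of large numbers)", {
  m <- shape_model()
  s <- sample_landmarks(m, 400, seed = 2)
  all_xy <- vapply(s, function(l) l$coords, matrix(0, 23, 2))
  mu <- apply(all_xy, c(1, 2), mean)
  # per-landmark total sd: modes (unit-RMS fields scaled by mode sds) + jitter
  per_lm_sd <- sqrt(rowSums(vapply(seq_along(m$modes), function(k)
    m$mode_sd[k]^2 * rowSums(m$modes[[k]]^2), numeric(23))) + 2 * m$jitter_sd^2)
  se <- per_lm_sd / sqrt(400)
  dev <- sqrt(rowSums((mu - m$template)^2))
  expect_true(all(dev < 3.5 * se + 1e-9))
})

test_that("rendering is deterministic, centred and in range", {
  ls <- sample_landmarks(shape_model(), 1, seed = 3)[[1]]
  img1 <- render_image(ls, 64, seed = 5)
  img2 <- render_image(ls, 64, seed = 5)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))
  expect_identical(dim(img1), c(64L, 64L))
  # blob-type (odd-index) landmarks: local max within 1 px of the mapped
  # center. Use a sparse configuration (grid spacing ~21 px at side 128) so
  # neighbouring patterns cannot interfere with the construction check.
  side <- 128L
  grid <- as.matrix(expand.grid(x = seq(150, 1050, by = 225),
                                y = seq(150, 1050, by = 225)))[1:23, ]
  sparse <- landmark_set(grid, space_1200())
  img <- render_image(sparse, side, seed = 5)
  bg <- cephmark:::render_background(side, 5)
  sc <- side / 1200
  for (i in seq(1, 23, by = 2)) {
    cx <- grid[i, 1] * sc; cy <- grid[i, 2] * sc
    win <- 5
    xs <- (round(cx) - win):(round(cx) + win)
    ys <- (round(cy) - win):(round(cy) + win)
    patch <- img[ys + 1, xs + 1] - bg[ys + 1, xs + 1]   # remove background trend
    peak <- which(patch == max(patch), arr.ind = TRUE)[1, ]
    px <- xs[peak[2]]; py <- ys[peak[1]]
    expect_lt(sqrt((px - cx)^2 + (py - cy)^2), 1.01)
  }
  # blank render: smooth background only
  expect_identical(bg, cephmark:::render_background(side, 5))
  expect_lt(diff(range(bg)), 0.7)
})

test_that("out-of-bounds landmarks are a render error", {
  p <- lm_coords(template_ls()); p[1, ] <- c(-50, 20)
  expect_error(render_image(landmark_set(p, space_1200()), 64), "render error")
})

test_that("corruption: zero noise is identity; seeded and structured", {
  ls <- template_ls()
  nm0 <- noise_model(mode_sd = numeric(0), indep_sd = 0, deep_inflation = 1)
  expect_equal(corrupt_landmarks(ls, nm0, seed = 1)$coords, ls$coords)
  nm <- noise_model()
  a <- corrupt_landmarks(ls, nm, seed = 7)
  expect_identical(a$coords, corrupt_landmarks(ls, nm, seed = 7)$coords)
  expect_identical(a$role, "stage1")
})

test_that("rank-1 noise reproduces its analytic cross-landmark covariance", {
  ls <- template_ls()
  nm <- noise_model(mode_sd = 5, indep_sd = 0, deep_inflation = 1)
  draws <- vapply(1:600, function(s)
    corrupt_landmarks(ls, nm, seed = s)$coords[, 2] - ls$coords[, 2], numeric(23))
  emp <- stats::cov(t(draws))
  theo <- 25 * tcrossprod(nm$modes[[1]][, 2])
  expect_lt(max(abs(emp - theo)), 0.25 * max(abs(theo)) + 0.5)
  # correlation across landmarks is genuinely nonzero
  expect_gt(min(stats::cor(t(draws))), 0.9)
})

test_that("independent isotropic noise has the Rayleigh mean radius", {
  ls <- template_ls()
  nm <- noise_model(mode_sd = numeric(0), indep_sd = 2, deep_inflation = 1)
  r <- unlist(lapply(1:450, function(s) {
    d <- corrupt_landmarks(ls, nm, seed = s)$coords - ls$coords
    sqrt(rowSums(d^2))
  }))
  expected <- 2 * sqrt(pi / 2)                 # Rayleigh mean, sigma = 2 px
  expect_lt(abs(mean(r) - expected) / expected, 0.03)
})

test_that("training-set fixture: decode before any training recovers landmarks", {
  ds <- make_training_set(3, side = 64, seed = 21)
  expect_identical(dim(ds$images), c(64L, 64L, 1L, 3L))
  expect_identical(dim(ds$heatmaps), c(16L, 16L, 23L, 3L))
  for (i in 1:3) {
    hs <- heatmap_stack(ds$heatmaps[, , , i], ds$sigma, crop_transform(scale = 1 / ds$r))
    dec <- hm_decode(hs, crop = ds$crop)
    err_in <- sqrt(rowSums((ct_map(ds$crop, dec$coords) -
                            ds$gt_input[[i]]$coords)^2))
    expect_lt(max(err_in), 2)                  # within 2 input px (0.5 hm px)
  }
})
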