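# shared fixtures: everything is generated in code, nothing on disk

space_1200 <- function() image_space(1200, 1200, 0.35)

template_ls <- function(space = space_1200()) {
  m <- shape_model(mode_sd = numeric(0), jitter_sd = 0,
                   side = space$width_px, mm_per_px = space$mm_per_px)
  sample_landmarks(m, 1, seed = 1)[[1]]
}

rand_ls <- function(seed, space = space_1200(), role = "ground_truth") {
  set.seed(seed)
  landmark_set(cbind(stats::runif(23, 50, space$width_px - 50),
                     stats::runif(23, 50, space$height_px - 50)),
               space, role = role)
}

# rotate/translate/scale a landmark set (exact similarity transform)
similarity_ls <- function(ls, angle_deg = 0, shift = c(0, 0), scale = 1) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p <- ls$coords %*% t(R) * scale
  p <- sweep(p, 2, shift, "+")
  big <- max(abs(p)) + 100
  landmark_set(p, image_space(ceiling(big), ceiling(big), ls$space$mm_per_px),
               role = ls$role, scheme = ls$scheme)
}

desk_cfg <- function(side = 64L) backbone_config(input_side = side)

expect_all_near <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
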