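# Synthetic facial-profile world: a 23-point template in a 1200x1200 space at
# 0.35 mm/px, low-rank shape variation, toy rendered images, and structured
# stage-1 localization noise. Geometric, not anatomically calibrated; it
# exists so every pipeline stage is testable without the private dataset.

# 23-point lateral-profile template. 18 points follow the soft-tissue /
# dental profile; 5 "deep" points (sella, menton, gonion and basion/porion
# analogues: indices 1, 8, 10, 13, 23) sit off the profile curve. The y-spread
# exceeds the x-spread, echoing the long-face geometry of the target data.
profile_template <- function() {
  m <- matrix(c(
    550, 345,   # L1  sella (deep)
    800, 360,   # L2  nasion
    820, 425,   # L3  cranial reference line, anterior
    560, 435,   # L4  cranial reference line, posterior
    755, 560,   # L5  A-point
    700, 680,   # L6  B-point
    710, 730,   # L7  pogonion-like
    690, 775,   # L8  menton (deep)
    790, 773,   # L9  mandibular border point
    580, 640,   # L10 gonion (deep)
    770, 628,   # L11 upper incisal edge
    763, 636,   # L12 lower incisal edge
    555, 520,   # L13 basion analogue (deep)
    810, 200,   # L14 forehead
    820, 300,   # L15 glabella
    830, 420,   # L16 nasal bridge
    880, 500,   # L17 pronasale
    840, 540,   # L18 subnasale
    835, 600,   # L19 upper lip
    830, 650,   # L20 lower lip
    760, 760,   # L21 soft-tissue chin
    860, 520,   # L22 columella
    500, 430    # L23 porion analogue (deep)
  ), ncol = 2, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

deep_landmarks <- function() c(1L, 8L, 10L, 13L, 23L)

# unit-RMS 46-dim deformation fields over a template
shape_mode_fields <- function(template) {
  ctr <- colMeans(template)
  dx <- template[, 1] - ctr[1]; dy <- template[, 2] - ctr[2]
  norm_field <- function(fx, fy) {
    s <- sqrt(mean(fx^2 + fy^2))
    cbind(fx, fy) / s
  }
  list(
    elongation  = norm_field(rep(0, 23), dy),          # long/short face
    prognathism = norm_field(dy, rep(0, 23)),          # anteroposterior shear
    rotation    = norm_field(-dy, dx)                  # head tilt (linearised)
  )
}

#' Statistical shape model for synthetic profile landmarks
#'
#' Template plus `k` low-rank deformation modes (vertical elongation,
#' anteroposterior shear, linearised rotation) with stated standard
#' deviations, plus independent per-landmark jitter. Mode displacements are
#' unit-RMS fields, so `mode_sd` is in pixels of the 1200-px space.
#'
#' @param mode_sd Per-mode standard deviations in px (default `c(60, 40, 25)`,
#'   i.e. about 21/14/9 mm of patient-to-patient variation — facial heights
#'   and jaw positions vary on the centimetre scale across adults).
#' @param jitter_sd Independent per-landmark jitter sd in px (default 2 px,
#'   about 0.7 mm, the scale of annotator disagreement).
#' @param side Image side in px (default 1200).
#' @param mm_per_px Pixel spacing (default 0.35).
#' @return An object of class `shape_model`.
#' @export
shape_model <- function(mode_sd = c(60, 40, 25), jitter_sd = 2,
                        side = 1200L, mm_per_px = 0.35) {
  template <- profile_template()
  modes <- shape_mode_fields(template)[seq_along(mode_sd)]
  structure(list(template = template, modes = modes, mode_sd = mode_sd,
                 jitter_sd = jitter_sd,
                 space = image_space(side, side, mm_per_px)),
            class = "shape_model")
}

#' Sample ground-truth landmark sets from the shape model
#'
#' @param model A [shape_model()].
#' @param n Number of sets (>= 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return List of `n` `landmark_set` objects (role `"ground_truth"`),
#'   clamped into image bounds.
#' @export
sample_landmarks <- function(model, n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  side <- model$space$width_px
  lapply(seq_len(n), function(i) {
    p <- model$template
    for (k in seq_along(model$modes))
      p <- p + stats::rnorm(1, 0, model$mode_sd[k]) * model$modes[[k]]
    p <- p + matrix(stats::rnorm(46, 0, model$jitter_sd), 23, 2)
    p[, 1] <- pmin(pmax(p[, 1], 10), side - 11)
    p[, 2] <- pmin(pmax(p[, 2], 10), side - 11)
    landmark_set(p, model$space, role = "ground_truth")
  })
}

# landmark-specific texture parameters: odd indices are radial blobs, even
# indices oriented ripple patches; every landmark gets a distinct orientation
# and frequency so the detector can tell them apart.
pattern_params <- function(side) {
  i <- 1:23
  list(kind  = ifelse(i %% 2L == 1L, "blob", "ripple"),
       theta = (i - 1) * 2.399963,          # golden-angle spread
       omega = 2.0 + 0.18 * i,              # rad per pattern sigma
       sigma = side * (0.035 + 0.004 * (i %% 5L)))
}

render_background <- function(side, seed) {
  # the background is deliberately identical across images: a per-image
  # random background would be an image-identity cue that lets the detector
  # memorise training images instead of reading the landmark textures.
  # Amplitudes are kept low enough that background + blob never saturates
  # at 1, so pattern maxima stay exactly on the landmark.
  gx <- matrix(rep((0:(side - 1)) / side, each = side), side, side)
  gy <- matrix(rep((0:(side - 1)) / side, times = side), side, side)
  0.18 + 0.22 * gy + 0.06 * sin(2 * pi * 1.5 * gx + 0.7) * sin(2 * pi * 1.2 * gy + 2.1)
}

#' Render a toy profile image for a landmark set
#'
#' Draws a distinct local texture (radial blob or oriented ripple, unique
#' frequency/orientation per landmark) centred exactly on each landmark over
#' a smooth seeded background. Landmark coordinates are mapped isotropically
#' from the set's own space to the requested side. Deterministic given seed.
#'
#' @param ls A [landmark_set()].
#' @param side Output image side in px.
#' @param seed Integer seed (controls the background phases).
#' @return `side` x `side` numeric matrix in `[0, 1]`; rows are y, columns x.
#' @export
render_image <- function(ls, side, seed = 1L) {
  sc <- side / max(ls$space$width_px, ls$space$height_px)
  pk <- lm_coords(ls) * sc
  if (any(pk < -0.5 | pk > side - 0.5)) stop("render error: landmark out of bounds")
  img <- render_background(side, seed)
  pp <- pattern_params(side)
  for (i in 1:23) {
    cx <- pk[i, 1]; cy <- pk[i, 2]; s <- pp$sigma[i]
    rad <- ceiling(4 * s)
    x0 <- max(0, floor(cx - rad)); x1 <- min(side - 1, ceiling(cx + rad))
    y0 <- max(0, floor(cy - rad)); y1 <- min(side - 1, ceiling(cy + rad))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    ddx <- outer(ys - cy, xs - cx, function(a, b) b)   # columns x
    ddy <- outer(ys - cy, xs - cx, function(a, b) a)
    env <- exp(-(ddx^2 + ddy^2) / (2 * s^2))
    if (pp$kind[i] == "blob") {
      patch <- 0.45 * env
    } else {
      u <- (cos(pp$theta[i]) * ddx + sin(pp$theta[i]) * ddy) / s
      patch <- 0.40 * cos(pp$omega[i] * u) * env
    }
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + patch
  }
  pmin(pmax(img, 0), 1)
}

#' Structured stage-1 localization noise model
#'
#' Shared low-rank error component plus independent per-landmark noise. The
#' two default correlated modes emulate tracing-superimposition errors: a
#' global shift (weighted toward y, where profile landmarks scatter) and a
#' global expansion about the centroid. Deep off-curve landmarks get inflated
#' independent noise, emulating the hard-to-localise points.
#'
#' @param mode_sd Per-mode sds in px of the ground-truth space
#'   (default `c(6, 6)`; rank = number of modes).
#' @param indep_sd Independent per-axis noise sd in px (default 1.5).
#' @param deep_inflation Multiplier on `indep_sd` for deep landmarks
#'   (default 2).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(mode_sd = c(6, 6), indep_sd = 1.5, deep_inflation = 2) {
  template <- profile_template()
  ctr <- colMeans(template)
  norm_field <- function(fx, fy) { s <- sqrt(mean(fx^2 + fy^2)); cbind(fx, fy) / s }
  modes <- list(
    shift  = norm_field(rep(0.5, 23), rep(1, 23)),
    expand = norm_field(template[, 1] - ctr[1], template[, 2] - ctr[2])
  )[seq_along(mode_sd)]
  infl <- rep(1, 23); infl[deep_landmarks()] <- deep_inflation
  structure(list(modes = modes, mode_sd = mode_sd, indep_sd = indep_sd,
                 inflation = infl),
            class = "noise_model")
}

#' Corrupt ground-truth landmarks with structured noise
#'
#' Adds the sampled low-rank correlated component and independent
#' per-landmark noise; returns a stage-1-role set. Deterministic given seed.
#'
#' @param ls A ground-truth [landmark_set()].
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return A `landmark_set` with role `"stage1"`.
#' @export
corrupt_landmarks <- function(ls, noise, seed = 1L) {
  set.seed(seed)
  p <- lm_coords(ls)
  for (k in seq_along(noise$modes))
    p <- p + stats::rnorm(1, 0, noise$mode_sd[k]) * noise$modes[[k]]
  p <- p + matrix(stats::rnorm(46, 0, noise$indep_sd), 23, 2) * noise$inflation
  landmark_set(p, ls$space, role = "stage1", scheme = ls$scheme)
}

#' Build a rendered training/evaluation set at network-input scale
#'
#' Samples `n` ground-truth sets, renders each at `side` x `side`, maps the
#' landmarks through the full-image crop transform into input space and
#' encodes the target heatmap stacks.
#'
#' @param n Number of images.
#' @param side Network input side (must be divisible by 32 to feed the
#'   backbone; default 64 for desk-scale runs).
#' @param seed Integer seed.
#' @param model A [shape_model()].
#' @param sigma Heatmap Gaussian sd (heatmap px).
#' @param r Heatmap resolution reduction factor.
#' @param normalized Encode normalised (`TRUE`) or peak-1 heatmaps.
#' @return An object of class `lp_dataset`: images `(side, side, 1, n)`
#'   array, `gt` (original-space sets), `gt_input` (input-space sets),
#'   target `heatmaps` `(side/r, side/r, 23, n)`, the `crop` transform and
#'   codec metadata.
#' @export
make_training_set <- function(n, side = 64L, seed = 1L, model = shape_model(),
                              sigma = 1.5, r = 4L, normalized = TRUE) {
  gt <- sample_landmarks(model, n, seed)
  big <- max(model$space$width_px, model$space$height_px)
  in_space <- image_space(side, side, model$space$mm_per_px * big / side)
  crop <- crop_transform(scale = side / big, offset = c(0, 0),
                         src_space = model$space, dst_space = in_space)
  images <- array(0, c(side, side, 1L, n))
  hm <- array(0, c(side %/% r, side %/% r, 23L, n))
  gt_input <- vector("list", n)
  for (i in seq_len(n)) {
    images[, , 1L, i] <- render_image(gt[[i]], side, seed = seed + i)
    gt_input[[i]] <- landmark_set(ct_map(crop, lm_coords(gt[[i]])), in_space,
                                  role = "ground_truth", scheme = gt[[i]]$scheme)
    hm[, , , i] <- hm_encode(gt_input[[i]], sigma = sigma, r = r,
                             normalized = normalized)$maps
  }
  structure(list(images = images, gt = gt, gt_input = gt_input, heatmaps = hm,
                 crop = crop, sigma = sigma, r = r, normalized = normalized,
                 space = model$space, in_space = in_space, seed = seed),
            class = "lp_dataset")
}
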