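#' Configuration of the high-resolution heatmap backbone
#'
#' A configurable instance of the parallel multi-branch high-resolution
#' topology: a two-convolution stride-2 stem (resolution 1/4), a first stage
#' of bottleneck residual units, then branches added successively (stage 2
#' has 2 branches, stage 3 has 3, stage 4 has 4) at widths C, 2C, 4C, 8C and
#' resolutions input/4 ... input/32, fused by exchange units (stride-2 3x3
#' convolutions down, nearest-neighbour upsampling plus 1x1 convolution up).
#' The head upsamples and concatenates all four resolutions and applies two
#' 1x1 convolutions to produce the 23 heatmap channels at input/4.
#'
#' The default is a desk-scale instance (C = 8, one multi-resolution block
#' per stage, 2 residual units per block) of the full-scale topology
#' (C = 18, blocks 1/4/3, 4 units — see [fullscale_backbone_config()]).
#'
#' @param input_side Input image side; must be divisible by 32.
#' @param in_channels Image channels (1 = grayscale).
#' @param base_width Branch-1 width C; branch widths are C, 2C, 4C, 8C.
#' @param stem_width Stem output channels (default `2 * base_width`).
#' @param stage1_units Number of bottleneck residual units in stage 1.
#' @param bottleneck_width Bottleneck inner width (stage-1 output is 4x this).
#' @param stage_blocks Multi-resolution block counts for stages 2-4.
#' @param units_per_block Residual units per branch per block.
#' @param head_width Channels of the head's inner 1x1 convolution.
#' @param n_landmarks Output channels (23).
#' @param exchange Wiring hook: `FALSE` drops the cross-branch connections of
#'   every exchange unit (used to detect dead wiring in tests).
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(input_side = 256L, in_channels = 1L, base_width = 8L,
                            stem_width = 2L * base_width, stage1_units = 1L,
                            bottleneck_width = base_width,
                            stage_blocks = c(1L, 1L, 1L), units_per_block = 2L,
                            head_width = 64L, n_landmarks = 23L, exchange = TRUE) {
  if (input_side %% 32L != 0L)
    stop("config error: input side must be divisible by 32")
  structure(list(input_side = as.integer(input_side), in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width), stem_width = as.integer(stem_width),
                 stage1_units = as.integer(stage1_units),
                 bottleneck_width = as.integer(bottleneck_width),
                 stage_blocks = as.integer(stage_blocks),
                 units_per_block = as.integer(units_per_block),
                 head_width = as.integer(head_width), n_landmarks = as.integer(n_landmarks),
                 exchange = isTRUE(exchange)),
            class = "backbone_config")
}

#' Full-scale backbone configuration
#'
#' The published full-scale hyperparameters: widths 18/36/72/144, stem and
#' bottleneck width 64 with 4 stage-1 units, 1/4/3 multi-resolution blocks
#' with 4 residual units each, head width 64, 256 input. Train-at-desk is not
#' expected with this instance; it exists for completeness and for the
#' structural-constant checks.
#'
#' @return A [backbone_config()].
#' @export
fullscale_backbone_config <- function() {
  backbone_config(input_side = 256L, in_channels = 3L, base_width = 18L,
                  stem_width = 64L, stage1_units = 4L, bottleneck_width = 64L,
                  stage_blocks = c(1L, 4L, 3L), units_per_block = 4L,
                  head_width = 64L)
}

#' Build a heatmap backbone model
#'
#' Parameter initialisation is deterministic given `seed` (He-normal
#' weights, zero biases). The returned model is an environment-backed
#' container; training updates it in place.
#'
#' @param cfg A [backbone_config()].
#' @param seed Integer seed.
#' @return An object of class `heatmap_model`.
#' @export
backbone_build <- function(cfg, seed = 1L) {
  set.seed(seed)
  g <- nn_graph()
  nn_add_node(g, "input", "input")
  cur <- nn_add_conv(g, "stem1", "input", cfg$in_channels, cfg$stem_width, 3, stride = 2, relu = TRUE)
  cur <- nn_add_conv(g, "stem2", cur, cfg$stem_width, cfg$stem_width, 3, stride = 2, relu = TRUE)
  ch <- cfg$stem_width
  out1 <- 4L * cfg$bottleneck_width
  for (u in seq_len(cfg$stage1_units)) {
    inp <- cur
    a <- nn_add_conv(g, sprintf("s1u%d.a", u), inp, ch, cfg$bottleneck_width, 1, relu = TRUE)
    b <- nn_add_conv(g, sprintf("s1u%d.b", u), a, cfg$bottleneck_width, cfg$bottleneck_width, 3, relu = TRUE)
    cc <- nn_add_conv(g, sprintf("s1u%d.c", u), b, cfg$bottleneck_width, out1, 1)
    skip <- if (ch != out1) nn_add_conv(g, sprintf("s1u%d.p", u), inp, ch, out1, 1) else inp
    s <- nn_add_node(g, sprintf("s1u%d.add", u), "add", c(cc, skip))
    cur <- nn_add_node(g, sprintf("s1u%d.out", u), "relu", s)
    ch <- out1
  }
  widths <- cfg$base_width * c(1L, 2L, 4L, 8L)
  br <- list(
    nn_add_conv(g, "t1.b1", cur, ch, widths[1], 3, relu = TRUE),
    nn_add_conv(g, "t1.b2", cur, ch, widths[2], 3, stride = 2, relu = TRUE)
  )
  nb <- 2L
  for (stage in 2:4) {
    for (blk in seq_len(cfg$stage_blocks[stage - 1L])) {
      tag <- sprintf("s%db%d", stage, blk)
      for (j in seq_len(nb)) {
        x <- br[[j]]
        for (u in seq_len(cfg$units_per_block)) {
          a <- nn_add_conv(g, sprintf("%s.br%du%d.a", tag, j, u), x, widths[j], widths[j], 3, relu = TRUE)
          b2 <- nn_add_conv(g, sprintf("%s.br%du%d.b", tag, j, u), a, widths[j], widths[j], 3)
          s <- nn_add_node(g, sprintf("%s.br%du%d.add", tag, j, u), "add", c(b2, x))
          x <- nn_add_node(g, sprintf("%s.br%du%d.out", tag, j, u), "relu", s)
        }
        br[[j]] <- x
      }
      if (cfg$exchange && nb > 1L) {
        newbr <- vector("list", nb)
        for (j in seq_len(nb)) {
          terms <- character()
          for (i in seq_len(nb)) {
            if (i == j) { terms <- c(terms, br[[i]]); next }
            if (i < j) {                      # downsample i -> j
              x <- br[[i]]
              for (dstep in seq_len(j - i)) {
                oc <- if (dstep == j - i) widths[j] else widths[i]
                x <- nn_add_conv(g, sprintf("%s.ex%d_%d.d%d", tag, i, j, dstep),
                                 x, widths[i], oc, 3, stride = 2)
              }
              terms <- c(terms, x)
            } else {                          # upsample i -> j
              up <- nn_add_node(g, sprintf("%s.ex%d_%d.up", tag, i, j), "upsample",
                                br[[i]], factor = 2L^(i - j))
              terms <- c(terms, nn_add_conv(g, sprintf("%s.ex%d_%d.c", tag, i, j),
                                            up, widths[i], widths[j], 1))
            }
          }
          s <- nn_add_node(g, sprintf("%s.ex.out%d", tag, j), "add", terms)
          newbr[[j]] <- nn_add_node(g, sprintf("%s.ex.relu%d", tag, j), "relu", s)
        }
        br <- newbr
      }
    }
    if (stage < 4L) {
      nb <- nb + 1L
      br[[nb]] <- nn_add_conv(g, sprintf("t%d.b%d", stage, nb), br[[nb - 1L]],
                              widths[nb - 1L], widths[nb], 3, stride = 2, relu = TRUE)
    }
  }
  terms <- br[[1]]
  for (j in 2:4)
    terms <- c(terms, nn_add_node(g, sprintf("head.up%d", j), "upsample",
                                  br[[j]], factor = 2L^(j - 1L)))
  cc <- nn_add_node(g, "head.concat", "concat", terms)
  h1 <- nn_add_conv(g, "head.c1", cc, sum(widths), cfg$head_width, 1, relu = TRUE)
  # zero-init output conv: untrained prediction is the zero heatmap, so early
  # training shapes peaks instead of first shrinking a large random output
  g$output <- nn_add_conv(g, "head.c2", h1, cfg$head_width, cfg$n_landmarks, 1,
                          zero_init = TRUE)
  m <- new.env(parent = emptyenv())
  m$graph <- g
  m$config <- cfg
  m$opt <- adam_state()
  m$epoch <- 0L
  class(m) <- "heatmap_model"
  m
}

as_image_batch <- function(images, in_channels = 1L) {
  d <- dim(images)
  if (length(d) == 2L) images <- array(images, c(d, 1L, 1L))
  else if (length(d) == 3L) images <- array(images, c(d[1], d[2], 1L, d[3]))
  d <- dim(images)
  if (d[3] != in_channels) stop("contract error: image channel mismatch")
  images
}

#' Forward pass: images to predicted heatmaps
#'
#' @param m A [backbone_build()] model.
#' @param images A `(side, side)` matrix, `(side, side, n)` or
#'   `(side, side, channels, n)` array matching the configured input side.
#' @return A `(side/4, side/4, 23, n)` array of predicted heatmaps.
#' @export
backbone_forward <- function(m, images) {
  x <- as_image_batch(images, m$config$in_channels)
  d <- dim(x)
  if (d[1] != m$config$input_side || d[2] != m$config$input_side)
    stop("contract error: input side mismatch")
  nn_forward(m$graph, x, keep = FALSE)$vals[[m$graph$output]]
}

#' One training epoch of the backbone
#'
#' Minimises the summed L2 heatmap loss over one pass of the dataset with
#' Adam, in mini-batches. Mutates the model in place and returns the mean
#' per-image loss of the epoch.
#'
#' @param m A [backbone_build()] model.
#' @param images Input batch array (see [backbone_forward()]).
#' @param heatmaps Target `(side/4, side/4, 23, n)` array.
#' @param lr Learning rate (full-scale default 1e-4; desk overfit runs use
#'   larger values).
#' @param batch_size Mini-batch size (default 16).
#' @param shuffle Shuffle sample order each epoch (uses the current RNG
#'   stream).
#' @return Mean per-image loss (invisible model mutation).
#' @export
backbone_train_epoch <- function(m, images, heatmaps, lr = 1e-4,
                                 batch_size = 16L, shuffle = TRUE) {
  x <- as_image_batch(images, m$config$in_channels)
  n <- dim(x)[4]
  if (n < 1L) stop("data error: empty dataset")
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  total <- 0
  g <- m$graph
  for (start in seq(1L, n, by = batch_size)) {
    ix <- ord[start:min(start + batch_size - 1L, n)]
    xb <- x[, , , ix, drop = FALSE]
    tb <- heatmaps[, , , ix, drop = FALSE]
    fwd <- nn_forward(g, xb, keep = TRUE)
    pred <- fwd$vals[[g$output]]
    diffs <- pred - tb
    loss <- sum(diffs^2)
    total <- total + loss
    if (lr > 0) {
      grads <- nn_backward(g, fwd, 2 * diffs / length(ix))
      g$params <- adam_update(g$params, grads, m$opt, lr)
    }
  }
  m$epoch <- m$epoch + 1L
  total / n
}

#' Decode predicted heatmaps for a batch
#'
#' Wraps [hm_decode()] over the batch dimension of a forward-pass output.
#'
#' @param pred `(h, w, 23, n)` array from [backbone_forward()].
#' @param r Resolution reduction factor (4).
#' @param crop Optional crop transform back to original-image space.
#' @param sigma Sigma recorded in the stacks (metadata only).
#' @param offset Apply the quarter-pixel decode offset.
#' @return List of `landmark_set` objects (role `"stage1"`).
#' @export
decode_batch <- function(pred, r = 4L, crop = NULL, sigma = 1.5, offset = TRUE) {
  n <- dim(pred)[4]
  link <- crop_transform(scale = 1 / r)
  lapply(seq_len(n), function(i) {
    hs <- heatmap_stack(pred[, , , i], sigma, link)
    hm_decode(hs, offset = offset, crop = crop)
  })
}
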