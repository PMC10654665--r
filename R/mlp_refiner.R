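#' Configuration of the coordinate-refinement MLPs
#'
#' Two independent three-layer perceptrons — one per axis — each mapping the
#' 23 stage-1 coordinates to 23 refined coordinates through a 500-unit hidden
#' layer. Coordinates are normalised into `[0, 1]` by the image side before
#' entering the network (recorded in the model metadata); the published
#' learning rate (1e-5) is implausible on raw 0-1200 px inputs.
#'
#' @param n_landmarks Inputs/outputs per axis (23).
#' @param hidden Hidden units (500).
#' @param lr Adam learning rate (1e-5).
#' @param weight_decay L2 regularisation factor (1e-4).
#' @param epochs_per_cycle Refiner epochs per training cycle (100).
#' @param batch_size Mini-batch size (16).
#' @param activation Hidden activation; `"relu"` (default, unstated in the
#'   original method) or `"tanh"`.
#' @param residual If `TRUE` the network predicts a residual added to its
#'   input instead of absolute coordinates (experimental flag; default
#'   `FALSE`, the literal absolute-coordinate formulation).
#' @param init `"identity"` (default) starts each axis network as the exact
#'   identity map (`relu(x) - relu(-x) = x` across paired hidden units, the
#'   rest zero-coupled); `"random"` is plain He initialisation. Identity
#'   initialisation makes training learn only the correction to the stage-1
#'   coordinates, which converges within desk-scale step budgets where the
#'   random start does not.
#' @return An object of class `refiner_config`.
#' @export
refiner_config <- function(n_landmarks = 23L, hidden = 500L, lr = 1e-5,
                           weight_decay = 1e-4, epochs_per_cycle = 100L,
                           batch_size = 16L, activation = c("relu", "tanh"),
                           residual = FALSE, init = c("identity", "random")) {
  structure(list(n_landmarks = as.integer(n_landmarks), hidden = as.integer(hidden),
                 lr = lr, weight_decay = weight_decay,
                 epochs_per_cycle = as.integer(epochs_per_cycle),
                 batch_size = as.integer(batch_size),
                 activation = match.arg(activation), residual = isTRUE(residual),
                 init = match.arg(init)),
            class = "refiner_config")
}

new_axis_net <- function(n, h, init = "identity", activation = "relu") {
  net <- list(W1 = he_init(n, h, n), b1 = numeric(h),
              W2 = matrix(0, h, n), b2 = numeric(n))
  if (init == "identity") {
    # start as the identity map: relu(x) - relu(-x) = x (tanh: small-slope
    # linear regime). The remaining hidden units keep their random W1
    # columns with zero W2 rows, so they contribute nothing initially but
    # receive gradients and add capacity as training proceeds.
    stopifnot(h >= 2L * n)
    a <- if (activation == "relu") 1 else 0.1
    net$W1[, seq_len(n)] <- diag(n) * a
    net$W1[, n + seq_len(n)] <- -diag(n) * a
    net$W2[seq_len(n), ] <- diag(n) / a
    net$W2[n + seq_len(n), ] <- -diag(n) / a
  } else {
    net$W2 <- he_init(h, n, h)
  }
  net
}

#' Build a refiner model
#'
#' The x- and y-axis networks share no parameters and are initialised from
#' the same seeded stream (x first). Training mutates the model in place;
#' parameters persist across training calls (they are initialised only
#' here, at the beginning of training).
#'
#' @param cfg A [refiner_config()].
#' @param space The [image_space()] whose width/height normalise x/y.
#' @param seed Integer seed.
#' @return An object of class `refiner_model`.
#' @export
refiner_build <- function(cfg, space, seed = 1L) {
  set.seed(seed)
  m <- new.env(parent = emptyenv())
  m$config <- cfg
  m$space <- space
  m$norm <- c(x = space$width_px, y = space$height_px)
  # per-coordinate centers and per-axis decorrelation (whitening) transforms
  # in side-normalised units, estimated from the first training batch and
  # then frozen; identity until then. The 23 coordinates of an axis are
  # driven by a few shape modes, so their covariance spans several orders of
  # magnitude; without decorrelation (classic MLP preprocessing) the
  # optimisation cannot converge within desk-scale step budgets.
  n <- cfg$n_landmarks
  m$center <- list(x = rep(0, n), y = rep(0, n))
  m$center_locked <- FALSE
  m$x <- new_axis_net(n, cfg$hidden, cfg$init, cfg$activation)
  m$y <- new_axis_net(n, cfg$hidden, cfg$init, cfg$activation)
  m$opt_x <- adam_state()
  m$opt_y <- adam_state()
  class(m) <- "refiner_model"
  m
}

#' Identity-weight refiner (test helper)
#'
#' Builds a refiner whose output equals its input exactly: the hidden layer
#' encodes `relu(x) - relu(-x) = x`. Requires `hidden >= 2 * n_landmarks`.
#'
#' @inheritParams refiner_build
#' @return A `refiner_model` computing the identity map.
#' @export
refiner_identity <- function(cfg = refiner_config(), space) {
  stopifnot(cfg$hidden >= 2L * cfg$n_landmarks, cfg$activation == "relu")
  m <- refiner_build(cfg, space, seed = 1L)
  n <- cfg$n_landmarks
  net <- list(W1 = matrix(0, n, cfg$hidden), b1 = numeric(cfg$hidden),
              W2 = matrix(0, cfg$hidden, n), b2 = numeric(n))
  net$W1[, seq_len(n)] <- diag(n)
  net$W1[, n + seq_len(n)] <- -diag(n)
  net$W2[seq_len(n), ] <- diag(n)
  net$W2[n + seq_len(n), ] <- -diag(n)
  m$x <- net
  m$y <- net
  m$center_locked <- TRUE    # keep centers at zero: output == input exactly
  m
}

act_fun <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else tanh(z)
}
act_grad <- function(z, activation) {
  if (activation == "relu") (z > 0) * 1 else 1 - tanh(z)^2
}

# base: what residual mode adds to the network output (the centered,
# unwhitened input); defaults to X for unwhitened callers
axis_forward <- function(net, X, cfg, base = X) {
  Z1 <- sweep(X %*% net$W1, 2, net$b1, "+")
  H <- act_fun(Z1, cfg$activation)
  out <- sweep(H %*% net$W2, 2, net$b2, "+")
  if (cfg$residual) out <- out + base
  list(out = out, Z1 = Z1, H = H)
}

#' Refine a stage-1 landmark set
#'
#' Normalises the 23 x/y coordinates, passes each axis through its own
#' network, and denormalises. Deterministic for fixed parameters.
#'
#' @param m A [refiner_build()] model.
#' @param ls A stage-1 [landmark_set()] in the refiner's space.
#' @return A [landmark_set()] with role `"refined"`.
#' @export
refine <- function(m, ls) {
  p <- lm_coords(ls)
  if (nrow(p) != m$config$n_landmarks) stop("contract error: coordinate count mismatch")
  xc <- matrix(p[, 1] / m$norm["x"] - m$center$x, 1)
  yc <- matrix(p[, 2] / m$norm["y"] - m$center$y, 1)
  rx <- (axis_forward(m$x, xc, m$config)$out + m$center$x) * m$norm["x"]
  ry <- (axis_forward(m$y, yc, m$config)$out + m$center$y) * m$norm["y"]
  landmark_set(cbind(as.numeric(rx), as.numeric(ry)), ls$space,
               role = "refined", scheme = ls$scheme)
}

#' Per-axis refiner L2 loss
#'
#' Sum over the 23 landmarks of squared differences between predicted and
#' ground-truth coordinates of one axis.
#'
#' @param pred,gt Numeric vectors of length 23.
#' @return Nonnegative scalar.
#' @export
refiner_loss <- function(pred, gt) {
  if (length(pred) != length(gt)) stop("contract error: length mismatch")
  sum((pred - gt)^2)
}

train_axis <- function(net, opt, Xs, Xg, cfg, epochs, base = Xs) {
  n <- nrow(Xs)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      ix <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- Xs[ix, , drop = FALSE]
      gb <- Xg[ix, , drop = FALSE]
      f <- axis_forward(net, xb, cfg, base = base[ix, , drop = FALSE])
      diff <- f$out - gb
      tot <- tot + sum(diff^2)
      dout <- 2 * diff / length(ix)
      gW2 <- t(f$H) %*% dout
      gb2 <- colSums(dout)
      dH <- dout %*% t(net$W2)
      dZ1 <- dH * act_grad(f$Z1, cfg$activation)
      gW1 <- t(xb) %*% dZ1
      gb1 <- colSums(dZ1)
      grads <- list(l1 = list(W = gW1, b = gb1), l2 = list(W = gW2, b = gb2))
      params <- list(l1 = list(W = net$W1, b = net$b1), l2 = list(W = net$W2, b = net$b2))
      params <- adam_update(params, grads, opt, cfg$lr, weight_decay = cfg$weight_decay)
      net$W1 <- params$l1$W; net$b1 <- params$l1$b
      net$W2 <- params$l2$W; net$b2 <- params$l2$b
    }
    trace[ep] <- tot / n
  }
  list(net = net, trace = trace)
}

#' Train the refiner on (stage-1, ground-truth) coordinate pairs
#'
#' The axis networks are trained independently (x completely first, then y)
#' for the given number of epochs. Parameters are *not* re-initialised:
#' consecutive calls continue the same optimisation trajectory, matching the
#' persistent-refiner cycle schedule.
#'
#' @param m A [refiner_build()] model (mutated in place).
#' @param stage1,gt Equal-length lists of `landmark_set` objects in the
#'   refiner's space.
#' @param epochs Training epochs (default the configured
#'   `epochs_per_cycle`).
#' @param lr Optional learning-rate override.
#' @return Invisibly, a list with per-epoch mean losses `x` and `y`.
#' @export
refiner_train <- function(m, stage1, gt, epochs = m$config$epochs_per_cycle,
                          lr = NULL) {
  if (length(stage1) != length(gt) || length(stage1) < 1L)
    stop("data error: nonempty paired training sets required")
  cfg <- m$config
  if (!is.null(lr)) cfg$lr <- lr
  if (epochs < 1L) return(invisible(list(x = numeric(0), y = numeric(0))))
  Xs <- t(vapply(stage1, function(l) l$coords[, 1], numeric(23))) / m$norm["x"]
  Ys <- t(vapply(stage1, function(l) l$coords[, 2], numeric(23))) / m$norm["y"]
  Xg <- t(vapply(gt, function(l) l$coords[, 1], numeric(23))) / m$norm["x"]
  Yg <- t(vapply(gt, function(l) l$coords[, 2], numeric(23))) / m$norm["y"]
  if (!m$center_locked) {
    m$center <- list(x = colMeans(Xs), y = colMeans(Ys))
    m$center_locked <- TRUE
  }
  Xc <- sweep(Xs, 2, m$center$x); Yc <- sweep(Ys, 2, m$center$y)
  Xg <- sweep(Xg, 2, m$center$x)
  Yg <- sweep(Yg, 2, m$center$y)
  rx <- train_axis(m$x, m$opt_x, Xc, Xg, cfg, epochs)
  m$x <- rx$net
  ry <- train_axis(m$y, m$opt_y, Yc, Yg, cfg, epochs)
  m$y <- ry$net
  invisible(list(x = rx$trace, y = ry$trace))
}
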