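# Minimal CNN engine: static computation graphs over 4-D (H, W, C, N) arrays
# with hand-written backprop and Adam. Convolutions use precomputed-index
# im2col so the hot path is one vectorised subscript plus one BLAS matmul.
# No external deep-learning dependency exists in this stack; the networks the
# package needs are small enough that this is fast at desk scale.

nn_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$params <- list()
  g$idx_cache <- new.env(parent = emptyenv())
  g
}

nn_add_node <- function(g, name, op, inputs = character(), ...) {
  g$nodes[[name]] <- c(list(name = name, op = op, inputs = inputs), list(...))
  name
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

# conv node + optional fused relu node; returns the output node name
nn_add_conv <- function(g, name, input, in_ch, out_ch, k, stride = 1L,
                        pad = (k - 1L) %/% 2L, relu = FALSE, zero_init = FALSE) {
  fan <- k * k * in_ch
  W <- if (zero_init) matrix(0, fan, out_ch) else he_init(fan, out_ch, fan)
  g$params[[name]] <- list(W = W, b = numeric(out_ch))
  nn_add_node(g, name, "conv", input, k = as.integer(k), stride = as.integer(stride),
              pad = as.integer(pad), in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
  if (relu) nn_add_node(g, paste0(name, ":r"), "relu", name) else name
}

# im2col gather index for a padded (Hp, Wp, C, N) array.
# Row blocks are kernel-offset-major (k*k blocks of C rows); within one block
# every index is distinct, which backward exploits for vectorised scatter-add.
im2col_index <- function(g, H, W, C, k, stride, pad, N) {
  key <- paste(H, W, C, k, stride, pad, N, sep = "_")
  hit <- g$idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L; Wo <- (Wp - k) %/% stride + 1L
  ky <- rep(0:(k - 1L), times = k)
  kx <- rep(0:(k - 1L), each = k)
  plane <- Hp * Wp
  row_off <- unlist(lapply(seq_len(k * k), function(b)
    ky[b] + kx[b] * Hp + (0:(C - 1L)) * plane))
  oy <- rep(0:(Ho - 1L), times = Wo)
  ox <- rep(0:(Wo - 1L), each = Ho)
  col0 <- oy * stride + ox * stride * Hp
  col_off <- as.vector(outer(col0, (0:(N - 1L)) * plane * C, `+`))
  idx <- outer(as.integer(row_off), as.integer(col_off), `+`) + 1L
  out <- list(idx = idx, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
  g$idx_cache[[key]] <- out
  out
}

conv_forward <- function(g, nd, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  p <- nd$pad
  if (p > 0L) {
    xp <- array(0, c(H + 2L * p, W + 2L * p, C, N))
    xp[p + seq_len(H), p + seq_len(W), , ] <- x
  } else xp <- x
  ic <- im2col_index(g, H, W, C, nd$k, nd$stride, p, N)
  cols <- matrix(as.vector(xp)[as.vector(ic$idx)], nrow = nrow(ic$idx))
  par <- g$params[[nd$name]]
  out <- crossprod(par$W, cols) + par$b
  y <- aperm(array(out, c(nd$out_ch, ic$Ho, ic$Wo, N)), c(2, 3, 1, 4))
  list(y = y, cols = cols, ic = ic, in_dim = d)
}

conv_backward <- function(g, nd, cache, dy, grads) {
  d <- cache$in_dim; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  ic <- cache$ic
  dmat <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = nd$out_ch)
  gW <- cache$cols %*% t(dmat)
  gb <- rowSums(dmat)
  pg <- grads[[nd$name]]
  if (is.null(pg)) grads[[nd$name]] <- list(W = gW, b = gb)
  else grads[[nd$name]] <- list(W = pg$W + gW, b = pg$b + gb)
  dcols <- g$params[[nd$name]]$W %*% dmat
  dxp <- numeric(ic$Hp * ic$Wp * C * N)
  k2 <- nd$k * nd$k
  for (b in seq_len(k2)) {
    rows <- ((b - 1L) * C + 1L):(b * C)
    ii <- as.vector(ic$idx[rows, , drop = FALSE])
    dxp[ii] <- dxp[ii] + as.vector(dcols[rows, , drop = FALSE])
  }
  dxp <- array(dxp, c(ic$Hp, ic$Wp, C, N))
  p <- nd$pad
  dx <- if (p > 0L) dxp[p + seq_len(H), p + seq_len(W), , , drop = FALSE] else dxp
  list(dx = dx, grads = grads)
}

upsample_nn <- function(x, f) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , , drop = FALSE]
}

upsample_nn_back <- function(dy, f) {
  d <- dim(dy)                                 # (H*f, W*f, C, N)
  H <- d[1] %/% f; W <- d[2] %/% f
  s1 <- colSums(array(dy, c(f, H * d[2] * d[3] * d[4])))       # over row factor
  t1 <- array(s1, c(H, f, W * d[3] * d[4]))
  s2 <- colSums(aperm(t1, c(2, 1, 3)))                          # over col factor
  array(s2, c(H, W, d[3], d[4]))
}

# Forward pass; keeps every node value plus conv caches for backward.
nn_forward <- function(g, x, keep = TRUE) {
  vals <- list(input = x)
  caches <- list()
  for (nd in g$nodes) {
    v <- switch(nd$op,
      input = x,
      conv = {
        cf <- conv_forward(g, nd, vals[[nd$inputs]])
        if (keep) caches[[nd$name]] <- cf[c("cols", "ic", "in_dim")]
        cf$y
      },
      relu = pmax(vals[[nd$inputs]], 0),
      add = Reduce(`+`, vals[nd$inputs]),
      upsample = upsample_nn(vals[[nd$inputs]], nd$factor),
      concat = {
        xs <- vals[nd$inputs]
        d1 <- dim(xs[[1]])
        cs <- vapply(xs, function(a) dim(a)[3], 0L)
        y <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
        at <- 0L
        for (a in xs) { y[, , at + seq_len(dim(a)[3]), ] <- a; at <- at + dim(a)[3] }
        y
      },
      stop("unknown op ", nd$op))
    vals[[nd$name]] <- v
  }
  list(vals = vals, caches = caches)
}

# Backward pass from d(loss)/d(output); returns param gradients.
nn_backward <- function(g, fwd, dout) {
  grads <- list()
  dvals <- list()
  dvals[[g$output]] <- dout
  for (nd in rev(g$nodes)) {
    dy <- dvals[[nd$name]]
    if (is.null(dy) || nd$op == "input") next
    push <- function(nm, dv) {
      dvals[[nm]] <<- if (is.null(dvals[[nm]])) dv else dvals[[nm]] + dv
    }
    switch(nd$op,
      conv = {
        bk <- conv_backward(g, nd, fwd$caches[[nd$name]], dy, grads)
        grads <- bk$grads
        push(nd$inputs, bk$dx)
      },
      relu = push(nd$inputs, dy * (fwd$vals[[nd$inputs]] > 0)),
      add = for (nm in nd$inputs) push(nm, dy),
      upsample = push(nd$inputs, upsample_nn_back(dy, nd$factor)),
      concat = {
        at <- 0L
        for (nm in nd$inputs) {
          nc <- dim(fwd$vals[[nm]])[3]
          push(nm, dy[, , at + seq_len(nc), , drop = FALSE])
          at <- at + nc
        }
      })
    dvals[[nd$name]] <- NULL
  }
  grads
}

# ---- Adam ----

adam_state <- function() {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- list()
  st$v <- list()
  st
}

adam_update <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    for (slot in names(grads[[nm]])) {
      gkey <- paste0(nm, ".", slot)
      gr <- grads[[nm]][[slot]]
      if (weight_decay > 0 && slot == "W")
        gr <- gr + weight_decay * params[[nm]][[slot]]
      m <- st$m[[gkey]]; v <- st$v[[gkey]]
      if (is.null(m)) { m <- gr * 0; v <- gr * 0 }
      m <- beta1 * m + (1 - beta1) * gr
      v <- beta2 * v + (1 - beta2) * gr^2
      st$m[[gkey]] <- m; st$v[[gkey]] <- v
      params[[nm]][[slot]] <- params[[nm]][[slot]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  params
}
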