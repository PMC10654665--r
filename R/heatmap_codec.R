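#' Heatmap stack container
#'
#' 23 nonnegative grids at reduced resolution, one per landmark, plus the
#' Gaussian sigma and the spatial link back to model-input space.
#'
#' @param maps A (h, w, 23) numeric array.
#' @param sigma Gaussian standard deviation in heatmap pixels.
#' @param link A [crop_transform()] mapping model-input coordinates to heatmap
#'   coordinates (scale `1/r` for resolution reduction factor `r`).
#' @param scheme An [lm_scheme()].
#' @param normalized Logical, whether channels carry the normalised Gaussian
#'   (peak `1/(2*pi*sigma^2)`) or the peak-1 variant.
#' @return An object of class `heatmap_stack`.
#' @export
heatmap_stack <- function(maps, sigma, link, scheme = lm_scheme(), normalized = TRUE) {
  d <- dim(maps)
  if (length(d) != 3L || d[3] != 23L) stop("heatmap stack must be (h, w, 23)")
  if (!all(is.finite(maps))) stop("heatmap values must be finite")
  structure(list(maps = maps, sigma = sigma, link = link, scheme = scheme,
                 normalized = normalized),
            class = "heatmap_stack")
}

#' Encode landmarks as Gaussian heatmaps
#'
#' Each channel holds the 2D Gaussian
#' \deqn{h_i(x) = \frac{1}{2\pi\sigma^2} \exp\!\left(-\frac{\lVert x - L_i\rVert^2}{2\sigma^2}\right)}
#' centred on the ground-truth landmark mapped into heatmap space
#' (input coordinates divided by the reduction factor `r`). With
#' `normalized = FALSE` the channel is divided by the central value so the
#' peak is 1. Landmarks outside the grid are encoded as truncated tails,
#' never rejected, so crops cannot crash training.
#'
#' @param ls A [landmark_set()] with coordinates in model-input space.
#' @param sigma Positive Gaussian sd in heatmap pixels (default 1.5; the
#'   convention for quarter-resolution facial-landmark heatmaps — the original
#'   method leaves it unstated).
#' @param grid `c(h, w)` heatmap grid shape.
#' @param r Resolution reduction factor from input to heatmap (default 4).
#' @param normalized Logical; `TRUE` gives the literal normalised form.
#' @return A [heatmap_stack()].
#' @export
hm_encode <- function(ls, sigma = 1.5, grid = NULL, r = 4, normalized = TRUE) {
  if (!is.finite(sigma) || sigma <= 0) stop("parameter error: sigma must be > 0")
  if (is.null(grid))
    grid <- c(ls$space$height_px %/% r, ls$space$width_px %/% r)
  h <- grid[1]; w <- grid[2]
  pk <- lm_coords(ls) / r                     # heatmap-space coordinates
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  maps <- array(0, c(h, w, 23))
  norm <- 1 / (2 * pi * sigma^2)
  for (i in 1:23) {
    gx <- exp(-(xs - pk[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - pk[i, 2])^2 / (2 * sigma^2))
    m <- norm * outer(gy, gx)                 # rows = y, cols = x
    if (!normalized) {
      m <- m / norm                           # peak value 1 at the exact centre
    }
    maps[, , i] <- m
  }
  link <- crop_transform(scale = 1 / r)
  heatmap_stack(maps, sigma, link, ls$scheme, normalized)
}

#' Decode heatmaps to sub-pixel landmark coordinates
#'
#' Per channel: take the argmax (ties broken by row-major first occurrence),
#' then — when `offset = TRUE` — shift the peak by 0.25 heatmap px along each
#' axis toward the larger of the two axis-neighbours ("largest toward second
#' largest" adjustment; no shift on an axis where the peak is on the border or
#' the neighbours are equal). The result is mapped back through the heatmap
#' link to model-input coordinates and, if `crop` is given, through the
#' inverse crop to original-image coordinates.
#'
#' @param hs A [heatmap_stack()].
#' @param offset Logical, apply the quarter-pixel offset (default `TRUE`).
#' @param crop Optional [crop_transform()] from the original image space to
#'   model-input space; when supplied, outputs are unmapped into that
#'   original space.
#' @param space An [image_space()] for the returned set (defaults to a space
#'   matching the decode target grid with 0.35 mm/px).
#' @return A [landmark_set()] with role `"stage1"`.
#' @export
hm_decode <- function(hs, offset = TRUE, crop = NULL, space = NULL) {
  d <- dim(hs$maps)
  h <- d[1]; w <- d[2]
  out <- matrix(0, 23, 2)
  for (i in 1:23) {
    m <- hs$maps[, , i]
    j <- which.max(t(m))                       # row-major first occurrence on ties
    if (max(m) == min(m)) stop(sprintf("decode error: channel %d has no strict maximum", i))
    cx <- (j - 1L) %% w + 1L
    ry <- (j - 1L) %/% w + 1L
    px <- cx - 1; py <- ry - 1                 # pixel-center coordinates
    if (offset) {
      if (cx > 1L && cx < w) {
        l <- m[ry, cx - 1L]; rgt <- m[ry, cx + 1L]
        if (rgt > l) px <- px + 0.25 else if (l > rgt) px <- px - 0.25
      }
      if (ry > 1L && ry < h) {
        up <- m[ry - 1L, cx]; dn <- m[ry + 1L, cx]
        if (dn > up) py <- py + 0.25 else if (up > dn) py <- py - 0.25
      }
    }
    out[i, ] <- c(px, py)
  }
  out <- ct_unmap(hs$link, out)                # heatmap -> input space
  if (!is.null(crop)) out <- ct_unmap(crop, out)
  if (is.null(space)) {
    side_w <- round(w / hs$link$scale); side_h <- round(h / hs$link$scale)
    if (!is.null(crop) && !is.null(crop$src_space)) space <- crop$src_space
    else space <- image_space(side_w, side_h)
  }
  landmark_set(out, space, role = "stage1", scheme = hs$scheme)
}

#' Summed L2 heatmap loss
#'
#' Sum over the 23 channels of the squared element-wise differences between
#' ground-truth and predicted heatmaps (the heatmap-regression training loss).
#'
#' @param gt,pred `heatmap_stack` objects or plain (h, w, 23) arrays of
#'   matching shape.
#' @return Nonnegative scalar.
#' @export
hm_l2_loss <- function(gt, pred) {
  a <- if (inherits(gt, "heatmap_stack")) gt$maps else gt
  b <- if (inherits(pred, "heatmap_stack")) pred$maps else pred
  if (!identical(dim(a), dim(b))) stop("contract error: heatmap shape mismatch")
  sum((a - b)^2)
}
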