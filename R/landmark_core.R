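#' Landmark scheme for the 23-point cephalometric set
#'
#' A `lm_scheme` records the fixed landmark count (23) and the ordered landmark
#' labels. Indices are 1-based and contiguous. Only the index/name pairs that
#' are fixed by the clinical measure recipes are pre-filled with anatomical
#' aliases (L1 sella, L2 nasion, L5 A-point, L6 B-point, L8 menton,
#' L10 gonion); every name can be overridden.
#'
#' @param names Optional character vector of 23 unique landmark labels.
#' @return An object of class `lm_scheme`.
#' @export
lm_scheme <- function(names = NULL) {
  if (is.null(names)) {
    names <- paste0("L", 1:23)
    alias <- c(L1 = "sella", L2 = "nasion", L5 = "A-point", L6 = "B-point",
               L8 = "menton", L10 = "gonion")
  } else {
    alias <- character()
  }
  if (length(names) != 23L) stop("a landmark scheme must have exactly 23 names")
  if (anyDuplicated(names)) stop("landmark names must be unique")
  structure(list(count = 23L, names = as.character(names), aliases = alias),
            class = "lm_scheme")
}

#' Image coordinate space
#'
#' Declares the pixel grid and physical pixel spacing of an image. The origin
#' convention is fixed across the package: x grows rightward, y grows downward,
#' and coordinate (0, 0) is the *center* of the top-left pixel (pixel-center
#' model). Coordinates are real-valued pixels.
#'
#' @param width_px,height_px Integer grid dimensions (>= 1).
#' @param mm_per_px Physical pixel spacing in millimetres (default 0.35, the
#'   spacing of the profile imaging device the pipeline targets).
#' @return An object of class `image_space`.
#' @export
image_space <- function(width_px, height_px, mm_per_px = 0.35) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px < 1L || height_px < 1L) stop("image dimensions must be >= 1 pixel")
  if (!is.finite(mm_per_px) || mm_per_px <= 0) stop("mm_per_px must be a positive real")
  structure(list(width_px = width_px, height_px = height_px,
                 mm_per_px = mm_per_px),
            class = "image_space")
}

#' Set of 23 landmark coordinates
#'
#' @param coords A 23 x 2 numeric matrix of (x, y) pixel coordinates
#'   (pixel-center convention, y down), all finite.
#' @param space An [image_space()].
#' @param role One of `"ground_truth"`, `"stage1"`, `"refined"` — whether the
#'   set is an annotation, a raw heatmap-decoded prediction, or an
#'   MLP-refined prediction.
#' @param scheme An [lm_scheme()].
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(coords, space, role = c("ground_truth", "stage1", "refined"),
                         scheme = lm_scheme()) {
  role <- match.arg(role)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || nrow(coords) != 23L || ncol(coords) != 2L)
    stop("coords must be a 23 x 2 numeric matrix")
  if (!all(is.finite(coords))) stop("landmark coordinates must all be finite")
  dimnames(coords) <- list(scheme$names, c("x", "y"))
  structure(list(coords = coords, space = space, role = role, scheme = scheme),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> role=%s space=%dx%d @ %g mm/px\n",
              x$role, x$space$width_px, x$space$height_px, x$space$mm_per_px))
  print(utils::head(x$coords, 4))
  cat("  ... 23 landmarks total\n")
  invisible(x)
}

#' Isotropic crop/resize transform between two coordinate spaces
#'
#' Maps source-space pixel coordinates to target-space coordinates by
#' `(p - offset) * scale`. Used for the model-input crop (full image to the
#' network input side) and for the heatmap-resolution link.
#'
#' @param scale Positive isotropic scale factor (target px per source px).
#' @param offset Length-2 numeric, crop origin (x0, y0) in source pixels.
#' @param src_space,dst_space Optional [image_space()] metadata.
#' @return An object of class `crop_transform`.
#' @export
crop_transform <- function(scale, offset = c(0, 0), src_space = NULL, dst_space = NULL) {
  if (!is.finite(scale) || scale <= 0) stop("crop scale must be > 0")
  structure(list(scale = scale, offset = as.numeric(offset),
                 src_space = src_space, dst_space = dst_space),
            class = "crop_transform")
}

#' Apply / invert a crop transform
#'
#' `ct_map()` sends source coordinates to target coordinates,
#' `ct_unmap()` inverts it; the round trip is the identity to machine
#' precision.
#'
#' @param ct A [crop_transform()].
#' @param p An n x 2 matrix (or length-2 vector) of coordinates.
#' @return Coordinates of the same shape as `p`.
#' @export
ct_map <- function(ct, p) {
  p <- rbind2mat(p)
  sweep(p, 2, ct$offset, "-") * ct$scale
}

#' @rdname ct_map
#' @export
ct_unmap <- function(ct, p) {
  p <- rbind2mat(p)
  sweep(p / ct$scale, 2, ct$offset, "+")
}

rbind2mat <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 2) else as.matrix(p)
}

#' Convert a pixel displacement to millimetres
#'
#' @param x An [image_space()] or [landmark_set()] carrying `mm_per_px`.
#' @param delta_px Numeric displacement(s) in pixels.
#' @return `delta_px * mm_per_px`.
#' @export
to_mm <- function(x, delta_px) {
  sp <- if (inherits(x, "landmark_set")) x$space else x
  if (!inherits(sp, "image_space") || is.null(sp$mm_per_px))
    stop("unit error: no mm_per_px available")
  delta_px * sp$mm_per_px
}

#' Unsigned angle at a vertex, in degrees
#'
#' Angle in `[0, 180]` between the rays `v -> a` and `v -> b`. For a measure
#' stated as "the angle between A, B, C" the middle listed point B is the
#' vertex (clinical convention for ANB/SNA/SNB).
#'
#' @param a,v,b Length-2 numeric points; `a != v`, `b != v`.
#' @return Angle in degrees.
#' @export
angle_at_vertex <- function(a, v, b) {
  u <- as.numeric(a) - as.numeric(v)
  w <- as.numeric(b) - as.numeric(v)
  if (all(u == 0) || all(w == 0))
    stop("geometry error: degenerate angle (ray endpoint equals vertex)")
  cr <- u[1] * w[2] - u[2] * w[1]
  dt <- sum(u * w)
  atan2(abs(cr), dt) * 180 / pi
}

#' Angle between two lines, in degrees
#'
#' Unsigned mode returns the acute angle in `[0, 90]`. Signed mode returns an
#' angle in `(-90, 90]` whose sign is the rotation from line 1 (oriented
#' `p1 -> p2`) to line 2 (oriented `q1 -> q2`), counterclockwise positive in
#' the package's image coordinate sense (x right, y down).
#'
#' @param p1,p2 Endpoints of line 1 (distinct).
#' @param q1,q2 Endpoints of line 2 (distinct).
#' @param signed Logical; default `FALSE`.
#' @return Angle in degrees.
#' @export
angle_between_lines <- function(p1, p2, q1, q2, signed = FALSE) {
  d1 <- as.numeric(p2) - as.numeric(p1)
  d2 <- as.numeric(q2) - as.numeric(q1)
  if (all(d1 == 0) || all(d2 == 0)) stop("geometry error: zero-length line")
  cr <- d1[1] * d2[2] - d1[2] * d2[1]
  dt <- sum(d1 * d2)
  ang <- atan2(cr, dt) * 180 / pi        # (-180, 180]
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180       # (-90, 90]
  if (signed) ang else abs(ang)
}

#' Euclidean distance between two points
#'
#' @param p,q Length-2 numeric points.
#' @param space An [image_space()]; required when `unit = "mm"`.
#' @param unit `"px"` (default) or `"mm"`.
#' @return Nonnegative distance.
#' @export
point_distance <- function(p, q, space = NULL, unit = c("px", "mm")) {
  unit <- match.arg(unit)
  d <- sqrt(sum((as.numeric(p) - as.numeric(q))^2))
  if (unit == "mm") {
    if (is.null(space)) stop("unit error: space with mm_per_px required for mm")
    d <- to_mm(space, d)
  }
  d
}

# internal: landmark coordinates as matrix, with validation
lm_coords <- function(ls) {
  stopifnot(inherits(ls, "landmark_set"))
  ls$coords
}
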