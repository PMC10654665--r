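#' Definitions of the eight clinical cephalometric measures
#'
#' Returns the geometric recipe and three-way classification bands for ANB,
#' SNB, SNA, ODI, APDI, FHI, FMA and MW (modified Wits). Angles are in
#' degrees, FHI is a dimensionless ratio, MW is in millimetres. Each measure
#' classifies into `type1` (the normal interval, inclusive at both ends),
#' with values above/below mapping to `type2`/`type3` per the clinical band
#' table. Three printed bands are inconsistent in the source table and are
#' corrected here (documented, overridable):
#' * SNB: retrognathic below 74.6, prognathic above 78.7 (printed directions
#'   are swapped and contradictory).
#' * ODI: open tendency below the normal lower bound 78.4 (printed 68.4
#'   leaves a gap).
#' * MW: edge-to-edge side below 2 mm (printed as the single value 0 mm).
#'
#' @param overrides Optional named list of per-measure band overrides, each
#'   `list(lo =, hi =, above =, below =)`.
#' @return Named list of measure definitions.
#' @export
measure_definitions <- function(overrides = NULL) {
  defs <- list(
    ANB  = list(unit = "deg",   lo = 3.2,  hi = 5.7,  above = "type2", below = "type3"),
    SNB  = list(unit = "deg",   lo = 74.6, hi = 78.7, above = "type3", below = "type2"),
    SNA  = list(unit = "deg",   lo = 79.4, hi = 83.2, above = "type2", below = "type3"),
    ODI  = list(unit = "deg",   lo = 78.4, hi = 80.5, above = "type2", below = "type3"),
    APDI = list(unit = "deg",   lo = 77.6, hi = 85.2, above = "type3", below = "type2"),
    FHI  = list(unit = "ratio", lo = 0.65, hi = 0.75, above = "type2", below = "type3"),
    FMA  = list(unit = "deg",   lo = 26.8, hi = 31.4, above = "type2", below = "type3"),
    MW   = list(unit = "mm",    lo = 2.0,  hi = 4.5,  above = "type3", below = "type2")
  )
  for (nm in names(overrides)) defs[[nm]] <- utils::modifyList(defs[[nm]], overrides[[nm]])
  defs
}

#' Compute one clinical measure from a landmark set
#'
#' Recipes (landmark indices are 1-based):
#' * ANB: angle at L2 between L5 and L6; SNB: at L2 between L1 and L6;
#'   SNA: at L2 between L1 and L5.
#' * ODI: signed line angle (L5-L6, L8-L10) + signed line angle
#'   (L3-L4, L17-L18).
#' * APDI: signed (L3-L4, L2-L7) + signed (L2-L7, L5-L6) + signed
#'   (L3-L4, L17-L18).
#' * FHI: dist(L1, L10) / dist(L2, L8) (posterior over anterior face height).
#' * FMA: unsigned line angle between L1-L2 and L10-L9.
#' * MW: dist(L12, L11) in mm.
#'
#' @param name One of `"ANB"`, `"SNB"`, `"SNA"`, `"ODI"`, `"APDI"`, `"FHI"`,
#'   `"FMA"`, `"MW"`.
#' @param ls A [landmark_set()].
#' @return Scalar measure value.
#' @export
compute_measure <- function(name, ls) {
  p <- lm_coords(ls)
  L <- function(i) p[i, ]
  sgn <- function(a, b, c, d) angle_between_lines(L(a), L(b), L(c), L(d), signed = TRUE)
  val <- tryCatch(switch(name,
    ANB  = angle_at_vertex(L(5), L(2), L(6)),
    SNB  = angle_at_vertex(L(1), L(2), L(6)),
    SNA  = angle_at_vertex(L(1), L(2), L(5)),
    ODI  = sgn(5, 6, 8, 10) + sgn(3, 4, 17, 18),
    APDI = sgn(3, 4, 2, 7) + sgn(2, 7, 5, 6) + sgn(3, 4, 17, 18),
    FHI  = point_distance(L(1), L(10)) / point_distance(L(2), L(8)),
    FMA  = angle_between_lines(L(1), L(2), L(10), L(9)),
    MW   = point_distance(L(12), L(11), ls$space, unit = "mm"),
    stop("unknown measure: ", name)
  ), error = function(e) stop(sprintf("measure error in %s: %s", name, conditionMessage(e))))
  if (name == "FHI" && !is.finite(val)) stop("measure error in FHI: zero anterior face height")
  val
}

#' Compute all eight measures
#'
#' @param ls A [landmark_set()].
#' @param defs Definitions from [measure_definitions()].
#' @return Named numeric vector of length 8.
#' @export
compute_measures <- function(ls, defs = measure_definitions()) {
  vapply(names(defs), compute_measure, 0, ls = ls)
}

#' Classify a measure value into one of three anatomical face types
#'
#' The normal interval `[lo, hi]` is inclusive at both ends and maps to
#' `type1`; values above `hi` map to the measure's above-class, values below
#' `lo` to its below-class. Exactly one label for every finite value.
#'
#' @param def A single definition from [measure_definitions()].
#' @param value Finite numeric value.
#' @return `"type1"`, `"type2"` or `"type3"`.
#' @export
classify_measure <- function(def, value) {
  if (!is.finite(value)) stop("value error: non-finite measure value")
  if (value > def$hi) def$above else if (value < def$lo) def$below else "type1"
}

#' Classify all eight measures of a landmark set
#'
#' @inheritParams compute_measures
#' @return Named character vector of face-type labels.
#' @export
classify_measures <- function(ls, defs = measure_definitions()) {
  v <- compute_measures(ls, defs)
  vapply(names(defs), function(nm) classify_measure(defs[[nm]], v[[nm]]), "")
}

#' Successful classification rate over paired image sets
#'
#' For every image, the eight measures are computed and classified from both
#' the ground-truth and the predicted landmarks; the SCR of a measure is the
#' percentage of images on which the two classes agree.
#'
#' @param gts,preds Equal-length lists of `landmark_set` objects.
#' @param defs Definitions from [measure_definitions()].
#' @return An object of class `measure_report`: per-image values/classes and
#'   the per-measure SCR vector (percent).
#' @export
scr_report <- function(gts, preds, defs = measure_definitions()) {
  if (length(gts) != length(preds) || length(gts) < 1L)
    stop("contract error: paired sets of equal positive length required")
  nms <- names(defs)
  vals_g <- t(vapply(gts, compute_measures, numeric(8), defs = defs))
  vals_p <- t(vapply(preds, compute_measures, numeric(8), defs = defs))
  cls <- function(vals) vapply(nms, function(nm)
    vapply(vals[, nm], function(v) classify_measure(defs[[nm]], v), ""), character(nrow(vals)))
  cg <- matrix(cls(vals_g), ncol = 8, dimnames = list(NULL, nms))
  cp <- matrix(cls(vals_p), ncol = 8, dimnames = list(NULL, nms))
  scr <- vapply(nms, function(nm) 100 * mean(cg[, nm] == cp[, nm]), 0)
  structure(list(values_gt = vals_g, values_pred = vals_p,
                 classes_gt = cg, classes_pred = cp, scr = scr, n = length(gts)),
            class = "measure_report")
}

#' @export
print.measure_report <- function(x, ...) {
  cat(sprintf("<measure_report> n=%d images\n  SCR (%%): ", x$n))
  cat(paste(sprintf("%s %.2f", names(x$scr), x$scr), collapse = "  "), "\n")
  invisible(x)
}

#' Write a measure report (per-image CSV + SCR JSON)
#'
#' @param report An [scr_report()] result.
#' @param prefix Output prefix; writes `<prefix>_measures.csv` and
#'   `<prefix>_scr.json`.
#' @return Invisibly, the two paths.
#' @export
write_measure_report <- function(report, prefix) {
  csv <- paste0(prefix, "_measures.csv")
  js <- paste0(prefix, "_scr.json")
  df <- data.frame(image_id = sprintf("img%04d", seq_len(report$n)))
  for (nm in colnames(report$values_pred)) {
    df[[paste0(nm, "_value")]] <- report$values_pred[, nm]
    df[[paste0(nm, "_class")]] <- report$classes_pred[, nm]
  }
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(as.list(report$scr), js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
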