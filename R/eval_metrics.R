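#' Per-landmark radial errors between a prediction and the ground truth
#'
#' Computes, in millimetres, the absolute per-axis differences `dx`, `dy` and
#' the radial error `R = sqrt(dx^2 + dy^2)` for each of the 23 landmarks.
#'
#' @param pred,gt `landmark_set` objects in the same space/scheme with
#'   `mm_per_px` set.
#' @param image_id Optional identifier recorded in the output.
#' @return A data frame with columns `image_id`, `landmark`, `dx_mm`,
#'   `dy_mm`, `r_mm`.
#' @export
radial_errors <- function(pred, gt, image_id = NA_character_) {
  if (!identical(pred$scheme$names, gt$scheme$names))
    stop("contract error: landmark scheme mismatch")
  if (pred$space$width_px != gt$space$width_px ||
      pred$space$height_px != gt$space$height_px ||
      pred$space$mm_per_px != gt$space$mm_per_px)
    stop("contract error: image space mismatch")
  mm <- gt$space$mm_per_px
  dx <- abs(pred$coords[, 1] - gt$coords[, 1]) * mm
  dy <- abs(pred$coords[, 2] - gt$coords[, 2]) * mm
  data.frame(image_id = image_id, landmark = seq_len(23L),
             dx_mm = dx, dy_mm = dy, r_mm = sqrt(dx^2 + dy^2),
             row.names = NULL)
}

#' Radial errors over paired lists of landmark sets
#'
#' @param preds,gts Equal-length lists of `landmark_set` objects.
#' @return Row-bound [radial_errors()] data frame, one image id per pair.
#' @export
radial_errors_set <- function(preds, gts) {
  if (length(preds) != length(gts) || length(preds) < 1L)
    stop("contract error: paired sets of equal positive length required")
  do.call(rbind, lapply(seq_along(preds), function(i)
    radial_errors(preds[[i]], gts[[i]], image_id = sprintf("img%04d", i))))
}

#' Summarise radial errors into MRE / SD / SDR
#'
#' MRE is the mean radial error, SD the sample standard deviation (n - 1
#' denominator) of the pooled radial errors, and SDR the percentage of
#' landmarks whose radial error is within (<=, inclusive) each threshold.
#' Per-landmark rows mirror the aggregate, grouped by landmark index.
#'
#' @param errors A [radial_errors()] data frame (possibly over many images).
#' @param thresholds SDR thresholds in mm, default `c(2, 2.5, 3, 4)`.
#' @return An object of class `metrics_report`: list with `per_landmark`
#'   data frame, `overall` list (mre, sd, dx/dy means and sds, sdr vector,
#'   n), and `thresholds`. SD over a single value is reported as `NA`
#'   (undefined), never 0.
#' @export
metrics_summary <- function(errors, thresholds = c(2, 2.5, 3, 4)) {
  if (nrow(errors) < 1L) stop("data error: no errors to summarise")
  sdr_of <- function(r) vapply(thresholds, function(t) 100 * mean(r <= t), 0)
  sd_or_na <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)
  agg <- function(df) {
    s <- c(mre = mean(df$r_mm), sd = sd_or_na(df$r_mm),
           dx = mean(df$dx_mm), dx_sd = sd_or_na(df$dx_mm),
           dy = mean(df$dy_mm), dy_sd = sd_or_na(df$dy_mm))
    list(stats = s, sdr = sdr_of(df$r_mm), n = nrow(df))
  }
  per <- lapply(split(errors, errors$landmark), agg)
  per_landmark <- do.call(rbind, lapply(names(per), function(k) {
    a <- per[[k]]
    cbind(data.frame(landmark = as.integer(k)),
          as.data.frame(as.list(a$stats)),
          as.data.frame(as.list(stats::setNames(a$sdr, paste0("sdr_", thresholds)))),
          data.frame(n = a$n))
  }))
  per_landmark <- per_landmark[order(per_landmark$landmark), , drop = FALSE]
  rownames(per_landmark) <- NULL
  ov <- agg(errors)
  structure(list(per_landmark = per_landmark,
                 overall = list(mre = unname(ov$stats["mre"]), sd = unname(ov$stats["sd"]),
                                dx = unname(ov$stats["dx"]), dx_sd = unname(ov$stats["dx_sd"]),
                                dy = unname(ov$stats["dy"]), dy_sd = unname(ov$stats["dy_sd"]),
                                sdr = stats::setNames(ov$sdr, paste0("sdr_", thresholds)),
                                n = ov$n),
                 thresholds = thresholds),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<metrics_report> n=%d landmarks pooled\n", o$n))
  cat(sprintf("  MRE %.4f mm  SD %s mm\n", o$mre,
              if (is.na(o$sd)) "NA" else sprintf("%.4f", o$sd)))
  cat("  SDR:", paste(sprintf("%.2f%%@%gmm", o$sdr, x$thresholds), collapse = "  "), "\n")
  invisible(x)
}

#' Write a metrics report to CSV + JSON
#'
#' The CSV mirrors the per-landmark evaluation table layout (landmark, MRE,
#' SD, dx, dx SD, dy, dy SD, SDR at each threshold); the JSON carries the
#' aggregate.
#'
#' @param report A [metrics_summary()] result.
#' @param prefix Output path prefix; writes `<prefix>_per_landmark.csv` and
#'   `<prefix>_overall.json`.
#' @return Invisibly, the two paths.
#' @export
write_metrics_report <- function(report, prefix) {
  csv <- paste0(prefix, "_per_landmark.csv")
  js <- paste0(prefix, "_overall.json")
  utils::write.csv(report$per_landmark, csv, row.names = FALSE)
  jsonlite::write_json(report$overall, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
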