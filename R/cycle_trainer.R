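#' Alternating two-stage training schedule
#'
#' One cycle = one backbone epoch followed by `refiner_epochs` refiner epochs
#' on pairs freshly decoded from the current backbone state. The refiner's
#' parameters persist across cycles. The backbone learning-rate milestones
#' follow the published schedule interpreted per cycle (one backbone epoch
#' per cycle makes epochs and cycles coincide): base 1e-4, dropping by
#' `lr_factor` at the milestone cycles (30 and 50 of 60 at full scale).
#'
#' @param cycles Total cycles (>= 0).
#' @param refiner_epochs Refiner epochs per cycle (100).
#' @param base_lr Backbone base learning rate.
#' @param lr_milestones Cycles at which the backbone lr is multiplied by
#'   `lr_factor` (cumulative).
#' @param lr_factor Multiplicative decay at each milestone (0.1).
#' @param batch_size Backbone mini-batch size (16).
#' @param refiner_lr Optional refiner learning-rate override for desk-scale
#'   runs; `NULL` keeps the refiner config's own rate (full-scale 1e-5,
#'   which assumes thousands of cycles of persistent training).
#' @param seed Integer seed for the run.
#' @return An object of class `cycle_schedule`.
#' @export
cycle_schedule <- function(cycles = 60L, refiner_epochs = 100L, base_lr = 1e-4,
                           lr_milestones = c(30L, 50L), lr_factor = 0.1,
                           batch_size = 16L, refiner_lr = NULL, seed = 1L) {
  if (is.unsorted(lr_milestones)) stop("lr milestones must be sorted")
  structure(list(cycles = as.integer(cycles), refiner_epochs = as.integer(refiner_epochs),
                 base_lr = base_lr, lr_milestones = as.integer(lr_milestones),
                 lr_factor = lr_factor, batch_size = as.integer(batch_size),
                 refiner_lr = refiner_lr, seed = as.integer(seed)),
            class = "cycle_schedule")
}

cycle_lr <- function(sched, cycle) {
  sched$base_lr * sched$lr_factor^sum(cycle >= sched$lr_milestones)
}

dataset_mre <- function(preds, gts) {
  metrics_summary(radial_errors_set(preds, gts))$overall$mre
}

# decode current backbone predictions on a dataset, in original space
decode_dataset <- function(bm, data, chunk = 16L) {
  n <- dim(data$images)[4]
  out <- vector("list", n)
  for (start in seq(1L, n, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n)
    pred <- backbone_forward(bm, data$images[, , , ix, drop = FALSE])
    out[ix] <- decode_batch(pred, r = data$r, crop = data$crop, sigma = data$sigma)
  }
  out
}

#' Run the alternating cycle schedule
#'
#' Per cycle: one backbone epoch on the heatmap loss, a fresh decode of the
#' training set through the current backbone, `refiner_epochs` refiner epochs
#' on the (decoded, ground-truth) pairs, then train/eval MRE of the refined
#' predictions. Emits a per-cycle trace (cycle, backbone_loss, refiner_loss,
#' train_mre_mm, eval_mre_mm) suitable for learning-curve plots. Both models
#' are mutated in place; the refiner is never re-initialised.
#'
#' @param sched A [cycle_schedule()].
#' @param bm A [backbone_build()] model.
#' @param rm A [refiner_build()] model (over the dataset's original space).
#' @param train,eval `lp_dataset` objects from [make_training_set()].
#' @return Data frame trace with one row per cycle.
#' @export
run_cycles <- function(sched, bm, rm, train, eval = NULL) {
  if (is.null(dim(train$images)) || dim(train$images)[4] < 1L)
    stop("data error: empty training set")
  trace <- data.frame(cycle = integer(), backbone_loss = numeric(),
                      refiner_loss = numeric(), train_mre_mm = numeric(),
                      eval_mre_mm = numeric())
  if (sched$cycles < 1L) return(trace)
  set.seed(sched$seed)
  for (cyc in seq_len(sched$cycles)) {
    lr <- cycle_lr(sched, cyc)
    bl <- backbone_train_epoch(bm, train$images, train$heatmaps, lr = lr,
                               batch_size = sched$batch_size)
    if (!is.finite(bl)) stop(sprintf("training error: non-finite backbone loss at cycle %d", cyc))
    s1 <- decode_dataset(bm, train)
    rl <- refiner_train(rm, s1, train$gt, epochs = sched$refiner_epochs,
                        lr = sched$refiner_lr)
    rloss <- mean(c(utils::tail(rl$x, 1), utils::tail(rl$y, 1)))
    if (!is.finite(rloss)) stop(sprintf("training error: non-finite refiner loss at cycle %d", cyc))
    refined <- lapply(s1, refine, m = rm)
    tmre <- dataset_mre(refined, train$gt)
    emre <- NA_real_
    if (!is.null(eval)) {
      e1 <- decode_dataset(bm, eval)
      emre <- dataset_mre(lapply(e1, refine, m = rm), eval$gt)
    }
    trace <- rbind(trace, data.frame(cycle = cyc, backbone_loss = bl,
                                     refiner_loss = rloss, train_mre_mm = tmre,
                                     eval_mre_mm = emre))
  }
  trace
}

#' Evaluate a checkpoint with and without the refiner
#'
#' Decodes the backbone's predictions once and summarises them twice — raw
#' stage-1 and MLP-refined — over the same decoded coordinates (the ablation
#' contract).
#'
#' @param bm A backbone model.
#' @param rm A refiner model.
#' @param data An `lp_dataset`.
#' @return List with `stage1` and `refined` [metrics_summary()] reports.
#' @export
evaluate_checkpoint <- function(bm, rm, data) {
  s1 <- decode_dataset(bm, data)
  list(stage1 = metrics_summary(radial_errors_set(s1, data$gt)),
       refined = metrics_summary(radial_errors_set(lapply(s1, refine, m = rm), data$gt)))
}
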