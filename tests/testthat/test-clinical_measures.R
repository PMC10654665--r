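# landmark set where ANB is controlled: vertex L2 at origin-ish
anb_ls <- function() {
  p <- lm_coords(template_ls())
  p[5, ] <- c(0, 100); p[2, ] <- c(0, 0); p[6, ] <- c(5, 100)
  landmark_set(p, space_1200())
}

test_that("measure recipes match hand geometry", {
  ls <- anb_ls()
  # angle at (0,0) between rays to (0,100) and (5,100): atan2(5,100)
  expect_equal(compute_measure("ANB", ls), atan2(5, 100) * 180 / pi, tolerance = 1e-9)
  expect_equal(compute_measure("ANB", ls), 2.862405, tolerance = 1e-5)
  # FHI is a pure ratio of the two face heights
  p <- lm_coords(template_ls())
  p[1, ] <- c(0, 0); p[10, ] <- c(0, 65); p[2, ] <- c(100, 0); p[8, ] <- c(200, 0)
  expect_equal(compute_measure("FHI", landmark_set(p, space_1200())), 0.65)
  # MW: 10 px apart at 0.35 mm/px
  p <- lm_coords(template_ls()); p[11, ] <- c(500, 500); p[12, ] <- c(510, 500)
  expect_equal(compute_measure("MW", landmark_set(p, space_1200())), 3.5)
  # composite indicators are sums of signed line angles
  q <- lm_coords(template_ls())
  odi <- compute_measure("ODI", landmark_set(q, space_1200()))
  manual <- angle_between_lines(q[5, ], q[6, ], q[8, ], q[10, ], signed = TRUE) +
    angle_between_lines(q[3, ], q[4, ], q[17, ], q[18, ], signed = TRUE)
  expect_equal(odi, manual, tolerance = 1e-12)
  apdi <- compute_measure("APDI", landmark_set(q, space_1200()))
  manual2 <- angle_between_lines(q[3, ], q[4, ], q[2, ], q[7, ], signed = TRUE) +
    angle_between_lines(q[2, ], q[7, ], q[5, ], q[6, ], signed = TRUE) +
    angle_between_lines(q[3, ], q[4, ], q[17, ], q[18, ], signed = TRUE)
  expect_equal(apdi, manual2, tolerance = 1e-12)
})

test_that("degenerate geometry raises a measure error naming the measure", {
  p <- lm_coords(template_ls()); p[5, ] <- p[2, ]
  expect_error(compute_measure("ANB", landmark_set(p, space_1200())), "measure error in ANB")
})

test_that("classification truth table covers every band of all eight measures", {
  defs <- measure_definitions()
  # (value relative to band, expected label): inclusive normal bounds,
  # above -> above-class, below -> below-class
  for (nm in names(defs)) {
    d <- defs[[nm]]
    expect_identical(classify_measure(d, d$lo), "type1")
    expect_identical(classify_measure(d, d$hi), "type1")
    expect_identical(classify_measure(d, (d$lo + d$hi) / 2), "type1")
    expect_identical(classify_measure(d, d$hi + 0.01), d$above)
    expect_identical(classify_measure(d, d$lo - 0.01), d$below)
    # exhaustive & exclusive over a value sweep
    sweep_vals <- seq(d$lo - 10, d$hi + 10, length.out = 101)
    labs <- vapply(sweep_vals, function(v) classify_measure(d, v), "")
    expect_true(all(labs %in% c("type1", "type2", "type3")))
  }
  expect_error(classify_measure(defs$ANB, NaN), "value error")
})

test_that("published band directions: ANB, APDI, corrected SNB/ODI/MW", {
  defs <- measure_definitions()
  expect_identical(classify_measure(defs$ANB, 4.0), "type1")
  expect_identical(classify_measure(defs$ANB, 6.0), "type2")   # class 2 above 5.7
  expect_identical(classify_measure(defs$ANB, 3.2), "type1")   # inclusive boundary
  expect_identical(classify_measure(defs$ANB, 2.0), "type3")
  expect_identical(classify_measure(defs$APDI, 70), "type2")   # class 2 tendency below
  expect_identical(classify_measure(defs$APDI, 90), "type3")
  expect_identical(classify_measure(defs$SNB, 70), "type2")    # retrognathic below (corrected)
  expect_identical(classify_measure(defs$SNB, 85), "type3")    # prognathic above
  expect_identical(classify_measure(defs$ODI, 70), "type3")    # open tendency below (corrected)
  expect_identical(classify_measure(defs$MW, 1.0), "type2")    # edge-to-edge side
  expect_identical(classify_measure(defs$MW, 5.0), "type3")    # large overjet
  # bands are overridable
  o <- measure_definitions(list(ANB = list(hi = 10)))
  expect_identical(classify_measure(o$ANB, 8), "type1")
})

test_that("measure invariances under similarity transforms", {
  ls <- template_ls()
  moved <- similarity_ls(ls, angle_deg = 17, shift = c(120, -60), scale = 1.7)
  for (nm in c("ANB", "SNA", "SNB", "FMA")) {
    expect_lt(abs(compute_measure(nm, moved) - compute_measure(nm, ls)), 1e-9)
  }
  scaled <- similarity_ls(ls, scale = 2.4)
  expect_lt(abs(compute_measure("FHI", scaled) - compute_measure("FHI", ls)), 1e-12)
  # MW scales linearly with mm_per_px
  ls2 <- landmark_set(ls$coords, image_space(1200, 1200, 0.7), scheme = ls$scheme)
  expect_equal(compute_measure("MW", ls2), 2 * compute_measure("MW", ls))
})

test_that("SCR: perfect agreement, single mismatch, loop oracle", {
  gts <- lapply(1:5, function(s) sample_landmarks(shape_model(), 1, seed = s)[[1]])
  rep0 <- scr_report(gts, gts)
  expect_true(all(rep0$scr == 100))
  # single image, force one measure class to flip: push MW over 4.5 mm
  g <- template_ls()
  p <- lm_coords(g); p[11, ] <- p[12, ] + c(30, 0)
  pred <- landmark_set(p, g$space, role = "refined")
  stopifnot(classify_measure(measure_definitions()$MW, compute_measure("MW", pred)) !=
            classify_measure(measure_definitions()$MW, compute_measure("MW", g)))
  rep1 <- scr_report(list(g), list(pred))
  expect_equal(unname(rep1$scr["MW"]), 0)
  # perturbed set matches a brute-force per-image comparison
  nm <- noise_model(mode_sd = c(30, 30), indep_sd = 6)
  preds <- lapply(seq_along(gts), function(i) corrupt_landmarks(gts[[i]], nm, seed = 100 + i))
  rep2 <- scr_report(gts, preds)
  defs <- measure_definitions()
  for (meas in names(defs)) {
    agree <- 0
    for (i in seq_along(gts)) {
      cg <- classify_measure(defs[[meas]], compute_measure(meas, gts[[i]]))
      cp <- classify_measure(defs[[meas]], compute_measure(meas, preds[[i]]))
      if (cg == cp) agree <- agree + 1
    }
    expect_equal(unname(rep2$scr[meas]), 100 * agree / length(gts))
  }
  expect_error(scr_report(gts, gts[1:2]), "contract error")
})
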