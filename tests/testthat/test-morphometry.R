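# Morphometry: landmark measurements, MSU classification, diagnostic rules.

test_that("offset angle treats directions as undirected lines", {
  expect_equal(measure_offset_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(measure_offset_angle(c(0, 0, 1), c(0, 0, -1)), 0)
  r5 <- drop(lumbarplan:::rot_x(5) %*% c(0, 0, 1))
  expect_equal(measure_offset_angle(c(0, 0, 1), r5), 5, tolerance = 1e-9)
  expect_error(measure_offset_angle(c(0, 0, 0), c(0, 0, 1)),
               "DegenerateDirection")
})

test_that("landmark measurements recover the phantom spec exactly", {
  sp <- small_spec(recess_height = 4, recess_angle = 45, foramen_height = 18)
  ph <- generate_phantom(sp, intensity = FALSE)
  lm <- ph$truth$landmarks[["L4/5"]]
  expect_equal(measure_disc_vertical_diameter(lm), 10, tolerance = 1e-9)
  expect_equal(measure_canal_diameter(lm), 14, tolerance = 1e-9)
  expect_equal(measure_foramen_height(lm, "left"), 18, tolerance = 1e-9)
  expect_equal(measure_foramen_height(lm, "right"),
               measure_foramen_height(lm, "left"), tolerance = 1e-12)
  expect_equal(measure_facet_joint_angle(lm, "left"), 40, tolerance = 1e-9)
  expect_equal(measure_facet_joint_angle(lm, "right"), 40, tolerance = 1e-9)
  rec <- measure_lateral_recess(lm, "left")
  expect_equal(unname(rec["height"]), 4, tolerance = 1e-9)
  expect_equal(unname(rec["angle"]), 45, tolerance = 1e-9)

  # degenerated foramen ordering
  fh <- matrix(18, 3, 2); fh[2, ] <- 12
  ph2 <- generate_phantom(small_spec(foramen_height = fh), intensity = FALSE)
  lv <- ph2$truth$disc_labels
  expect_lt(measure_foramen_height(ph2$truth$landmarks[[lv[2]]], "left"),
            measure_foramen_height(ph2$truth$landmarks[[lv[1]]], "left"))

  expect_error(measure_canal_diameter(list(posterior_disc_edge_mid = c(0, 0, 0))),
               "MissingLandmark")
})

test_that("psoas asymmetry shows up in the measured area ratio", {
  # 1 mm voxels: the area quotient of two rasterized ellipses is stable to
  # grid alignment at this resolution (the per-area 2% bound is checked on
  # the coarser default grid elsewhere)
  psoas <- matrix(c(15, 10, 15, 12), 2, 2, byrow = TRUE,
                  dimnames = list(c("left", "right"), c("lr", "ap")))
  sp <- phantom_spec(grid_shape = c(116, 128, 160), spacing = c(1, 1, 1),
                     n_discs = 3, noise_sd = 0, psoas_semiaxes = psoas)
  ph <- generate_phantom(sp, intensity = FALSE)
  vc <- ph$truth$vertebra_centers["L4", ]
  l <- measure_psoas_csa(ph$labels, vc, "left")
  r <- measure_psoas_csa(ph$labels, vc, "right")
  expect_equal(r / l, 12 / 10, tolerance = 0.02)
})

test_that("herniation ratio from constructed masks follows the area quotient", {
  dims <- c(30, 30, 10)
  vox <- array(0L, dims)
  lmrow <- c(canal = 20L, herniation = 30L)
  vox[6:25, 6:15, 4:6] <- 20L                   # canal: 200 voxels/slice
  vox[11:15, 16:25, 5] <- 30L                   # herniation: 50 voxels on one slice
  lv <- label_volume(vox, rep(1, 3), c(0, 0, 0), lmrow)
  expect_equal(herniation_ratio(lv, level_z = 4, half_span = 3), 50 / 250)
  lv0 <- label_volume(array(20L, dims), rep(1, 3), c(0, 0, 0), lmrow)
  expect_equal(herniation_ratio(lv0, 4), 0)
  lvbad <- label_volume(array(0L, dims) + 0L, rep(1, 3), c(0, 0, 0), lmrow)
  expect_error(herniation_ratio(lvbad, 4), "DegenerateCanal")
})

test_that("MSU grade and zone follow the intra-facet partition", {
  line <- list(p1 = c(-15, -8, 0), p2 = c(15, -8, 0))
  margin <- c(0, 0, 0)
  mid <- c(0, 1, 0)
  expect_identical(msu_classify(NULL, margin, line, mid)$grade, "none")
  # apex at 40% of the margin->line depth, on the midline -> (1, A)
  g1 <- msu_classify(c(0, -3.2, 0), margin, line, mid)
  expect_identical(g1$grade, "1"); expect_identical(g1$zone, "A")
  # apex at 75% depth, lateral 10 mm (outer quarter) -> (2, B)
  g2 <- msu_classify(c(10, -6, 0), margin, line, mid)
  expect_identical(g2$grade, "2"); expect_identical(g2$zone, "B")
  # apex beyond the line, lateral past its endpoint -> (3, C)
  g3 <- msu_classify(c(16, -10, 0), margin, line, mid)
  expect_identical(g3$grade, "3"); expect_identical(g3$zone, "C")
  bad <- list(p1 = c(0, -8, 0), p2 = c(0, -8, 0))
  expect_error(msu_classify(c(0, -3, 0), margin, bad, mid),
               "DegenerateLandmark")
})

test_that("diagnostic rules use strict thresholds with a switchable angle arm", {
  mk_report <- function(canal = 14, rh = 5, ra = 45, grade = "none") {
    structure(list(measurements = data.frame(
      level = "L4/5", canal_diameter = canal,
      lateral_recess_height_left = rh, lateral_recess_angle_left = ra,
      lateral_recess_height_right = 5, lateral_recess_angle_right = 45,
      msu_grade = grade, stringsAsFactors = FALSE)),
      class = "morphometry_report")
  }
  thr <- diagnostic_thresholds()
  expect_true(diagnose(mk_report(canal = 9.9), thr)$canal_stenosis)
  expect_false(diagnose(mk_report(canal = 10.0), thr)$canal_stenosis)
  expect_false(diagnose(mk_report(rh = 3.0, ra = 30.0), thr)$recess_stenosis_left)
  expect_true(diagnose(mk_report(rh = 2.9), thr)$recess_stenosis_left)
  expect_true(diagnose(mk_report(rh = 5, ra = 25), thr)$recess_stenosis_left)
  expect_true(diagnose(mk_report(grade = "1"), thr)$herniation)

  # the literature's other angle convention is selectable
  thr_gt <- diagnostic_thresholds(recess_angle_direction = "greater")
  expect_true(diagnose(mk_report(ra = 35), thr_gt)$recess_stenosis_left)
  expect_false(diagnose(mk_report(ra = 25), thr_gt)$recess_stenosis_left)
})

test_that("bilaterally symmetric phantoms give exactly equal sides", {
  ph <- get_small_phantom()
  rep <- morphometry_report(ph$labels, ph$truth)
  m <- rep$measurements
  expect_identical(m$psoas_csa_left, m$psoas_csa_right)
  expect_equal(m$facet_joint_angle_left, m$facet_joint_angle_right,
               tolerance = 1e-12)
  expect_equal(m$lateral_recess_height_left, m$lateral_recess_height_right,
               tolerance = 1e-12)
  expect_equal(m$foramen_height_left, m$foramen_height_right,
               tolerance = 1e-12)
})

test_that("detection rate equals the planted prevalence exactly", {
  base <- small_spec()
  co <- phantom_cohort(10, base, list(
    canal_stenosis = list(prop = 0.3, level = "L4/5", range = c(7, 8.5)),
    herniation = list(prop = 0.5, level = "L4/5", extent_range = c(4, 7),
                      zone = "A")), seed = 3)
  dx <- lapply(co, function(p) diagnose(morphometry_report(p$labels, p$truth)))
  expect_equal(detection_rate(dx, "canal_stenosis", "L4/5"), 0.3)
  expect_equal(detection_rate(dx, "herniation", "L4/5"), 0.5)
  expect_equal(detection_rate(dx, "canal_stenosis", "L3/4"), 0)
  expect_error(detection_rate(list(), "herniation", "L4/5"), "EmptyCohort")
})
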