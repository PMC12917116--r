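# Synthetic phantom: geometry, determinism, pose handling, cohorts.

test_that("disc normals follow the lordosis arc model", {
  ph0 <- generate_phantom(small_spec(lordosis_angle = 0), intensity = FALSE)
  expect_equal(unname(ph0$truth$disc_normals),
               matrix(c(0, 0, 1), 3, 3, byrow = TRUE), tolerance = 1e-12)

  ph <- generate_phantom(phantom_spec(lordosis_angle = 40, noise_sd = 0),
                         intensity = FALSE)
  nrm <- ph$truth$disc_normals
  for (k in 1:4) {
    ang <- acos(sum(nrm[k, ] * nrm[k + 1, ])) * 180 / pi
    expect_equal(ang, 40 / 5, tolerance = 1e-9)
  }
  for (k in 1:5) expect_unit(nrm[k, ])
})

test_that("generation is deterministic given (spec, seed)", {
  sp <- small_spec(noise_sd = 4, seed = 11L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$labels$voxels, b$labels$voxels)
  expect_identical(a$intensity$voxels, b$intensity$voxels)
  expect_identical(a$truth$landmarks, b$truth$landmarks)
  c <- generate_phantom(small_spec(noise_sd = 4, seed = 12L))
  expect_false(identical(a$intensity$voxels, c$intensity$voxels))
  expect_identical(a$labels$voxels, c$labels$voxels) # geometry is seed-free
})

test_that("rasterized structures agree with analytic ground truth", {
  ph <- get_small_phantom()
  sp <- small_spec()
  tr <- ph$truth
  half_diag <- sqrt(sum(sp$spacing^2)) / 2
  for (lbl in tr$disc_labels) {
    m <- lumbarplan:::structure_mask(ph$labels, lbl)
    cen <- lumbarplan:::mask_centroid(m, sp$spacing, c(0, 0, 0))
    expect_lt(sqrt(sum((cen - tr$disc_centers[lbl, ])^2)), half_diag)
  }
  # psoas cross-section area within 2% of pi * a * b
  for (side in c("left", "right")) {
    csa <- measure_psoas_csa(ph$labels, tr$vertebra_centers["L4", ], side)
    expect_lt(abs(csa - pi * 15 * 10) / (pi * 15 * 10), 0.02)
  }
})

test_that("out-of-grid anatomy is rejected with the structure named", {
  sp <- small_spec()
  sp$pose$translation <- c(0, 60, 0)
  expect_error(generate_phantom(sp), "OutOfBounds")
})

test_that("apply_pose: identity, round trip, and pure translation", {
  ph <- get_small_phantom()
  sp <- small_spec()
  ident <- apply_pose(ph$labels, c(0, 0, 0), c(0, 0, 0))
  expect_identical(ident$voxels, ph$labels$voxels)

  posed <- apply_pose(ph$labels, c(10, 0, 0), c(0, 0, 0))
  expect_true(all(unique(as.vector(posed$voxels)) %in%
                    c(0L, unname(ph$labels$label_map))))
  back <- apply_pose(posed, c(-10, 0, 0), c(0, 0, 0))
  for (lbl in c(ph$truth$disc_labels, "canal")) {
    c1 <- lumbarplan:::mask_centroid(
      lumbarplan:::structure_mask(ph$labels, lbl), sp$spacing, c(0, 0, 0))
    c2 <- lumbarplan:::mask_centroid(
      lumbarplan:::structure_mask(back, lbl), sp$spacing, c(0, 0, 0))
    expect_lt(sqrt(sum((c1 - c2)^2)), sqrt(sum(sp$spacing^2))) # within 1 voxel
  }

  shifted <- apply_pose(ph$labels, c(0, 0, 0), c(0, 0, 6))
  for (lbl in ph$truth$disc_labels) {
    c1 <- lumbarplan:::mask_centroid(
      lumbarplan:::structure_mask(ph$labels, lbl), sp$spacing, c(0, 0, 0))
    c2 <- lumbarplan:::mask_centroid(
      lumbarplan:::structure_mask(shifted, lbl), sp$spacing, c(0, 0, 0))
    expect_equal(c2[3] - c1[3], 6, tolerance = 0.75)   # 0.5 voxel slack
    expect_lt(abs(c2[1] - c1[1]), 0.75)
  }

  expect_error(apply_pose(ph$labels, c(0, 0, 0), c(0, 80, 0)), "OutOfBounds")
})

test_that("posed generation moves landmarks with the anatomy", {
  sp <- small_spec()
  sp$pose <- list(rotation = c(5, 0, 0), translation = c(2, -3, 4))
  ph <- generate_phantom(sp, intensity = FALSE)
  tr <- ph$truth
  for (lbl in tr$disc_labels) {
    m <- lumbarplan:::structure_mask(ph$labels, lbl)
    cen <- lumbarplan:::mask_centroid(m, sp$spacing, c(0, 0, 0))
    expect_lt(sqrt(sum((cen - tr$disc_centers[lbl, ])^2)),
              sqrt(sum(sp$spacing^2)))  # pose equivariance, 1 voxel
  }
  # measurements on posed landmarks still recover the spec values
  lm <- tr$landmarks[["L4/5"]]
  expect_equal(measure_disc_vertical_diameter(lm), 10, tolerance = 1e-9)
  expect_equal(measure_canal_diameter(lm), 14, tolerance = 1e-9)
})

test_that("cohorts plant pathology deterministically and reproducibly", {
  base <- small_spec()
  vr <- list(lordosis_angle = c(15, 35),
             canal_stenosis = list(prop = 0.3, level = "L4/5", range = c(7, 8.5)))
  co <- phantom_cohort(10, base, vr, seed = 5)
  stenotic <- vapply(co, function(p)
    p$truth$planted_diagnoses[["L4/5"]]$canal_stenosis, logical(1))
  expect_identical(sum(stenotic), 3L)

  co2 <- phantom_cohort(10, base, vr, seed = 5)
  expect_identical(lapply(co, function(p) p$labels$voxels),
                   lapply(co2, function(p) p$labels$voxels))
  expect_identical(lapply(co, function(p) p$truth$true_measurements),
                   lapply(co2, function(p) p$truth$true_measurements))

  single <- phantom_cohort(1, base, list(lordosis_angle = c(20, 40)), seed = 1)
  expect_equal(single[[1]]$spec$lordosis_angle, 30)

  expect_error(phantom_cohort(4, base, list(disc_height = c(-2, 5)), seed = 1),
               "InvalidRange")
})
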