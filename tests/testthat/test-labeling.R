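# Disc labeling: reference disc, template matching vs brute force, fusion,
# identification rate.

cand_row <- function(x, y, z, heat = 200, channel = "c") {
  data.frame(x = x, y = y, z = z, heat = heat, channel = channel,
             stringsAsFactors = FALSE)
}

test_that("reference disc is the most caudal candidate above threshold", {
  pool <- rbind(cand_row(0, 0, 200), cand_row(0, 0, 160), cand_row(0, 0, 120))
  expect_equal(find_reference_disc(pool)$z, 120)
  expect_equal(find_reference_disc(cand_row(1, 2, 50))$z, 50)
  tie <- rbind(cand_row(0, 0, 100, heat = 200), cand_row(5, 0, 100, heat = 150))
  expect_equal(find_reference_disc(tie)$heat, 200)
  low <- cand_row(0, 0, 10, heat = 50)
  expect_error(find_reference_disc(low, threshold = 128), "NoReferenceFound")
})

test_that("perfect template geometry gives the identity assignment, error 0", {
  tmpl <- disc_template(lordosis_angle = 0, adjacent_spacing = 37)
  z <- (4:0) * 37
  pool <- do.call(rbind, lapply(seq_along(z), function(i)
    cand_row(0, 0, z[i], channel = tmpl$labels[i])))
  asg <- match_template(pool, tmpl)
  expect_false(any(asg$mapping$missing))
  expect_equal(asg$matching_error, 0, tolerance = 1e-9)
  expect_equal(asg$mapping$z, z)
  expect_equal(asg$reference$z, 0)
})

test_that("spurious peaks are rejected and channel swaps are corrected", {
  tmpl <- disc_template(lordosis_angle = 0, adjacent_spacing = 37)
  z <- (4:0) * 37
  pool <- do.call(rbind, lapply(seq_along(z), function(i)
    cand_row(0, 0, z[i], channel = tmpl$labels[i])))
  # spurious peak 20 mm from the true L3/4 centre
  spur <- rbind(pool, cand_row(0, 20, z[3] + 5, heat = 140))
  asg <- match_template(spur, tmpl)
  expect_equal(asg$mapping$z, z)
  expect_equal(asg$mapping$y, rep(0, 5))

  # channels swapped in the "network output": labeling follows spatial order
  swapped <- pool
  swapped$channel <- swapped$channel[c(2, 1, 3, 4, 5)]
  asg2 <- match_template(swapped, tmpl)
  expect_equal(asg2$mapping$z, z)
  expect_equal(asg2$mapping$label, tmpl$labels)
})

test_that("match_template equals exhaustive enumeration on random instances", {
  set.seed(99)
  tol <- 1e-9
  for (trial in 1:60) {
    d <- sample(2:6, 1)
    tmpl <- disc_template(disc_names_for(d), adjacent_spacing = 37,
                          lordosis_angle = 30)
    pool <- random_candidate_pool(d, 3)
    got <- match_template(pool, tmpl)
    ora <- oracle_match_template(pool, tmpl$distances)
    expect_equal(got$matching_error, ora$err, tolerance = tol)
    got_pts <- got$mapping[!got$mapping$missing, c("x", "y", "z")]
    ora_pts <- ora$pool[ora$rows[!is.na(ora$rows)], c("x", "y", "z")]
    expect_equal(unname(as.matrix(got_pts)), unname(as.matrix(ora_pts)),
                 tolerance = tol)
  }
})

test_that("matching error is invariant under rigid motion of all candidates", {
  set.seed(12)
  tmpl <- disc_template()
  pool <- random_candidate_pool(5, 2)
  e0 <- match_template(pool, tmpl)$matching_error
  R <- lumbarplan:::rotation_matrix(c(9, -4, 17))
  pts <- as.matrix(pool[, c("x", "y", "z")]) %*% t(R)
  moved <- pool
  moved$x <- pts[, 1] + 12; moved$y <- pts[, 2] - 5; moved$z <- pts[, 3] + 40
  e1 <- match_template(moved, tmpl)$matching_error
  expect_lt(abs(e0 - e1), 1e-9)
})

test_that("fewer candidates than labels leaves the surplus labels MISSING", {
  tmpl <- disc_template(lordosis_angle = 0, adjacent_spacing = 37)
  z <- (4:0) * 37
  pool <- do.call(rbind, lapply(c(1, 2, 4, 5), function(i)
    cand_row(0, 0, z[i])))
  asg <- match_template(pool, tmpl)
  expect_identical(sum(asg$mapping$missing), 1L)
  expect_true(asg$mapping$missing[3])       # the middle disc is the one absent
  expect_equal(asg$matching_error, 0, tolerance = 1e-9)
})

test_that("fuse_labels gates far components and infers vertebra labels", {
  ph <- get_small_phantom()
  tr <- ph$truth
  seg <- as_generic_segmentation(ph$labels)
  tmpl <- disc_template(tr$disc_labels, adjacent_spacing = 37)
  pool <- do.call(rbind, lapply(tr$disc_labels, function(l)
    cand_row(tr$disc_centers[l, 1], tr$disc_centers[l, 2],
             tr$disc_centers[l, 3], channel = l)))
  asg <- match_template(pool, tmpl)
  fused <- fuse_labels(seg, asg)
  for (lbl in tr$disc_labels) {
    expect_equal(dice_coefficient(
      lumbarplan:::structure_mask(fused, lbl),
      lumbarplan:::structure_mask(ph$labels, lbl)), 1)
  }
  # vertebra between L4/5 and L5/S1 must be L5
  expect_true("L5" %in% names(fused$label_map))
  l5 <- lumbarplan:::mask_centroid(lumbarplan:::structure_mask(fused, "L5"),
                                   seg$spacing, seg$origin)
  expect_gt(l5[3], tr$disc_centers["L5/S1", 3])
  expect_lt(l5[3], tr$disc_centers["L4/5", 3])

  # add a spurious blob 40 mm from any candidate: stays unlabeled
  vox <- seg$voxels
  vox[5:8, 5:8, 5:8] <- 1L
  seg2 <- label_volume(vox, seg$spacing, seg$origin, seg$label_map)
  fused2 <- fuse_labels(seg2, asg, gate = 15)
  blob <- lumbarplan:::structure_mask(fused2, "disc_unlabeled")
  expect_true(any(blob[5:8, 5:8, 5:8]))
})

test_that("identification rate applies the per-axis 6 mm and closest-label rules", {
  truth <- matrix(c(0, 0, 148, 0, 0, 111, 0, 0, 74, 0, 0, 37, 0, 0, 0),
                  5, 3, byrow = TRUE,
                  dimnames = list(disc_names_for(5), NULL))
  expect_equal(identification_rate(truth, truth), 1)

  pred <- truth
  pred["L3/4", 1] <- 7           # one axis displaced by 7 mm
  expect_equal(identification_rate(pred, truth), 0.8)

  pred2 <- truth
  pred2["L3/4", ] <- truth["L4/5", ] + c(0, 0, 2)  # nearest centroid is L4/5
  expect_equal(identification_rate(pred2, truth), 0.8)

  # missing prediction counts as not identified, no error
  expect_equal(identification_rate(truth[1:4, ], truth), 0.8)
})
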