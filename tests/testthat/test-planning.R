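# Scan planning: PCA axes, plane fitting, saturation band, quality factor,
# display slices.

rasterize_ellipsoid <- function(semi, dims = c(40, 40, 40), spacing = 1,
                                rot = NULL) {
  ctr <- (dims - 1) * spacing / 2
  pts <- lumbarplan:::voxel_world_coords(dims, rep(spacing, 3), c(0, 0, 0))
  loc <- sweep(pts, 2, ctr)
  if (!is.null(rot)) loc <- loc %*% rot
  inside <- (loc[, 1] / semi[1])^2 + (loc[, 2] / semi[2])^2 +
    (loc[, 3] / semi[3])^2 <= 1
  array(inside, dims)
}

test_that("principal axes recover an axis-aligned ellipsoid", {
  m <- rasterize_ellipsoid(c(20, 15, 4))
  ax <- disc_principal_axes(m, rep(1, 3))
  expect_false(ax$isotropic)
  expect_lt(angle_between_lines(ax$axes[, 3], c(0, 0, 1)), 1)
  expect_lt(angle_between_lines(ax$axes[, 1], c(1, 0, 0)), 1)
  expect_true(all(diff(ax$variances) <= 0))
  # frame is orthonormal
  g <- t(ax$axes) %*% ax$axes
  expect_lt(max(abs(g - diag(3))), 1e-9)

  ball <- rasterize_ellipsoid(c(10, 10, 10))
  expect_warning(axb <- disc_principal_axes(ball, rep(1, 3)), "isotropic")
  expect_true(axb$isotropic)

  tiny <- array(FALSE, c(5, 5, 5)); tiny[1:5] <- TRUE
  expect_error(disc_principal_axes(tiny, rep(1, 3)), "DegenerateMask")
})

test_that("a rotated ellipsoid's smallest axis matches the rotated normal", {
  R <- lumbarplan:::rot_x(10)
  m <- rasterize_ellipsoid(c(20, 15, 4), rot = R)
  ax <- disc_principal_axes(m, rep(1, 3))
  # points p inside satisfy R^T p axis-aligned, so the world normal is R[, 3]
  expect_lt(angle_between_lines(ax$axes[, 3], R[, 3]), 1)
})

test_that("transverse planes recover phantom disc normals and posterior centres", {
  ph <- get_small_phantom()
  sp <- small_spec()
  tr <- ph$truth
  for (lbl in tr$disc_labels) {
    m <- lumbarplan:::structure_mask(ph$labels, lbl)
    pl <- transverse_plane_for_disc(m, sp$spacing)
    expect_lt(angle_between_lines(pl$normal, tr$disc_normals[lbl, ]), 1.5)
    expect_gt(pl$normal[3], 0)
    # centre lies within the most-posterior 10% of disc voxels in -Y
    pts <- lumbarplan:::index_to_world(arrayInd(which(m), dim(m)),
                                       sp$spacing, c(0, 0, 0))
    expect_lte(pl$center[2], stats::quantile(pts[, 2], 0.10))
    # orthonormal frame
    expect_lt(abs(sum(pl$normal * pl$in_plane_axes[[1]])), 1e-9)
    expect_lt(abs(sum(pl$normal * pl$in_plane_axes[[2]])), 1e-9)
    expect_lt(abs(sum(pl$in_plane_axes[[1]] * pl$in_plane_axes[[2]])), 1e-9)
  }
})

test_that("long-axis planes: straight spine, lateral lean, mirror symmetry", {
  z <- seq(0, 148, by = 37)
  straight <- cbind(60, 54, z)
  lp <- fit_long_axis_planes(straight)
  expect_equal(abs(lp$sagittal$normal), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(lp$sagittal$center, colMeans(straight), tolerance = 1e-9)

  # 5 degree lateral lean: x = z * tan(5 deg)
  lean <- cbind(60 + z * tan(5 * pi / 180), 54, z)
  lp2 <- fit_long_axis_planes(lean)
  true_axis <- lumbarplan:::unit_vector(c(tan(5 * pi / 180), 0, 1))
  expect_lt(angle_between_lines(lp2$long_axis, true_axis), 0.5)

  # mirror equivariance: reflecting the centres about a sagittal plane
  # reflects the fitted sagittal normal; for the straight spine the plane is
  # literally unchanged
  mirrored <- lean
  mirrored[, 1] <- 2 * 60 - mirrored[, 1]
  lp3 <- fit_long_axis_planes(mirrored)
  refl <- lp2$sagittal$normal * c(1, -1, -1)
  expect_lt(angle_between_lines(lp3$sagittal$normal, refl), 1e-6)
  str_m <- straight
  str_m[, 1] <- 2 * 60 - str_m[, 1]
  lp4 <- fit_long_axis_planes(str_m)
  expect_lt(angle_between_lines(lp4$sagittal$normal, lp$sagittal$normal), 1e-6)

  expect_error(fit_long_axis_planes(straight[1, , drop = FALSE]),
               "InsufficientPoints")
})

test_that("saturation band sits anterior of all discs with the exact offset", {
  dims <- c(30, 120, 30)
  mask <- array(FALSE, dims)
  mask[10:20, 40:53, 10:20] <- TRUE    # anterior-most disc voxel at y = 52 (1 mm spacing)
  cor_pl <- lumbarplan:::new_scan_plane(c(15, 40, 15), c(0, 1, 0),
                                        c(0, 0, 1), c(1, 0, 0))
  band <- place_saturation_band(mask, rep(1, 3), c(0, 0, 0), cor_pl,
                                offset_distance = 10, thickness = 30)
  # near face at most-anterior voxel (y = 52) + 10
  expect_equal(band$near_face_distance, 62)
  expect_equal(band$center[2], 62 + 15)
  expect_equal(band$normal, c(0, 1, 0))
  # no disc voxel inside the band
  pts <- lumbarplan:::index_to_world(arrayInd(which(mask), dims),
                                     rep(1, 3), c(0, 0, 0))
  expect_true(all(pts %*% band$normal < band$near_face_distance))
  # band exceeding the volume is refused with the feasible offset reported
  expect_error(place_saturation_band(mask, rep(1, 3), c(0, 0, 0), cor_pl,
                                     offset_distance = 10, thickness = 60),
               "OutOfBounds")
})

test_that("quality factor: perfect 1, missing-disc fraction, monotone decay", {
  tmpl <- disc_template(lordosis_angle = 0, adjacent_spacing = 37)
  mk_asg <- function(z, missing = rep(FALSE, length(z))) {
    mapping <- data.frame(label = tmpl$labels[seq_along(z)],
                          x = 0, y = 0, z = z, heat = 200, missing = missing,
                          stringsAsFactors = FALSE)
    mapping$x[missing] <- NA
    structure(list(mapping = mapping, matching_error = 0, template = tmpl),
              class = "label_assignment")
  }
  perfect <- mk_asg((4:0) * 37)
  expect_equal(quality_factor(perfect), 1)

  onemiss <- mk_asg((4:0) * 37, missing = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # remaining adjacent spacings: 37 (ok), 74 vs T(2,4) = 74 (ok), 37 (ok)
  expect_equal(quality_factor(onemiss), 0.8)

  jitter1 <- mk_asg((4:0) * 37 + c(0, 2, -2, 2, 0))
  jitter2 <- mk_asg((4:0) * 37 + 2 * c(0, 2, -2, 2, 0))
  expect_lt(quality_factor(jitter2), quality_factor(jitter1))
  expect_lt(quality_factor(jitter1), 1)
  expect_gte(quality_factor(jitter2), 0)

  expect_error(quality_factor(mk_asg(c(0), missing = FALSE)),
               "InsufficientDiscs")
})

test_that("display slice equals the array slice for axis-aligned planes", {
  ph <- get_small_phantom()
  vol <- ph$intensity
  dims <- dim(vol$voxels)
  i <- 38   # sagittal plane through voxel column i
  plane <- lumbarplan:::new_scan_plane(
    center = c((i - 1) * 1.5, (dims[2] - 1) * 1.5 / 2, (dims[3] - 1) * 1.5 / 2),
    normal = c(1, 0, 0), axis1 = c(0, 1, 0), axis2 = c(0, 0, 1))
  ext <- c((dims[2] - 1) * 1.5 / 2, (dims[3] - 1) * 1.5 / 2)
  img <- select_display_slice(vol, plane, extent = ext, pixel_spacing = 1.5)
  expect_equal(dim(img), c(dims[2], dims[3]))
  expect_lt(max(abs(img - vol$voxels[i, , ])), 1e-9)
  expect_equal(attr(img, "coverage"), 1)

  # tilted plane matches a brute-force trilinear resampler on a small patch
  tilt <- lumbarplan:::rot_x(5) %*% c(1, 0, 0)
  a1 <- lumbarplan:::rot_x(5) %*% c(0, 1, 0)
  a2 <- lumbarplan:::rot_x(5) %*% c(0, 0, 1)
  pl2 <- lumbarplan:::new_scan_plane(plane$center, drop(tilt), drop(a1), drop(a2))
  img2 <- select_display_slice(vol, pl2, extent = c(9, 9), pixel_spacing = 1.5)
  u <- attr(img2, "u"); v <- attr(img2, "v")
  for (ui in c(1, 4, 13)) for (vi in c(2, 7, 12)) {
    p <- pl2$center + u[ui] * drop(a1) + v[vi] * drop(a2)
    idx <- p / 1.5 + 1
    i0 <- floor(idx); f <- idx - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
        (if (dz) f[3] else 1 - f[3])
      acc <- acc + w * vol$voxels[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    expect_equal(img2[ui, vi], acc, tolerance = 1e-6)
  }
})
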