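# Scan-plane planning: per-disc transverse plane groups from the principal
# axes of each disc mask, least-squares sagittal/coronal planes through the
# disc centres, anterior saturation-band placement, a spacing-consistency
# quality factor, and display-slice resampling.

new_scan_plane <- function(center, normal, axis1, axis2, extent = c(0, 0)) {
  normal <- unit_vector(normal)
  axis1 <- unit_vector(axis1)
  axis2 <- unit_vector(axis2)
  if (abs(sum(normal * axis1)) > 1e-9 || abs(sum(normal * axis2)) > 1e-9 ||
      abs(sum(axis1 * axis2)) > 1e-9)
    stop("plane frame must be orthonormal")
  structure(list(center = center, normal = normal,
                 in_plane_axes = list(axis1, axis2), extent = extent),
            class = "scan_plane")
}

#' @export
print.scan_plane <- function(x, ...) {
  cat(sprintf("<scan_plane> center (%s) mm, normal (%s)\n",
              paste(sprintf("%.1f", x$center), collapse = ", "),
              paste(sprintf("%.3f", x$normal), collapse = ", ")))
  invisible(x)
}

# Complete a unit normal to a right-handed orthonormal frame.
complete_plane_frame <- function(normal, hint = c(1, 0, 0)) {
  normal <- unit_vector(normal)
  a1 <- hint - sum(hint * normal) * normal
  if (vec_norm(a1) < 1e-6) {
    hint <- c(0, 1, 0)
    a1 <- hint - sum(hint * normal) * normal
  }
  a1 <- unit_vector(a1)
  a2 <- cross3(normal, a1)
  list(a1, a2)
}

#' Principal axes of a disc mask
#'
#' Eigen-decomposition of the covariance of the mask's voxel world
#' coordinates. Axes are sorted by descending variance and sign-oriented so
#' that axis k has a non-negative dot product with the k-th world axis
#' (+X, +Y, +Z). For a lumbar disc the smallest-variance axis is the disc
#' normal.
#'
#' @param mask Logical 3D array.
#' @param spacing mm triple.
#' @param origin World origin.
#' @return List: `axes` (3 x 3 matrix, columns = axes), `variances`,
#'   `centroid`, `isotropic` (flag set when `lambda1 / lambda3 < 1.05`).
#' @export
disc_principal_axes <- function(mask, spacing, origin = c(0, 0, 0)) {
  idx <- which(mask)
  if (length(idx) < 10) stop("DegenerateMask: fewer than 10 voxels")
  pts <- index_to_world(arrayInd(idx, dim(mask)), spacing, origin)
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  axes <- eg$vectors
  for (k in 1:3) if (axes[k, k] < 0) axes[, k] <- -axes[, k]
  iso <- eg$values[1] / eg$values[3] < 1.05
  if (iso) warning("disc_principal_axes: near-isotropic mask, axes unreliable")
  list(axes = axes, variances = eg$values, centroid = ctr, isotropic = iso)
}

# Centroid of the most-posterior `frac` of disc voxels along -Y within the
# mid-Z slab of the mask (robust "posterior edge point").
posterior_edge_point <- function(mask, spacing, origin, frac = 0.05) {
  idx <- which(mask)
  pts <- index_to_world(arrayInd(idx, dim(mask)), spacing, origin)
  zc <- mean(pts[, 3])
  slab <- abs(pts[, 3] - zc) <= max(spacing[3], 1.5)
  if (!any(slab)) slab <- rep(TRUE, nrow(pts))
  p <- pts[slab, , drop = FALSE]
  cut <- stats::quantile(p[, 2], frac)
  colMeans(p[p[, 2] <= cut, , drop = FALSE])
}

#' Transverse scan plane for one disc
#'
#' The plane normal is the principal axis closest to the head-foot (+Z)
#' direction, sign-flipped toward +Z; the scan centre is the disc's
#' posterior edge point (centroid of the most-posterior 5% of mid-disc
#' voxels). If the mask is near-isotropic the normal falls back to +Z.
#'
#' @param mask Logical 3D array (one disc).
#' @param spacing,origin Grid geometry.
#' @param axes Optional result of [disc_principal_axes()] (recomputed when
#'   omitted).
#' @return A `scan_plane`.
#' @export
transverse_plane_for_disc <- function(mask, spacing, origin = c(0, 0, 0),
                                      axes = NULL) {
  if (is.null(axes)) axes <- disc_principal_axes(mask, spacing, origin)
  if (isTRUE(axes$isotropic)) {
    normal <- c(0, 0, 1)
  } else {
    dots <- abs(t(axes$axes) %*% c(0, 0, 1))
    normal <- axes$axes[, which.max(dots)]
    if (normal[3] < 0) normal <- -normal
  }
  center <- posterior_edge_point(mask, spacing, origin)
  fr <- complete_plane_frame(normal)
  new_scan_plane(center, normal, fr[[1]], fr[[2]])
}

#' Fit sagittal and coronal planes through the disc centres
#'
#' The spine long axis is the total-least-squares line through the centres
#' (first principal component). The sagittal plane contains the long axis
#' and the anterior (+Y-projected) direction; the coronal plane is
#' orthogonal to it and also contains the long axis. Both planes are
#' centred at the centroid of the disc centres.
#'
#' @param centers n x 3 matrix of disc centres (n >= 2), head -> foot order.
#' @return List with `sagittal` and `coronal` `scan_plane`s and the fitted
#'   `long_axis` unit vector.
#' @export
fit_long_axis_planes <- function(centers) {
  if (is.null(dim(centers)) || nrow(centers) < 2)
    stop("InsufficientPoints: need at least 2 disc centres")
  ctr <- colMeans(centers)
  x <- sweep(centers, 2, ctr)
  sv <- svd(x)
  axis <- sv$v[, 1]
  if (axis[3] < 0) axis <- -axis     # orient head-ward

  y_part <- c(0, 1, 0) - sum(c(0, 1, 0) * axis) * axis
  if (vec_norm(y_part) < 1e-6) {
    warning("fit_long_axis_planes: long axis parallel to +Y, falling back to world axes")
    sag_normal <- c(1, 0, 0)
  } else {
    sag_normal <- unit_vector(cross3(axis, unit_vector(y_part)))
  }
  if (sag_normal[1] < 0) sag_normal <- -sag_normal
  cor_normal <- unit_vector(cross3(axis, sag_normal))
  if (cor_normal[2] < 0) cor_normal <- -cor_normal

  sag <- new_scan_plane(ctr, sag_normal, axis,
                        unit_vector(cross3(sag_normal, axis)))
  cor <- new_scan_plane(ctr, cor_normal, axis,
                        unit_vector(cross3(cor_normal, axis)))
  list(sagittal = sag, coronal = cor, long_axis = axis)
}

#' Place the anterior saturation band
#'
#' The band is a slab normal to the coronal scan direction whose near face
#' sits `offset_distance` mm anterior of the most anterior disc voxel, so it
#' never overlaps disc tissue.
#'
#' @param disc_mask Logical 3D array of all disc voxels.
#' @param spacing,origin Grid geometry.
#' @param coronal Coronal `scan_plane` (band normal = its normal).
#' @param offset_distance mm between the anterior-most disc point and the
#'   band's near face (default 10).
#' @param thickness Band thickness in mm (default 30).
#' @return Object of class `saturation_band`: `center`, `normal`,
#'   `thickness`, `offset_distance`, `near_face_distance` (signed distance
#'   of the near face along the normal).
#' @export
place_saturation_band <- function(disc_mask, spacing, origin = c(0, 0, 0),
                                  coronal, offset_distance = 10,
                                  thickness = 30) {
  if (offset_distance <= 0) stop("offset_distance must be > 0")
  if (thickness <= 0) stop("thickness must be > 0")
  idx <- which(disc_mask)
  if (length(idx) == 0) stop("MissingStructure: no disc voxels")
  pts <- index_to_world(arrayInd(idx, dim(disc_mask)), spacing, origin)
  nrm <- coronal$normal
  if (nrm[2] < 0) nrm <- -nrm        # anterior direction
  proj <- pts %*% nrm
  near <- max(proj) + offset_distance
  center_d <- near + thickness / 2
  anchor <- pts[which.max(proj), ]
  center <- anchor + (center_d - max(proj)) * nrm

  dims <- dim(disc_mask)
  hi_world <- origin + (dims - 0.5) * spacing
  far_d <- near + thickness
  corner_max <- sum(pmax(nrm * hi_world, nrm * (origin - 0.5 * spacing)))
  if (far_d > corner_max) {
    stop(sprintf(
      "OutOfBounds: band exits the volume; maximum feasible offset %.1f mm",
      max(0, corner_max - thickness - max(proj))))
  }
  if (any(proj >= near)) stop("saturation band overlaps disc voxels")
  structure(list(center = as.numeric(center), normal = as.numeric(nrm),
                 thickness = thickness, offset_distance = offset_distance,
                 near_face_distance = near),
            class = "saturation_band")
}

#' Quality factor of a label assignment
#'
#' A reliability score in [0, 1] combining the inter-disc spacing
#' information: `(n_present / n_total) * exp(-mean relative deviation of
#' adjacent spacings from the template)`. It equals 1 exactly when every
#' adjacent spacing matches the template and no disc is missing, and
#' decreases monotonically with spacing deviation or missing discs (i.e. it
#' is inversely related to labeling uncertainty).
#'
#' @param assignment A `label_assignment`.
#' @param template A [disc_template()] (defaults to the assignment's).
#' @return Scalar in [0, 1].
#' @export
quality_factor <- function(assignment, template = assignment$template) {
  mp <- assignment$mapping
  present <- which(!mp$missing)
  if (length(present) < 2) stop("InsufficientDiscs: need >= 2 assigned discs")
  dev <- numeric(0)
  for (a in seq_along(present)[-length(present)]) {
    i <- present[a]; j <- present[a + 1]
    d <- sqrt(sum((c(mp$x[i], mp$y[i], mp$z[i]) -
                     c(mp$x[j], mp$y[j], mp$z[j]))^2))
    t <- template$distances[i, j]
    dev <- c(dev, abs(d - t) / t)
  }
  frac <- length(present) / nrow(mp)
  max(0, min(1, frac * exp(-mean(dev))))
}

#' Resample a display slice from an intensity volume
#'
#' Trilinear resampling of the volume onto the plane's in-plane grid at the
#' native in-plane spacing. Pixels outside the volume are 0; the attribute
#' `coverage` reports the in-volume fraction.
#'
#' @param volume An [mri_volume()].
#' @param plane A `scan_plane`.
#' @param extent Half-extents (mm) of the sampled sheet along the two
#'   in-plane axes; defaults to covering the volume diagonal.
#' @param pixel_spacing Sample spacing in mm (default: mean voxel spacing).
#' @return 2D matrix of intensities with attribute `coverage`.
#' @export
select_display_slice <- function(volume, plane, extent = NULL,
                                 pixel_spacing = NULL) {
  dims <- dim(volume$voxels)
  if (is.null(pixel_spacing)) pixel_spacing <- mean(volume$spacing)
  if (is.null(extent)) {
    extent <- rep(sqrt(sum(((dims - 1) * volume$spacing)^2)) / 2, 2)
  }
  u <- seq(-extent[1], extent[1], by = pixel_spacing)
  v <- seq(-extent[2], extent[2], by = pixel_spacing)
  a1 <- plane$in_plane_axes[[1]]
  a2 <- plane$in_plane_axes[[2]]
  grid <- expand.grid(u = u, v = v)
  pts <- outer(grid$u, a1) + outer(grid$v, a2)
  pts <- sweep(pts, 2, plane$center, FUN = "+")
  vals <- trilinear_sample(volume, pts)
  img <- matrix(vals$value, nrow = length(u), ncol = length(v))
  if (vals$coverage == 0) stop("OutOfBounds: plane does not intersect the volume")
  attr(img, "coverage") <- vals$coverage
  attr(img, "u") <- u
  attr(img, "v") <- v
  img
}

# Trilinear interpolation at arbitrary world points; outside -> 0.
trilinear_sample <- function(volume, pts) {
  dims <- dim(volume$voxels)
  cont <- world_to_index(pts, volume$spacing, volume$origin)
  if (is.null(dim(cont))) cont <- matrix(cont, ncol = 3)
  i0 <- floor(cont)
  fr <- cont - i0
  inside <- i0[, 1] >= 1 & i0[, 1] <= dims[1] - 1 &
    i0[, 2] >= 1 & i0[, 2] <= dims[2] - 1 &
    i0[, 3] >= 1 & i0[, 3] <= dims[3] - 1
  # points sitting exactly on the last voxel plane still count as inside
  edge <- cont[, 1] >= 1 & cont[, 1] <= dims[1] &
    cont[, 2] >= 1 & cont[, 2] <= dims[2] &
    cont[, 3] >= 1 & cont[, 3] <= dims[3]
  i0[edge & !inside, ] <- pmin(matrix(i0[edge & !inside, ], ncol = 3),
                               matrix(rep(dims - 1, each = sum(edge & !inside)),
                                      ncol = 3))
  i0 <- pmax(i0, 1)
  use <- edge
  out <- numeric(nrow(cont))
  if (any(use)) {
    ii <- i0[use, , drop = FALSE]
    ff <- cont[use, , drop = FALSE] - ii
    ff <- pmin(pmax(ff, 0), 1)
    acc <- numeric(sum(use))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx == 1) ff[, 1] else 1 - ff[, 1]) *
        (if (dy == 1) ff[, 2] else 1 - ff[, 2]) *
        (if (dz == 1) ff[, 3] else 1 - ff[, 3])
      lin <- (ii[, 1] + dx) + (ii[, 2] + dy - 1) * dims[1] +
        (ii[, 3] + dz - 1) * dims[1] * dims[2]
      acc <- acc + w * volume$voxels[lin]
    }
    out[use] <- acc
  }
  list(value = out, coverage = mean(use))
}

#' Plan scanning parameters for a labeled phantom or segmentation
#'
#' Convenience wrapper tying the planning operations together: per-disc
#' transverse planes (PCA), sagittal/coronal planes (least squares through
#' the assigned disc centres), the anterior saturation band, and the quality
#' factor.
#'
#' @param labels A [label_volume()] containing per-disc codes.
#' @param assignment A `label_assignment` (for disc centres, labels and the
#'   quality factor).
#' @param sat_offset,sat_thickness Saturation-band geometry in mm.
#' @return Object of class `scan_plan`.
#' @export
build_scan_plan <- function(labels, assignment, sat_offset = 10,
                            sat_thickness = 30) {
  disc_labels <- assignment$mapping$label[!assignment$mapping$missing]
  transverse <- list()
  all_disc <- array(FALSE, dim(labels$voxels))
  for (lbl in disc_labels) {
    if (!lbl %in% names(labels$label_map)) next
    m <- structure_mask(labels, lbl)
    if (!any(m)) next
    all_disc <- all_disc | m
    transverse[[lbl]] <- transverse_plane_for_disc(m, labels$spacing,
                                                   labels$origin)
  }
  mp <- assignment$mapping[!assignment$mapping$missing, , drop = FALSE]
  lp <- fit_long_axis_planes(as.matrix(mp[, c("x", "y", "z")]))
  band <- place_saturation_band(all_disc, labels$spacing, labels$origin,
                                lp$coronal, sat_offset, sat_thickness)
  qf <- quality_factor(assignment)
  structure(list(sagittal = lp$sagittal, coronal = lp$coronal,
                 transverse = transverse, sat_band = band,
                 quality_factor = qf,
                 disc_labels = disc_labels,
                 vertebra_labels = vapply(disc_labels, vertebra_above, "")),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf("<scan_plan> %d transverse plane group(s), quality factor %.3f\n",
              length(x$transverse), x$quality_factor))
  cat("  sagittal normal:", paste(sprintf("%.3f", x$sagittal$normal), collapse = ", "), "\n")
  cat("  coronal  normal:", paste(sprintf("%.3f", x$coronal$normal), collapse = ", "), "\n")
  invisible(x)
}
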