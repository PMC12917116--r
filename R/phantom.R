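# Parametric synthetic lumbar localizer phantom.
#
# The phantom emulates the anatomy a lumbar localizer scan shows: five
# vertebral bodies (L1-L5) plus a sacral base, five intervertebral discs
# (L1/2 ... L5/S1) tilted by a discretised circular-arc lordosis model, the
# spinal canal, spinous processes, bilateral psoas muscles, and optionally a
# planted disc herniation or stenosis. Every landmark and measurement the
# morphometry module computes is also produced analytically, so downstream
# stages can be validated against exact ground truth.
#
# World frame: RAS+ (+X right, +Y anterior, +Z head). The spine is stacked
# along +Z; per-level tilt rotates about the +X (left-right) axis so that
# adjacent disc normals differ by lordosis_angle / n_discs degrees, the
# tangent increments of a circular arc sampled once per level.

LUMBAR_DISC_NAMES <- c("T12/L1", "L1/2", "L2/3", "L3/4", "L4/5", "L5/S1")
LUMBAR_VERT_NAMES <- c("T12", "L1", "L2", "L3", "L4", "L5")

disc_names_for <- function(n) {
  if (n < 1 || n > 6) stop("n_discs must be between 1 and 6")
  utils::tail(LUMBAR_DISC_NAMES, n)
}

vert_names_for <- function(n) utils::tail(LUMBAR_VERT_NAMES, n)

#' Specify a synthetic lumbar phantom
#'
#' Returns a validated parameter set for [generate_phantom()]. All linear
#' dimensions are in mm, angles in degrees. Defaults describe a healthy adult
#' lumbar spine at localizer resolution; pathology is planted by deforming
#' the specification (narrow canal, shallow recess, posterior disc bump), so
#' the analytic ground truth remains exact.
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param spacing Real triple, mm per voxel.
#' @param n_discs Number of discs (head to foot ending at L5/S1).
#' @param lordosis_angle Total tangent arc (degrees) of the lumbar curve;
#'   adjacent disc normals differ by `lordosis_angle / n_discs`.
#' @param disc_heights Per-level disc heights (mm).
#' @param disc_radii Per-level c(AP, LR) semi-axes (mm); recycled from a
#'   length-2 vector.
#' @param vertebra_heights Per-level vertebral body heights (mm).
#' @param sacrum_height Height (mm) of the sacral base segment.
#' @param canal_diameter Per-level spinal canal diameter (mm), defined as the
#'   distance from the posterior disc edge midpoint to the spinous process
#'   midpoint (the measurement the morphometry module reports).
#' @param foramen_height Per-level, per-side foraminal heights (mm);
#'   n x 2 matrix (columns left, right) or scalar.
#' @param recess_height,recess_angle Per-level, per-side lateral recess
#'   height (mm) and angle (degrees); n x 2 matrices or scalars.
#' @param facet_angle Per-level, per-side facet joint angle to the midline
#'   (degrees); n x 2 matrix or scalar.
#' @param psoas_semiaxes c(LR, AP) semi-axes (mm) of the elliptic psoas
#'   cross-section, or a 2 x 2 matrix (rows left, right).
#' @param herniation Optional named list, one entry per affected disc level,
#'   each `list(extent = mm, zone = "A"|"B"|"C")`. Extent is the posterior
#'   protrusion beyond the disc margin.
#' @param pose Rigid pose: `list(rotation = degrees triple, translation = mm
#'   triple)`, applied about the volume centre after the anatomy is built.
#' @param noise_sd Additive Gaussian intensity noise (intensity units).
#' @param seed Integer seed controlling the noise; the geometry is
#'   deterministic regardless.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(80, 96, 168),
                         spacing = c(1.5, 1.5, 1.5),
                         n_discs = 5,
                         lordosis_angle = 40,
                         disc_heights = 10,
                         disc_radii = c(16, 22),
                         vertebra_heights = 27,
                         sacrum_height = 30,
                         canal_diameter = 14,
                         foramen_height = 18,
                         recess_height = 5,
                         recess_angle = 45,
                         facet_angle = 40,
                         psoas_semiaxes = c(15, 10),
                         herniation = NULL,
                         pose = list(rotation = c(0, 0, 0),
                                     translation = c(0, 0, 0)),
                         noise_sd = 5,
                         seed = 1L) {
  n <- as.integer(n_discs)
  per_level <- function(x, what) {
    if (length(x) == 1) x <- rep(x, n)
    if (length(x) != n) stop(sprintf("%s must have length 1 or %d", what, n))
    as.numeric(x)
  }
  per_side <- function(x, what) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(n, 2))) stop(sprintf("%s must be %d x 2", what, n))
      m <- x
    } else {
      m <- matrix(per_level(x, what), n, 2)
    }
    colnames(m) <- c("left", "right")
    m
  }
  radii <- if (is.matrix(disc_radii)) disc_radii else
    matrix(disc_radii, n, 2, byrow = TRUE)
  colnames(radii) <- c("ap", "lr")
  psoas <- if (is.matrix(psoas_semiaxes)) psoas_semiaxes else
    matrix(psoas_semiaxes, 2, 2, byrow = TRUE)
  dimnames(psoas) <- list(c("left", "right"), c("lr", "ap"))

  spec <- structure(list(
    grid_shape = as.integer(grid_shape),
    spacing = as.numeric(spacing),
    n_discs = n,
    disc_labels = disc_names_for(n),
    vertebra_labels = vert_names_for(n),
    lordosis_angle = as.numeric(lordosis_angle),
    disc_heights = per_level(disc_heights, "disc_heights"),
    disc_radii = radii,
    vertebra_heights = per_level(vertebra_heights, "vertebra_heights"),
    sacrum_height = as.numeric(sacrum_height),
    canal_diameter = per_level(canal_diameter, "canal_diameter"),
    foramen_height = per_side(foramen_height, "foramen_height"),
    recess_height = per_side(recess_height, "recess_height"),
    recess_angle = per_side(recess_angle, "recess_angle"),
    facet_angle = per_side(facet_angle, "facet_angle"),
    psoas_semiaxes = psoas,
    herniation = herniation,
    pose = pose,
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(grid_shape < 8)) stop("grid_shape too small")
    if (any(spacing <= 0)) stop("spacing must be positive")
    lin <- c(disc_heights, disc_radii, vertebra_heights, sacrum_height,
             canal_diameter, foramen_height, recess_height, psoas_semiaxes)
    if (any(lin <= 0)) stop("all linear dimensions must be positive")
    if (any(recess_angle <= 0 | recess_angle >= 90))
      stop("recess_angle must be in (0, 90)")
    if (any(facet_angle <= 0 | facet_angle >= 90))
      stop("facet_angle must be in (0, 90)")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (!is.null(herniation)) {
      if (is.null(names(herniation)) ||
          !all(names(herniation) %in% disc_labels))
        stop("herniation entries must be named by disc level")
      for (h in herniation) {
        if (h$extent < 0) stop("herniation extent must be >= 0")
        if (!h$zone %in% c("A", "B", "C")) stop("herniation zone must be A, B or C")
      }
    }
    if (length(pose$rotation) != 3 || length(pose$translation) != 3)
      stop("pose must have rotation and translation triples")
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d discs (%s..%s), grid %s @ %s mm, lordosis %g deg\n",
              x$n_discs, x$disc_labels[1], x$disc_labels[x$n_discs],
              paste(x$grid_shape, collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              x$lordosis_angle))
  if (!is.null(x$herniation))
    cat("planted herniation at:", paste(names(x$herniation), collapse = ", "), "\n")
  invisible(x)
}

# Fixed secondary geometry, derived from the per-level primary parameters.
# These are modelling constants of the phantom, not tunables.
PHANTOM_GEOM <- list(
  vertebra_radius_shrink = 2,    # vertebral body semi-axes = disc semi-axes - 2 mm
  spinous_half_width = 5,        # mm, LR half width of the spinous process block
  spinous_length = 16,           # mm, posterior extent of the spinous block
  psoas_gap = 2,                 # mm between disc LR edge and psoas medial edge
  psoas_anterior_offset = 2,     # mm anterior shift of psoas centres
  foramen_lateral_gap = 3,       # mm lateral of the disc LR edge
  recess_lateral_offset = 12,    # mm lateral of midline for the recess landmarks
  facet_lateral_offset = 14,     # mm lateral of midline for facet line anchors
  facet_posterior_offset = 4,    # mm posterior of the disc posterior margin
  intra_facet_offset = 8,        # mm posterior of the disc margin (MSU reference)
  intra_facet_half_length = 15,  # mm half length of the intra-facet line
  herniation_lr_semiaxis = 8,    # mm LR semi-axis of the planted bump
  spine_y_bias = -14             # mm posterior shift of the whole spine in grid
                                 # (leaves anterior room for the saturation band)
)

PHANTOM_INTENSITY <- c(background = 15, vertebra = 110, sacrum = 110,
                       disc = 170, canal = 90, spinous_process = 105,
                       psoas = 80, herniation = 160)

phantom_label_map <- function(spec) {
  codes <- c(stats::setNames(seq_len(spec$n_discs),
                             spec$vertebra_labels),
             stats::setNames(spec$n_discs + 1L, "S1"),
             stats::setNames(10L + seq_len(spec$n_discs), spec$disc_labels),
             canal = 20L, spinous_process = 21L,
             psoas_left = 22L, psoas_right = 23L,
             herniation = 30L)
  codes
}

# --- spine segment chain ----------------------------------------------------

# Structures head -> foot: V1, D1, V2, D2, ..., Vn, Dn, sacrum (2n + 1 of
# them). Tilt (rotation about +X) of structure j is
#   lordosis * (j - (n + 1)) / (2 n),
# so discs (even j) step by exactly lordosis / n between adjacent levels.
spine_chain <- function(spec) {
  n <- spec$n_discs
  m <- 2L * n + 1L
  j <- seq_len(m)
  kind <- ifelse(j == m, "sacrum", ifelse(j %% 2 == 1, "vertebra", "disc"))
  level <- ifelse(kind == "disc", j %/% 2, ifelse(kind == "vertebra",
                                                  (j + 1) %/% 2, NA))
  heights <- numeric(m)
  heights[kind == "vertebra"] <- spec$vertebra_heights
  heights[kind == "disc"] <- spec$disc_heights
  heights[kind == "sacrum"] <- spec$sacrum_height
  tilt <- spec$lordosis_angle * (j - (n + 1)) / (2 * n)

  ext <- (spec$grid_shape - 1) * spec$spacing
  centre <- ext / 2
  total_z <- sum(heights * cos(tilt * pi / 180))
  base <- c(centre[1], centre[2] + PHANTOM_GEOM$spine_y_bias,
            centre[3] - total_z / 2)

  centres <- matrix(0, m, 3)
  dirs <- matrix(0, m, 3)
  p <- base
  for (jj in rev(seq_len(m))) {     # build bottom (sacrum) up
    a <- tilt[jj] * pi / 180
    d <- c(0, sin(a), cos(a))
    centres[jj, ] <- p + d * heights[jj] / 2
    p <- p + d * heights[jj]
    dirs[jj, ] <- d
  }
  list(index = j, kind = kind, level = level, heights = heights,
       tilt = tilt, centres = centres, dirs = dirs,
       volume_centre = centre)
}

# Orthonormal local frame of a chain structure: e_x = LR, e_y = anterior,
# e_z = segment direction. Before any pose, e_x is the world +X axis.
chain_frame <- function(dir) {
  e_z <- unit_vector(dir)
  e_x <- c(1, 0, 0)
  e_y <- unit_vector(cross3(e_z, e_x))
  if (e_y[2] < 0) e_y <- -e_y
  e_x <- cross3(e_y, e_z)
  cbind(e_x, e_y, e_z)
}

# --- rasterization ----------------------------------------------------------

# Rasterize one structure into `vox` (integer array, modified and returned).
# `inside_fn(pts)` takes an m x 3 world-coordinate matrix and returns logical.
# Half-voxel supersampling: a voxel gets the code when at least 4 of its
# 2x2x2 subsample points are inside, which keeps rasterized areas within ~2%
# of the analytic values at localizer resolution.
rasterize_into <- function(vox, spec, inside_fn, bbox_world, code) {
  lo <- pmax(1, floor(world_to_index(bbox_world$lo, spec$spacing, c(0, 0, 0))) - 1)
  hi <- pmin(spec$grid_shape,
             ceiling(world_to_index(bbox_world$hi, spec$spacing, c(0, 0, 0))) + 1)
  if (any(hi < lo)) return(vox)
  dims <- hi - lo + 1
  ind <- arrayInd(seq_len(prod(dims)), dims)
  ind <- sweep(ind, 2, lo - 1L, FUN = "+")
  base <- index_to_world(ind, spec$spacing, c(0, 0, 0))
  counts <- integer(nrow(base))
  # half-voxel subcell corners plus the voxel centre; the 5-of-9 majority
  # reduces exactly to the midpoint rule on straight boundaries (no edge
  # dilation bias) while still smoothing thin/curved structures
  offs <- rbind(as.matrix(expand.grid(c(-0.25, 0.25), c(-0.25, 0.25),
                                      c(-0.25, 0.25))), c(0, 0, 0))
  for (r in seq_len(nrow(offs))) {
    pts <- sweep(base, 2, offs[r, ] * spec$spacing, FUN = "+")
    counts <- counts + inside_fn(pts)
  }
  hit <- counts >= 5L
  if (any(hit)) {
    flat <- ind[hit, , drop = FALSE]
    lin <- flat[, 1] + (flat[, 2] - 1L) * spec$grid_shape[1] +
      (flat[, 3] - 1L) * spec$grid_shape[1] * spec$grid_shape[2]
    vox[lin] <- code
  }
  vox
}

# Inside test for an elliptic cylinder in a local frame.
elliptic_cylinder_fn <- function(centre, frame, semi_ap, semi_lr, height) {
  force(centre); force(frame)
  function(pts) {
    loc <- sweep(pts, 2, centre) %*% frame
    (loc[, 1] / semi_lr)^2 + (loc[, 2] / semi_ap)^2 <= 1 &
      abs(loc[, 3]) <= height / 2
  }
}

box_fn <- function(centre, frame, half) {
  function(pts) {
    loc <- sweep(pts, 2, centre) %*% frame
    abs(loc[, 1]) <= half[1] & abs(loc[, 2]) <= half[2] & abs(loc[, 3]) <= half[3]
  }
}

frame_bbox <- function(centre, frame, half) {
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  pts <- corners %*% diag(half) %*% t(frame)
  pts <- sweep(pts, 2, centre, FUN = "+")
  list(lo = apply(pts, 2, min), hi = apply(pts, 2, max))
}

# --- phantom generation -----------------------------------------------------

#' Generate a synthetic lumbar phantom
#'
#' Rasterizes the anatomy described by a [phantom_spec()] into a label volume
#' and an intensity volume, and returns the analytic ground truth (disc
#' centres and normals, all morphometry landmarks, true measurement values
#' and planted diagnoses). Deterministic given `(spec, spec$seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param intensity If `FALSE`, skip the intensity volume (saves memory for
#'   large cohorts where only labels and truth are needed).
#' @return A list with elements `labels` ([label_volume()]), `intensity`
#'   ([mri_volume()] or `NULL`) and `truth` (class `phantom_truth`).
#' @export
generate_phantom <- function(spec, intensity = TRUE) {
  validate_phantom_spec(spec)
  chain <- spine_chain(spec)
  n <- spec$n_discs
  g <- PHANTOM_GEOM
  pose_rot <- spec$pose$rotation
  pose_tr <- spec$pose$translation
  vc <- chain$volume_centre
  posed <- !all(pose_rot == 0) || !all(pose_tr == 0)

  tp <- function(p) if (posed) apply_rigid(p, pose_rot, pose_tr, vc) else p
  tv <- function(v) if (posed) drop(rotation_matrix(pose_rot) %*% v) else v

  # posed centres and frames for every chain structure
  centres <- tp(chain$centres)
  if (is.null(dim(centres))) centres <- matrix(centres, ncol = 3)
  frames <- lapply(seq_along(chain$index), function(j) {
    f <- chain_frame(chain$dirs[j, ])
    if (posed) rotation_matrix(pose_rot) %*% f else f
  })

  disc_idx <- which(chain$kind == "disc")
  vert_idx <- which(chain$kind == "vertebra")
  sac_idx <- which(chain$kind == "sacrum")

  world_lo <- -0.5 * spec$spacing
  world_hi <- (spec$grid_shape - 0.5) * spec$spacing
  check_bounds <- function(bbox, name) {
    if (any(bbox$lo < world_lo) || any(bbox$hi > world_hi))
      stop(sprintf("OutOfBounds: structure '%s' exceeds the grid after pose", name))
  }

  label_map <- phantom_label_map(spec)
  vox <- array(0L, dim = spec$grid_shape)

  # canal radius per chain structure (vertebra: mean of flanking discs)
  canal_r <- numeric(length(chain$index))
  canal_r[disc_idx] <- spec$canal_diameter / 2
  for (j in vert_idx) {
    k <- chain$level[j]
    adj <- c(if (k > 1) spec$canal_diameter[k - 1], spec$canal_diameter[min(k, n)])
    canal_r[j] <- mean(adj) / 2
  }
  canal_r[sac_idx] <- spec$canal_diameter[n] / 2

  vert_ap <- spec$disc_radii[, "ap"] - g$vertebra_radius_shrink
  vert_lr <- spec$disc_radii[, "lr"] - g$vertebra_radius_shrink

  # psoas: straight elliptic cylinders along the (posed) spine z range
  z_lo <- chain$centres[sac_idx, 3] + chain$heights[sac_idx] / 2
  z_hi <- chain$centres[1, 3] + chain$heights[1] / 2
  psoas_h <- z_hi - z_lo
  psoas_cz <- (z_hi + z_lo) / 2
  spine_x <- chain$volume_centre[1]
  spine_y <- chain$volume_centre[2] + g$spine_y_bias
  max_lr <- max(spec$disc_radii[, "lr"])

  # rasterization order encodes priority: later structures override earlier
  # ones where the half-voxel majority vote claims the same voxel.
  for (side in c("left", "right")) {
    sgn <- if (side == "left") -1 else 1
    a <- spec$psoas_semiaxes[side, "lr"]
    b <- spec$psoas_semiaxes[side, "ap"]
    ctr0 <- c(spine_x + sgn * (max_lr + g$psoas_gap + a),
              spine_y + g$psoas_anterior_offset, psoas_cz)
    ctr <- tp(ctr0)
    fr <- if (posed) rotation_matrix(pose_rot) %*% diag(3) else diag(3)
    bb <- frame_bbox(ctr, fr, c(a, b, psoas_h / 2))
    check_bounds(bb, paste0("psoas_", side))
    vox <- rasterize_into(vox, spec,
                          elliptic_cylinder_fn(ctr, fr, b, a, psoas_h),
                          bb, label_map[[paste0("psoas_", side)]])
  }

  for (j in seq_along(chain$index)) {      # canal segments
    # posterior offset uses the level's disc AP semi-axis (sacrum: last level)
    k <- if (is.na(chain$level[j])) n else min(chain$level[j], n)
    ap <- spec$disc_radii[k, "ap"]
    f0 <- chain_frame(chain$dirs[j, ])
    ctr0 <- chain$centres[j, ] - f0[, 2] * (ap + canal_r[j])
    ctr <- tp(ctr0)
    fr <- frames[[j]]
    hh <- chain$heights[j] * 1.02
    bb <- frame_bbox(ctr, fr, c(canal_r[j], canal_r[j], hh / 2))
    check_bounds(bb, "canal")
    vox <- rasterize_into(vox, spec,
                          elliptic_cylinder_fn(ctr, fr, canal_r[j], canal_r[j], hh),
                          bb, label_map[["canal"]])
  }

  for (k in seq_len(n)) {                  # spinous process blocks, per disc level
    j <- disc_idx[k]
    fr <- frames[[j]]
    ap <- spec$disc_radii[k, "ap"]
    ctr <- centres[j, ] - fr[, 2] * (ap + spec$canal_diameter[k] + g$spinous_length / 2)
    half <- c(g$spinous_half_width, g$spinous_length / 2, spec$disc_heights[k] / 2 + 2)
    bb <- frame_bbox(ctr, fr, half)
    check_bounds(bb, "spinous_process")
    vox <- rasterize_into(vox, spec, box_fn(ctr, fr, half), bb,
                          label_map[["spinous_process"]])
  }

  for (j in vert_idx) {                    # vertebral bodies
    k <- chain$level[j]
    fr <- frames[[j]]
    bb <- frame_bbox(centres[j, ], fr, c(vert_lr[k], vert_ap[k], chain$heights[j] / 2))
    check_bounds(bb, spec$vertebra_labels[k])
    vox <- rasterize_into(vox, spec,
                          elliptic_cylinder_fn(centres[j, ], fr, vert_ap[k],
                                               vert_lr[k], chain$heights[j]),
                          bb, label_map[[spec$vertebra_labels[k]]])
  }
  {                                        # sacral base
    j <- sac_idx
    fr <- frames[[j]]
    bb <- frame_bbox(centres[j, ], fr, c(vert_lr[n], vert_ap[n], chain$heights[j] / 2))
    check_bounds(bb, "S1")
    vox <- rasterize_into(vox, spec,
                          elliptic_cylinder_fn(centres[j, ], fr, vert_ap[n],
                                               vert_lr[n], chain$heights[j]),
                          bb, label_map[["S1"]])
  }

  for (k in seq_len(n)) {                  # discs
    j <- disc_idx[k]
    fr <- frames[[j]]
    bb <- frame_bbox(centres[j, ], fr,
                     c(spec$disc_radii[k, "lr"], spec$disc_radii[k, "ap"],
                       chain$heights[j] / 2))
    check_bounds(bb, spec$disc_labels[k])
    vox <- rasterize_into(vox, spec,
                          elliptic_cylinder_fn(centres[j, ], fr,
                                               spec$disc_radii[k, "ap"],
                                               spec$disc_radii[k, "lr"],
                                               chain$heights[j]),
                          bb, label_map[[spec$disc_labels[k]]])
  }

  if (!is.null(spec$herniation)) {         # planted posterior bumps
    for (lvl in names(spec$herniation)) {
      h <- spec$herniation[[lvl]]
      if (h$extent <= 0) next
      k <- match(lvl, spec$disc_labels)
      j <- disc_idx[k]
      fr <- frames[[j]]
      ap <- spec$disc_radii[k, "ap"]
      xoff <- herniation_lateral_offset(h$zone, g$intra_facet_half_length)
      base_pt <- centres[j, ] - fr[, 2] * ap + fr[, 1] * xoff
      semi <- c(g$herniation_lr_semiaxis, h$extent, spec$disc_heights[k] / 2)
      bb <- frame_bbox(base_pt, fr, semi)
      check_bounds(bb, paste0("herniation_", lvl))
      inside <- local({
        ctr <- base_pt; f <- fr; s <- semi
        function(pts) {
          loc <- sweep(pts, 2, ctr) %*% f
          (loc[, 1] / s[1])^2 + (loc[, 2] / s[2])^2 + (loc[, 3] / s[3])^2 <= 1 &
            loc[, 2] <= 0
        }
      })
      vox <- rasterize_into(vox, spec, inside, bb, label_map[["herniation"]])
    }
  }

  labels <- label_volume(vox, spec$spacing, c(0, 0, 0), label_map)

  intens <- NULL
  if (intensity) {
    means <- PHANTOM_INTENSITY
    lut <- rep(means[["background"]], max(label_map) + 1L)
    for (nm in names(label_map)) {
      cls <- if (nm %in% spec$vertebra_labels) "vertebra"
      else if (nm == "S1") "sacrum"
      else if (nm %in% spec$disc_labels) "disc"
      else if (nm %in% c("psoas_left", "psoas_right")) "psoas"
      else nm
      lut[label_map[[nm]] + 1L] <- means[[cls]]
    }
    ivox <- array(lut[vox + 1L], dim = spec$grid_shape)
    if (spec$noise_sd > 0) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      set.seed(spec$seed)
      ivox <- ivox + array(stats::rnorm(length(ivox), 0, spec$noise_sd),
                           dim = spec$grid_shape)
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    }
    intens <- mri_volume(ivox, spec$spacing, c(0, 0, 0))
  }

  truth <- phantom_ground_truth(spec, chain, centres, frames)
  list(labels = labels, intensity = intens, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

herniation_lateral_offset <- function(zone, half_len) {
  switch(zone, A = 0, B = 0.75 * half_len, C = 1.1 * half_len)
}

# Analytic ground truth: landmarks and true measurement values, all in posed
# world coordinates.
phantom_ground_truth <- function(spec, chain, centres, frames) {
  n <- spec$n_discs
  g <- PHANTOM_GEOM
  disc_idx <- which(chain$kind == "disc")
  vert_idx <- which(chain$kind == "vertebra")

  disc_centres <- centres[disc_idx, , drop = FALSE]
  rownames(disc_centres) <- spec$disc_labels
  disc_normals <- t(vapply(disc_idx, function(j) frames[[j]][, 3], numeric(3)))
  rownames(disc_normals) <- spec$disc_labels
  vert_centres <- centres[vert_idx, , drop = FALSE]
  rownames(vert_centres) <- spec$vertebra_labels

  landmarks <- stats::setNames(vector("list", n), spec$disc_labels)
  true_meas <- stats::setNames(vector("list", n), spec$disc_labels)
  diagnoses <- stats::setNames(vector("list", n), spec$disc_labels)

  psoas_area <- c(left = pi * prod(spec$psoas_semiaxes["left", ]),
                  right = pi * prod(spec$psoas_semiaxes["right", ]))

  for (k in seq_len(n)) {
    j <- disc_idx[k]
    fr <- frames[[j]]
    ex <- fr[, 1]; ey <- fr[, 2]; ez <- fr[, 3]
    c0 <- centres[j, ]
    ap <- spec$disc_radii[k, "ap"]
    lr <- spec$disc_radii[k, "lr"]
    h <- spec$disc_heights[k]

    post <- c0 - ey * ap
    lm <- list(
      posterior_disc_edge_mid = post,
      spinous_process_mid = post - ey * spec$canal_diameter[k],
      anterior_disc_point = c0 + ey * ap,
      disc_superior_edge_mid = c0 + ez * h / 2,
      disc_inferior_edge_mid = c0 - ez * h / 2,
      vertical_direction = ez,
      midline_direction = ey,
      intra_facet_line = list(
        p1 = post - ey * g$intra_facet_offset - ex * g$intra_facet_half_length,
        p2 = post - ey * g$intra_facet_offset + ex * g$intra_facet_half_length)
    )
    for (side in c("left", "right")) {
      sgn <- if (side == "left") -1 else 1
      fh <- spec$foramen_height[k, side]
      fbase <- c0 + ex * sgn * (lr + g$foramen_lateral_gap) - ey * 0.6 * ap
      lm[[paste0("foramen_superior_", side)]] <- fbase + ez * fh / 2
      lm[[paste0("foramen_inferior_", side)]] <- fbase - ez * fh / 2

      rp <- c0 + ex * sgn * g$recess_lateral_offset - ey * ap
      lm[[paste0("recess_disc_posterior_", side)]] <- rp
      lm[[paste0("sap_medial_edge_", side)]] <- rp - ey * spec$recess_height[k, side]
      th <- spec$recess_angle[k, side] * pi / 180
      lm[[paste0("recess_superior_dir_", side)]] <-
        cos(th / 2) * ey + sin(th / 2) * ex
      lm[[paste0("recess_inferior_dir_", side)]] <-
        cos(th / 2) * ey - sin(th / 2) * ex

      phi <- spec$facet_angle[k, side] * pi / 180
      fdir <- cos(phi) * ey + sgn * sin(phi) * ex
      fanchor <- c0 + ex * sgn * g$facet_lateral_offset -
        ey * (ap + g$facet_posterior_offset)
      lm[[paste0("facet_line_", side)]] <-
        list(p1 = fanchor - 5 * fdir, p2 = fanchor + 5 * fdir)
    }

    hern <- spec$herniation[[spec$disc_labels[k]]]
    extent <- if (is.null(hern)) 0 else hern$extent
    hr <- if (extent > 0) {
      (pi / 2) * g$herniation_lr_semiaxis * extent /
        (pi * (spec$canal_diameter[k] / 2)^2)
    } else 0
    if (extent > 0) {
      lm$herniation_apex <- post - ey * extent +
        ex * herniation_lateral_offset(hern$zone, g$intra_facet_half_length)
    }

    landmarks[[k]] <- lm
    side_pair <- function(m) c(left = unname(m[k, "left"]),
                               right = unname(m[k, "right"]))
    true_meas[[k]] <- list(
      disc_vertical_diameter = h,
      canal_diameter = spec$canal_diameter[k],
      foramen_height = side_pair(spec$foramen_height),
      psoas_csa = psoas_area,
      facet_joint_angle = side_pair(spec$facet_angle),
      lateral_recess_height = side_pair(spec$recess_height),
      lateral_recess_angle = side_pair(spec$recess_angle),
      herniation_ratio = hr
    )
    diagnoses[[k]] <- list(
      canal_stenosis = spec$canal_diameter[k] < 10,
      recess_stenosis_left = spec$recess_height[k, "left"] < 3 ||
        spec$recess_angle[k, "left"] < 30,
      recess_stenosis_right = spec$recess_height[k, "right"] < 3 ||
        spec$recess_angle[k, "right"] < 30,
      herniation = extent > 0
    )
  }

  structure(list(disc_centers = disc_centres,
                 disc_normals = disc_normals,
                 vertebra_centers = vert_centres,
                 landmarks = landmarks,
                 true_measurements = true_meas,
                 planted_diagnoses = diagnoses,
                 pose = spec$pose,
                 disc_labels = spec$disc_labels),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d discs: %s\n", nrow(x$disc_centers),
              paste(rownames(x$disc_centers), collapse = ", ")))
  invisible(x)
}

# --- posing an existing label volume ---------------------------------------

#' Apply a rigid pose to a label volume
#'
#' Nearest-neighbour resampling of the voxel labels under a rigid transform
#' (rotation in degrees about the volume centre, then translation in mm).
#' The label set is preserved; an error is raised if any labeled voxel would
#' leave the grid.
#'
#' @param volume A [label_volume()].
#' @param rotation Degrees triple (about X, then Y, then Z).
#' @param translation mm triple.
#' @return A posed [label_volume()].
#' @export
apply_pose <- function(volume, rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  stopifnot(inherits(volume, "label_volume"))
  dims <- dim(volume$voxels)
  centre <- volume$origin + (dims - 1) * volume$spacing / 2

  lab_idx <- which(volume$voxels != 0L)
  if (length(lab_idx)) {
    pts <- index_to_world(arrayInd(lab_idx, dims), volume$spacing, volume$origin)
    fwd <- apply_rigid(pts, rotation, translation, centre)
    lo <- volume$origin - 0.5 * volume$spacing
    hi <- volume$origin + (dims - 0.5) * volume$spacing
    if (any(sweep(fwd, 2, lo) < 0) || any(sweep(fwd, 2, hi) > 0))
      stop("OutOfBounds: pose pushes labeled voxels outside the grid")
  }

  out_pts <- voxel_world_coords(dims, volume$spacing, volume$origin)
  R <- rotation_matrix(rotation)
  src <- sweep(out_pts, 2, centre + translation) %*% R  # == (p - pivot - t) %*% t(R^T)
  src <- sweep(src, 2, centre, FUN = "+")
  src_idx <- round(world_to_index(src, volume$spacing, volume$origin))
  ok <- src_idx[, 1] >= 1 & src_idx[, 1] <= dims[1] &
    src_idx[, 2] >= 1 & src_idx[, 2] <= dims[2] &
    src_idx[, 3] >= 1 & src_idx[, 3] <= dims[3]
  new_vox <- integer(prod(dims))
  lin <- src_idx[ok, 1] + (src_idx[ok, 2] - 1) * dims[1] +
    (src_idx[ok, 3] - 1) * dims[1] * dims[2]
  new_vox[ok] <- volume$voxels[lin]
  label_volume(array(new_vox, dims), volume$spacing, volume$origin,
               volume$label_map)
}
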