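# Lumbar morphometry and diagnostic rules.
#
# All measurements operate on per-level landmark sets (from phantom ground
# truth or an extraction routine) and on label volumes for the area-based
# quantities, decoupling the geometry from segmentation quality. "Vertical"
# distances are projections onto the level's head-foot axis (the landmark
# set's `vertical_direction`), matching how the readings are taken on
# sagittal images of a curved, possibly posed spine.
#
# Diagnostic thresholds (strict inequalities, boundary = negative finding):
#   spinal canal stenosis:   canal diameter < 10 mm
#   lateral recess stenosis: recess height < 3 mm OR recess angle < 30 deg
#   herniation:              MSU grade >= 1
# The recess-angle comparison direction is configurable (see
# [diagnostic_thresholds()]): the source literature states both directions
# in different places; the default follows the results convention (< 30 deg
# indicates stenosis).

#' Default diagnostic thresholds
#'
#' @param canal_mm Canal-diameter threshold (default 10).
#' @param recess_height_mm Recess-height threshold (default 3).
#' @param recess_angle_deg Recess-angle threshold (default 30).
#' @param recess_angle_direction `"less"` (angle below threshold = stenosis,
#'   default) or `"greater"`.
#' @return Named list of thresholds.
#' @export
diagnostic_thresholds <- function(canal_mm = 10, recess_height_mm = 3,
                                  recess_angle_deg = 30,
                                  recess_angle_direction = c("less", "greater")) {
  list(canal_mm = canal_mm, recess_height_mm = recess_height_mm,
       recess_angle_deg = recess_angle_deg,
       recess_angle_direction = match.arg(recess_angle_direction))
}

need_landmark <- function(lm, name) {
  v <- lm[[name]]
  if (is.null(v) || anyNA(unlist(v))) stop("MissingLandmark: ", name)
  v
}

#' Offset angle between two positioning lines
#'
#' Angle between the standard and the actual positioning line, treated as
#' undirected lines, so the result is in [0, 90] degrees.
#'
#' @param standard_line,actual_line Direction vectors.
#' @return Degrees in [0, 90].
#' @export
measure_offset_angle <- function(standard_line, actual_line) {
  angle_between_lines(standard_line, actual_line)
}

#' Disc vertical diameter
#'
#' Distance between the superior and inferior disc edge midpoints projected
#' onto the level's head-foot axis.
#'
#' @param landmarks Per-level landmark list (see phantom ground truth).
#' @return mm.
#' @export
measure_disc_vertical_diameter <- function(landmarks) {
  s <- need_landmark(landmarks, "disc_superior_edge_mid")
  i <- need_landmark(landmarks, "disc_inferior_edge_mid")
  ax <- unit_vector(need_landmark(landmarks, "vertical_direction"))
  abs(sum((s - i) * ax))
}

#' Foraminal height
#'
#' Vertical distance between the superior and inferior foraminal borders on
#' the given side.
#'
#' @inheritParams measure_disc_vertical_diameter
#' @param side `"left"` or `"right"`.
#' @return mm.
#' @export
measure_foramen_height <- function(landmarks, side = c("left", "right")) {
  side <- match.arg(side)
  s <- need_landmark(landmarks, paste0("foramen_superior_", side))
  i <- need_landmark(landmarks, paste0("foramen_inferior_", side))
  ax <- unit_vector(need_landmark(landmarks, "vertical_direction"))
  abs(sum((s - i) * ax))
}

#' Psoas cross-sectional area at mid-vertebral level
#'
#' Counts the side's psoas voxels on the axial slice through the vertebral
#' body centre and multiplies by the in-plane voxel area.
#'
#' @param labels A [label_volume()] with `psoas_left` / `psoas_right` codes.
#' @param vertebra_center World point (mm) of the vertebra of interest (the
#'   slice is taken at its Z).
#' @param side `"left"` or `"right"`.
#' @return Area in mm^2.
#' @export
measure_psoas_csa <- function(labels, vertebra_center, side = c("left", "right")) {
  side <- match.arg(side)
  code <- labels$label_map[[paste0("psoas_", side)]]
  kz <- round((vertebra_center[3] - labels$origin[3]) / labels$spacing[3]) + 1
  if (kz < 1 || kz > dim(labels$voxels)[3])
    stop("MissingStructure: slice outside the grid")
  slice <- labels$voxels[, , kz]
  n <- sum(slice == code)
  if (n == 0) stop("MissingStructure: no psoas voxels on the mid-vertebral slice")
  n * labels$spacing[1] * labels$spacing[2]
}

#' Facet joint angle
#'
#' Angle between the side's facet line and the midline direction at the
#' mid-disc level, in [0, 90] degrees.
#'
#' @inheritParams measure_foramen_height
#' @return Degrees.
#' @export
measure_facet_joint_angle <- function(landmarks, side = c("left", "right")) {
  side <- match.arg(side)
  fl <- need_landmark(landmarks, paste0("facet_line_", side))
  mid <- need_landmark(landmarks, "midline_direction")
  dirv <- fl$p2 - fl$p1
  if (vec_norm(dirv) < 1e-9) stop("DegenerateDirection: facet line endpoints coincide")
  angle_between_lines(dirv, mid)
}

#' Spinal canal diameter
#'
#' Euclidean distance from the posterior disc edge midpoint to the spinous
#' process midpoint at the mid-disc level.
#'
#' @inheritParams measure_disc_vertical_diameter
#' @return mm.
#' @export
measure_canal_diameter <- function(landmarks) {
  p <- need_landmark(landmarks, "posterior_disc_edge_mid")
  s <- need_landmark(landmarks, "spinous_process_mid")
  vec_norm(p - s)
}

#' Lateral recess height and angle
#'
#' Height: distance between the medial edge of the superior articular
#' process and the posterior disc edge on that side. Angle: angle between
#' the lines parallel to the superior and inferior recess borders.
#'
#' @inheritParams measure_foramen_height
#' @return Named numeric `c(height, angle)`.
#' @export
measure_lateral_recess <- function(landmarks, side = c("left", "right")) {
  side <- match.arg(side)
  sap <- need_landmark(landmarks, paste0("sap_medial_edge_", side))
  pd <- need_landmark(landmarks, paste0("recess_disc_posterior_", side))
  su <- need_landmark(landmarks, paste0("recess_superior_dir_", side))
  inf <- need_landmark(landmarks, paste0("recess_inferior_dir_", side))
  c(height = vec_norm(sap - pd), angle = angle_between_lines(su, inf))
}

#' Disc herniation ratio
#'
#' Maximum over the level's axial slices of the herniated-disc area divided
#' by the spinal canal area on the same slice. The canal area includes the
#' voxels displaced by the herniation (the canal boundary, not the residual
#' lumen).
#'
#' @param labels A [label_volume()] with `herniation` and `canal` codes.
#' @param level_z Z (mm) of the disc centre; slices within half the disc
#'   height are evaluated.
#' @param half_span mm above/below `level_z` to search (default 6).
#' @return Ratio >= 0 (0 when no herniation voxels exist at the level).
#' @export
herniation_ratio <- function(labels, level_z, half_span = 6) {
  hcode <- labels$label_map[["herniation"]]
  ccode <- labels$label_map[["canal"]]
  dims <- dim(labels$voxels)
  kz <- round((level_z + c(-1, 1) * half_span - labels$origin[3]) /
                labels$spacing[3]) + 1
  kz <- max(1, kz[1]):min(dims[3], kz[2])
  best <- 0
  any_canal <- FALSE
  for (k in kz) {
    slice <- labels$voxels[, , k]
    ha <- sum(slice == hcode)
    ca <- sum(slice == ccode) + ha
    if (ca == 0) next
    any_canal <- TRUE
    best <- max(best, ha / ca)
  }
  if (!any_canal) stop("DegenerateCanal: no canal area at the level")
  best
}

#' MSU grade and zone of a disc herniation
#'
#' Grades the herniation extent against the intra-facet line: the apex short
#' of 50% of the posterior-margin-to-line distance is grade 1, between 50%
#' and the line grade 2, beyond the line grade 3. The zone comes from the
#' mediolateral apex position along the intra-facet line: the central two
#' quarters are zone A, the outer quarters zone B, beyond the line's
#' endpoints zone C. Extent 0 returns grade "none".
#'
#' @param apex World point of the herniation apex (or `NULL` for none).
#' @param posterior_margin World point of the posterior disc margin at the
#'   herniation's mediolateral position.
#' @param intra_facet_line List with `p1`, `p2` world endpoints.
#' @param midline_direction Unit vector (anterior-posterior) of the level.
#' @return List `grade` ("none", "1", "2", "3") and `zone` ("A", "B", "C" or
#'   `NA` for none).
#' @export
msu_classify <- function(apex, posterior_margin, intra_facet_line,
                         midline_direction) {
  if (is.null(apex)) return(list(grade = "none", zone = NA_character_))
  p1 <- intra_facet_line$p1
  p2 <- intra_facet_line$p2
  lv <- p2 - p1
  if (vec_norm(lv) < 1e-9) stop("DegenerateLandmark: intra-facet line")
  mid_if <- (p1 + p2) / 2
  ey <- unit_vector(midline_direction)     # anterior
  # posterior depth of apex and of the intra-facet line, from the disc margin
  depth_apex <- sum((posterior_margin - apex) * ey)
  depth_line <- sum((posterior_margin - mid_if) * ey)
  if (depth_line <= 0) stop("DegenerateLandmark: intra-facet line anterior to disc margin")
  if (depth_apex <= 0) return(list(grade = "none", zone = NA_character_))
  grade <- if (depth_apex < 0.5 * depth_line) "1"
  else if (depth_apex <= depth_line) "2"
  else "3"
  # mediolateral position along the intra-facet line
  u <- unit_vector(lv)
  t_apex <- abs(sum((apex - mid_if) * u))
  half <- vec_norm(lv) / 2
  zone <- if (t_apex <= half / 2) "A" else if (t_apex <= half) "B" else "C"
  list(grade = grade, zone = zone)
}

#' Full morphometry report for one phantom
#'
#' Runs every measurement on the ground-truth landmark set (and the label
#' volume for the area-based quantities) and applies the diagnostic rules.
#'
#' @param labels A [label_volume()].
#' @param truth A `phantom_truth` (for landmarks and vertebra centres).
#' @param thresholds A [diagnostic_thresholds()] list.
#' @param planned_normals Optional matrix of planned transverse normals
#'   (rows named by level) used to fill the per-level offset angle against
#'   the true disc normals.
#' @return Object of class `morphometry_report`: `measurements` (data frame,
#'   one row per level), `diagnoses` (data frame), `thresholds`.
#' @export
morphometry_report <- function(labels, truth,
                               thresholds = diagnostic_thresholds(),
                               planned_normals = NULL) {
  levels <- truth$disc_labels
  rows <- list()
  diags <- list()
  for (k in seq_along(levels)) {
    lvl <- levels[k]
    lm <- truth$landmarks[[lvl]]
    rec_l <- measure_lateral_recess(lm, "left")
    rec_r <- measure_lateral_recess(lm, "right")
    vert_name <- vertebra_above(lvl)
    vc <- truth$vertebra_centers[vert_name, ]
    csa_l <- measure_psoas_csa(labels, vc, "left")
    csa_r <- measure_psoas_csa(labels, vc, "right")
    hr <- tryCatch(herniation_ratio(labels, truth$disc_centers[lvl, 3]),
                   error = function(e) NA_real_)
    msu <- msu_classify(lm$herniation_apex %||% NULL,
                        lm$posterior_disc_edge_mid,
                        lm$intra_facet_line, lm$midline_direction)
    off <- if (!is.null(planned_normals) && lvl %in% rownames(planned_normals))
      measure_offset_angle(truth$disc_normals[lvl, ], planned_normals[lvl, ])
    else NA_real_
    rows[[lvl]] <- data.frame(
      level = lvl,
      offset_angle = off,
      disc_vertical_diameter = measure_disc_vertical_diameter(lm),
      canal_diameter = measure_canal_diameter(lm),
      foramen_height_left = measure_foramen_height(lm, "left"),
      foramen_height_right = measure_foramen_height(lm, "right"),
      psoas_csa_left = csa_l, psoas_csa_right = csa_r,
      facet_joint_angle_left = measure_facet_joint_angle(lm, "left"),
      facet_joint_angle_right = measure_facet_joint_angle(lm, "right"),
      lateral_recess_height_left = rec_l[["height"]],
      lateral_recess_angle_left = rec_l[["angle"]],
      lateral_recess_height_right = rec_r[["height"]],
      lateral_recess_angle_right = rec_r[["angle"]],
      herniation_ratio = ifelse(is.na(hr), 0, hr),
      msu_grade = msu$grade, msu_zone = msu$zone %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  meas <- do.call(rbind, rows)
  rownames(meas) <- NULL
  rep <- structure(list(measurements = meas, thresholds = thresholds),
                   class = "morphometry_report")
  rep$diagnoses <- diagnose(rep, thresholds)
  rep
}

#' Apply the diagnostic rules to a morphometry report
#'
#' Pure function of the measurements and thresholds. Canal stenosis: canal
#' diameter strictly below the canal threshold. Lateral recess stenosis (per
#' side): recess height strictly below the height threshold OR recess angle
#' on the stenotic side of the angle threshold. Herniation: MSU grade >= 1.
#' Missing measurements yield `NA` ("indeterminate"), never a silent
#' negative.
#'
#' @param report A `morphometry_report` (or anything with a `measurements`
#'   data frame).
#' @param thresholds A [diagnostic_thresholds()] list.
#' @return Data frame, one row per level: `canal_stenosis`,
#'   `recess_stenosis_left`, `recess_stenosis_right`, `herniation`.
#' @export
diagnose <- function(report, thresholds = diagnostic_thresholds()) {
  m <- report$measurements
  angle_arm <- function(a) {
    if (thresholds$recess_angle_direction == "less")
      a < thresholds$recess_angle_deg
    else a > thresholds$recess_angle_deg
  }
  data.frame(
    level = m$level,
    canal_stenosis = m$canal_diameter < thresholds$canal_mm,
    recess_stenosis_left = m$lateral_recess_height_left < thresholds$recess_height_mm |
      angle_arm(m$lateral_recess_angle_left),
    recess_stenosis_right = m$lateral_recess_height_right < thresholds$recess_height_mm |
      angle_arm(m$lateral_recess_angle_right),
    herniation = m$msu_grade %in% c("1", "2", "3"),
    stringsAsFactors = FALSE)
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("<morphometry_report> %d level(s)\n", nrow(x$measurements)))
  print(x$measurements[, c("level", "disc_vertical_diameter", "canal_diameter",
                           "lateral_recess_height_left", "msu_grade")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Detection rate of a condition over a cohort
#'
#' Proportion of positive findings for the named condition at the named
#' level across a list of diagnosis data frames.
#'
#' @param diagnoses_list List of data frames as returned by [diagnose()].
#' @param condition Column name (`"canal_stenosis"`,
#'   `"recess_stenosis_left"`, `"recess_stenosis_right"`, `"herniation"`).
#' @param level Disc level name (e.g. `"L4/5"`).
#' @return Fraction in [0, 1].
#' @export
detection_rate <- function(diagnoses_list, condition, level) {
  if (length(diagnoses_list) == 0) stop("EmptyCohort")
  pos <- vapply(diagnoses_list, function(d) {
    row <- d[d$level == level, condition]
    isTRUE(row)
  }, logical(1))
  mean(pos)
}
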