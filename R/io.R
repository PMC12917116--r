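# NIfTI, JSON and CSV input/output, plus pipeline configuration.

#' Write a volume to NIfTI-1
#'
#' @param volume An [mri_volume()] or [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "mri_volume"))
  vox <- volume$voxels
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' Volumes are reoriented to RAS+ when stored otherwise (a message notes
#' the reorientation). The voxel data round-trips bit-exactly through
#' [write_volume()] / `read_volume()`.
#'
#' @param path NIfTI file.
#' @param label_map Optional named integer vector; when given, the result is
#'   a [label_volume()].
#' @return An [mri_volume()] or [label_volume()].
#' @export
read_volume <- function(path, label_map = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("FormatError: ", conditionMessage(e)))
  orient <- tryCatch(RNifti::orientation(img),
                     error = function(e) stop("FormatError: missing affine"))
  if (!identical(orient, "RAS")) {
    message("read_volume: reorienting ", orient, " -> RAS")
    RNifti::orientation(img) <- "RAS"
  }
  aff <- RNifti::xform(img)
  spacing <- abs(diag(aff)[1:3])
  if (any(spacing == 0)) stop("FormatError: zero spacing in affine")
  origin <- aff[1:3, 4]
  vox <- array(as.vector(img), dim = dim(img)[1:3])
  if (is.null(label_map)) {
    mri_volume(vox, spacing, origin)
  } else {
    label_volume(array(as.integer(round(vox)), dim = dim(vox)),
                 spacing, origin, label_map)
  }
}

round_sig <- function(x, digits = 6) {
  if (is.numeric(x)) signif(x, digits) else x
}

# Recursively order list keys and round numerics for deterministic JSON.
canonical_json_ready <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x))))
      x <- x[order(names(x))]
    lapply(x, canonical_json_ready)
  } else if (is.data.frame(x)) {
    x[] <- lapply(x, round_sig)
    x
  } else {
    round_sig(x)
  }
}

write_json_report <- function(x, path) {
  txt <- jsonlite::toJSON(canonical_json_ready(x), auto_unbox = TRUE,
                          digits = NA, na = "null", pretty = TRUE)
  writeLines(txt, path)
  invisible(path)
}

plane_to_list <- function(p) {
  list(center = as.numeric(p$center), normal = as.numeric(p$normal),
       in_plane_axes = lapply(p$in_plane_axes, as.numeric),
       extent = as.numeric(p$extent))
}

#' Serialize a scan plan or morphometry report
#'
#' JSON output is deterministic: keys sorted, floats at 6 significant
#' digits. CSV output for a morphometry report is long format, one row per
#' level and side.
#'
#' @param report A `scan_plan`, `morphometry_report` or plain list.
#' @param path Output file.
#' @param format `"json"` or `"csv"` (CSV only for morphometry reports).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!inherits(report, "morphometry_report"))
      stop("csv output is only defined for morphometry reports")
    df <- morphometry_long(report)
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  obj <- if (inherits(report, "scan_plan")) {
    list(type = "scan_plan",
         sagittal = plane_to_list(report$sagittal),
         coronal = plane_to_list(report$coronal),
         transverse = lapply(report$transverse, plane_to_list),
         sat_band = report$sat_band[c("center", "normal", "thickness",
                                      "offset_distance")],
         quality_factor = report$quality_factor,
         disc_labels = report$disc_labels,
         vertebra_labels = unname(report$vertebra_labels),
         disc_centers = if (!is.null(report$disc_centers))
           apply(report$disc_centers, 1, as.numeric, simplify = FALSE))
  } else if (inherits(report, "morphometry_report")) {
    list(type = "morphometry_report",
         measurements = report$measurements,
         diagnoses = report$diagnoses,
         thresholds = report$thresholds)
  } else {
    report
  }
  write_json_report(obj, path)
}

# Long (level x side) table of the side-resolved metrics.
morphometry_long <- function(report) {
  m <- report$measurements
  out <- list()
  for (side in c("left", "right")) {
    out[[side]] <- data.frame(
      level = m$level, side = side,
      offset_angle = m$offset_angle,
      disc_vertical_diameter = m$disc_vertical_diameter,
      canal_diameter = m$canal_diameter,
      foramen_height = m[[paste0("foramen_height_", side)]],
      psoas_csa = m[[paste0("psoas_csa_", side)]],
      facet_joint_angle = m[[paste0("facet_joint_angle_", side)]],
      lateral_recess_height = m[[paste0("lateral_recess_height_", side)]],
      lateral_recess_angle = m[[paste0("lateral_recess_angle_", side)]],
      herniation_ratio = m$herniation_ratio,
      msu_grade = m$msu_grade,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$level, res$side), ]
}

# --- ground truth serialization --------------------------------------------

serialize_truth <- function(truth) {
  list(
    disc_labels = truth$disc_labels,
    disc_centers = asplit_named(truth$disc_centers),
    disc_normals = asplit_named(truth$disc_normals),
    vertebra_centers = asplit_named(truth$vertebra_centers),
    landmarks = lapply(truth$landmarks, function(lm)
      lapply(lm, function(v) if (is.list(v)) lapply(v, as.numeric) else as.numeric(v))),
    true_measurements = truth$true_measurements,
    planted_diagnoses = truth$planted_diagnoses,
    pose = truth$pose)
}

asplit_named <- function(m) {
  stats::setNames(lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])),
                  rownames(m))
}

#' Write phantom ground truth as JSON
#' @param truth A `phantom_truth`.
#' @param path Output file.
#' @export
write_ground_truth <- function(truth, path) {
  write_json_report(serialize_truth(truth), path)
}

#' Read phantom ground truth from JSON
#' @param path JSON file written by [write_ground_truth()].
#' @return A `phantom_truth`.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  to_mat <- function(lst) {
    m <- do.call(rbind, lapply(lst, as.numeric))
    rownames(m) <- names(lst)
    m
  }
  lmk <- lapply(x$landmarks, function(lm)
    lapply(lm, function(v) if (is.list(v)) lapply(v, as.numeric) else as.numeric(v)))
  structure(list(disc_centers = to_mat(x$disc_centers),
                 disc_normals = to_mat(x$disc_normals),
                 vertebra_centers = to_mat(x$vertebra_centers),
                 landmarks = lmk,
                 true_measurements = x$true_measurements,
                 planted_diagnoses = x$planted_diagnoses,
                 pose = x$pose,
                 disc_labels = unlist(x$disc_labels)),
            class = "phantom_truth")
}

# --- pipeline configuration -------------------------------------------------

#' Default pipeline configuration
#'
#' All tunable constants of the pipeline in one place. The diagnostic
#' thresholds (canal 10 mm, recess height 3 mm, recess angle 30 deg), the
#' 6 mm identification tolerance, the heat peak 256 and the focal-loss
#' gamma = 2 are the published method constants; the rest are package
#' defaults.
#'
#' @return Nested named list.
#' @export
pipeline_config <- function() {
  list(
    heatmap = list(sigma = 6, threshold = 128),
    labeling = list(adjacent_spacing = 37, gate = 15, tolerance = 6),
    planning = list(sat_offset = 10, sat_thickness = 30),
    thresholds = list(canal_mm = 10, recess_height_mm = 3,
                      recess_angle_deg = 30, recess_angle_direction = "less"),
    loss = list(gamma = 2),
    seed = 1L)
}

#' Read and validate a pipeline configuration
#'
#' YAML or JSON; unknown keys are rejected and out-of-range values reported
#' by name.
#'
#' @param path Config file, or `NULL` for defaults.
#' @return Validated config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- pipeline_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  merge_validate <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      full <- paste0(prefix, k)
      if (!k %in% names(base)) stop("unknown config key: ", full)
      if (is.list(base[[k]])) {
        base[[k]] <- merge_validate(base[[k]], upd[[k]], paste0(full, "."))
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  cfg <- merge_validate(cfg, user)
  positive <- c("heatmap.sigma", "heatmap.threshold", "labeling.adjacent_spacing",
                "labeling.gate", "labeling.tolerance", "planning.sat_offset",
                "planning.sat_thickness", "thresholds.canal_mm",
                "thresholds.recess_height_mm", "thresholds.recess_angle_deg")
  for (key in positive) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.numeric(v) || v <= 0)
      stop(sprintf("config key %s must be a positive number", key))
  }
  if (!cfg$thresholds$recess_angle_direction %in% c("less", "greater"))
    stop("config key thresholds.recess_angle_direction must be 'less' or 'greater'")
  if (cfg$loss$gamma < 0) stop("config key loss.gamma must be >= 0")
  cfg
}
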