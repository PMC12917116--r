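# Volume containers.
#
# A volume is a 3D array plus voxel spacing (mm) and world origin (mm, RAS+).
# Label volumes additionally carry a name -> integer code map with background
# fixed at 0.

#' Create an intensity volume
#'
#' @param voxels 3D numeric array.
#' @param spacing Voxel spacing in mm (length 3).
#' @param origin World coordinates (mm) of the centre of voxel `[1, 1, 1]`.
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "mri_volume")
}

#' Create a label volume
#'
#' @inheritParams mri_volume
#' @param label_map Named integer vector mapping structure names to voxel
#'   codes. Codes must be positive and unique; background is 0.
#' @return An object of class `label_volume` (inherits `mri_volume`).
#' @export
label_volume <- function(voxels, spacing, origin = c(0, 0, 0), label_map) {
  obj <- mri_volume(voxels, spacing, origin)
  label_map <- as.integer(label_map) |> stats::setNames(names(label_map))
  if (any(label_map <= 0)) stop("label codes must be positive (0 = background)")
  if (anyDuplicated(label_map)) stop("label codes must be unique")
  obj$label_map <- label_map
  class(obj) <- c("label_volume", "mri_volume")
  obj
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n",
              class(x)[1], paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              paste(format(x$origin, trim = TRUE), collapse = ", ")))
  if (!is.null(x$label_map)) {
    cat("labels:", paste(sprintf("%s=%d", names(x$label_map), x$label_map),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

# Binary mask (logical 3D array) of one named structure, or of several.
structure_mask <- function(vol, names) {
  stopifnot(inherits(vol, "label_volume"))
  codes <- vol$label_map[names]
  if (anyNA(codes)) stop("unknown structure name(s): ",
                         paste(names[is.na(codes)], collapse = ", "))
  array(vol$voxels %in% codes, dim = dim(vol$voxels))
}

# World centroid (mm) of a logical mask.
mask_centroid <- function(mask, spacing, origin) {
  idx <- which(mask)
  if (length(idx) == 0) stop("MissingStructure: empty mask")
  ind <- arrayInd(idx, dim(mask))
  colMeans(index_to_world(ind, spacing, origin))
}

#' Collapse a phantom label volume to a generic segmentation
#'
#' Maps every disc code to one generic `disc` code and every vertebral body
#' code (including the sacral base) to one `vertebra` code, emulating the
#' class-agnostic output of a segmentation network before labeling.
#'
#' @param vol A [label_volume()] with per-structure codes.
#' @param disc_names,vertebra_names Structure names to collapse.
#' @return A [label_volume()] with codes `disc = 1`, `vertebra = 2`.
#' @export
as_generic_segmentation <- function(vol,
                                    disc_names = grep("/", names(vol$label_map),
                                                      value = TRUE),
                                    vertebra_names = grep("^(L[1-5]|S1|T12)$",
                                                          names(vol$label_map),
                                                          value = TRUE)) {
  stopifnot(inherits(vol, "label_volume"))
  out <- array(0L, dim(vol$voxels))
  out[vol$voxels %in% vol$label_map[disc_names]] <- 1L
  out[vol$voxels %in% vol$label_map[vertebra_names]] <- 2L
  label_volume(out, vol$spacing, vol$origin, c(disc = 1L, vertebra = 2L))
}
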