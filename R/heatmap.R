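# Gaussian keypoint heatmaps, candidate extraction, and the training /
# evaluation functions used around the disc localization network: focal
# loss, heatmap mean squared error and the Dice coefficient.
#
# A heatmap stores one 3D channel per target disc; values are "heat units"
# in [0, 256], with 256 at the keypoint. Channels are ordered head -> foot.

HEAT_PEAK <- 256

#' Build Gaussian heatmap targets for disc-centre keypoints
#'
#' Each channel holds `256 * exp(-||x - k||^2 / (2 sigma^2))` for its
#' keypoint `k`, evaluated at voxel centres in world mm, so the value at a
#' voxel-centred keypoint is exactly 256.
#'
#' @param keypoints n x 3 matrix of world points (mm), one row per disc;
#'   row names become channel labels.
#' @param shape Integer triple, grid dimensions.
#' @param spacing mm triple.
#' @param origin World origin (mm) of voxel `[1, 1, 1]`.
#' @param sigma Gaussian width in mm. The default, 6 mm, is on the scale of
#'   the 6 mm identification tolerance and keeps neighbouring disc peaks
#'   separable at typical 30-40 mm disc spacing.
#' @return Object of class `disc_heatmap`: list of `channels` (3D arrays),
#'   `channel_labels`, `spacing`, `origin`.
#' @export
make_gaussian_heatmap <- function(keypoints, shape, spacing, origin = c(0, 0, 0),
                                  sigma = 6) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.null(dim(keypoints))) keypoints <- matrix(keypoints, ncol = 3)
  labels <- rownames(keypoints) %||% (if (nrow(keypoints)) paste0("k", seq_len(nrow(keypoints))) else character(0))
  lo <- origin - 0.5 * spacing
  hi <- origin + (shape - 0.5) * spacing
  if (nrow(keypoints) &&
      (any(sweep(keypoints, 2, lo) < 0) || any(sweep(keypoints, 2, hi) > 0)))
    stop("OutOfBounds: keypoint outside the grid")

  ax <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
  channels <- lapply(seq_len(nrow(keypoints)), function(r) {
    k <- keypoints[r, ]
    dx2 <- (ax[[1]] - k[1])^2
    dy2 <- (ax[[2]] - k[2])^2
    dz2 <- (ax[[3]] - k[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    HEAT_PEAK * exp(-d2 / (2 * sigma^2))
  })
  structure(list(channels = channels,
                 channel_labels = labels,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "disc_heatmap")
}

#' @export
print.disc_heatmap <- function(x, ...) {
  cat(sprintf("<disc_heatmap> %d channel(s): %s\n", length(x$channels),
              paste(x$channel_labels, collapse = ", ")))
  invisible(x)
}

# 26-neighbourhood offsets (3D Moore neighbourhood).
NEIGHBOR_OFFSETS_26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Extract candidate disc centres from a heatmap
#'
#' Returns, per channel, the strict local maxima (26-connectivity) with heat
#' above `threshold`, sorted by heat descending. Ties on a plateau are
#' broken in favour of the lowest linear index, so extraction is
#' deterministic.
#'
#' @param heatmap A `disc_heatmap`.
#' @param threshold Heat units in (0, 256); default 128 (half peak).
#' @return Named list (one per channel) of data frames with columns
#'   `x, y, z` (world mm), `heat`, `channel`.
#' @export
extract_candidates <- function(heatmap, threshold = 128) {
  if (threshold <= 0 || threshold >= HEAT_PEAK)
    stop("threshold must be in (0, 256)")
  out <- lapply(seq_along(heatmap$channels), function(ci) {
    ch <- heatmap$channels[[ci]]
    dims <- dim(ch)
    cand <- which(ch > threshold)
    if (length(cand) == 0)
      return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        heat = numeric(0), channel = character(0),
                        stringsAsFactors = FALSE))
    ind <- arrayInd(cand, dims)
    keep <- rep(TRUE, length(cand))
    for (r in seq_len(nrow(NEIGHBOR_OFFSETS_26))) {
      off <- NEIGHBOR_OFFSETS_26[r, ]
      nb <- sweep(ind, 2, off, FUN = "+")
      inside <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      lin <- nb[inside, 1] + (nb[inside, 2] - 1) * dims[1] +
        (nb[inside, 3] - 1) * dims[1] * dims[2]
      v <- ch[cand[inside]]
      nv <- ch[lin]
      # strict max, plateau tie-break by lower linear index
      bad <- nv > v | (nv == v & lin < cand[inside])
      keep[inside][bad] <- FALSE
    }
    ind <- ind[keep, , drop = FALSE]
    if (nrow(ind) == 0)
      return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        heat = numeric(0), channel = character(0),
                        stringsAsFactors = FALSE))
    w <- index_to_world(ind, heatmap$spacing, heatmap$origin)
    if (is.null(dim(w))) w <- matrix(w, ncol = 3)
    df <- data.frame(x = w[, 1], y = w[, 2], z = w[, 3],
                     heat = ch[ind], stringsAsFactors = FALSE)
    df$channel <- heatmap$channel_labels[ci]
    df[order(-df$heat), , drop = FALSE]
  })
  stats::setNames(out, heatmap$channel_labels)
}

#' Focal loss
#'
#' `FL(pt) = -(1 - pt)^gamma * log(pt)` with `pt = p` where the voxel label
#' is the positive class and `1 - p` otherwise. With `gamma = 0` this is
#' exactly the cross-entropy loss. Probabilities are clamped to
#' `[eps, 1 - eps]` before the log; the clamp is reported once per session
#' via a warning when it actually fires.
#'
#' @param prob Predicted probability of the positive class (vector/array).
#' @param label Voxel labels in `{0, 1}` (same length).
#' @param gamma Focusing parameter, >= 0. Default 2.
#' @param reduction `"mean"` or `"sum"`.
#' @param eps Clamping epsilon for numerical safety.
#' @return Scalar loss.
#' @export
focal_loss <- function(prob, label, gamma = 2, reduction = c("mean", "sum"),
                       eps = 1e-7) {
  reduction <- match.arg(reduction)
  if (gamma < 0) stop("gamma must be >= 0")
  if (length(prob) != length(label)) stop("ShapeMismatch: prob vs label")
  pt <- ifelse(label == 1, prob, 1 - prob)
  # the loss is finite at pt = 1 (exactly 0); only pt <= 0 must be clamped
  if (any(pt <= 0 | pt > 1)) {
    if (!isTRUE(getOption("lumbarplan.clamp_warned"))) {
      warning("focal_loss: probabilities clamped into (0, 1]")
      options(lumbarplan.clamp_warned = TRUE)
    }
    pt <- pmin(pmax(pt, eps), 1)
  }
  fl <- -(1 - pt)^gamma * log(pt)
  if (reduction == "mean") mean(fl) else sum(fl)
}

#' Heatmap mean squared error
#'
#' `(1/N) * sum((Y_i - f(x_i))^2)` over all voxels of all channels, in raw
#' heat units (peak 256; values are not normalised before the MSE).
#'
#' @param predicted,target `disc_heatmap` objects with identical shape and
#'   channel order.
#' @return Scalar MSE.
#' @export
heatmap_mse <- function(predicted, target) {
  if (length(predicted$channels) != length(target$channels))
    stop("ShapeMismatch: different channel counts")
  total <- 0
  nvox <- 0
  for (i in seq_along(predicted$channels)) {
    p <- predicted$channels[[i]]
    t <- target$channels[[i]]
    if (!identical(dim(p), dim(t))) stop("ShapeMismatch: channel ", i)
    total <- total + sum((p - t)^2)
    nvox <- nvox + length(p)
  }
  total / nvox
}

#' Dice coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` for two binary masks of the same shape.
#' Two empty masks are defined to agree perfectly (Dice 1).
#'
#' @param a,b Logical (or 0/1) arrays of identical shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("ShapeMismatch: masks differ in shape")
  a <- as.logical(a)
  b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
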