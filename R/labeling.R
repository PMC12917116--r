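# Anatomical disc labeling: anchor the caudal reference disc (L5/S1), match
# candidate centres to an empirical inter-disc distance template by
# minimising the matching error
#
#   sum over unordered pairs i < j of | D(c_i, c_j) - T(i, j) |,
#
# fuse labels with a disc segmentation, and score the identification rate.

#' Build an inter-disc distance template
#'
#' @param labels Disc names ordered head -> foot.
#' @param adjacent_spacing Distance (mm) between adjacent disc centres, a
#'   scalar or length `d - 1` vector. Longer-range entries are composed as
#'   chord lengths of the lordosis arc.
#' @param lordosis_angle Total arc (degrees) used for the chord composition.
#' @param distances Optionally a full symmetric d x d matrix overriding the
#'   parametric construction.
#' @return Object of class `disc_template` with `labels` and `distances`.
#' @export
disc_template <- function(labels = disc_names_for(5),
                          adjacent_spacing = 37,
                          lordosis_angle = 40,
                          distances = NULL) {
  d <- length(labels)
  if (is.null(distances)) {
    seg <- if (length(adjacent_spacing) == 1) rep(adjacent_spacing, d - 1)
    else adjacent_spacing
    if (length(seg) != d - 1) stop("adjacent_spacing must be scalar or length d - 1")
    # chain the per-level segments with the arc's tangent increments, then
    # take chord lengths between disc positions
    step <- lordosis_angle / d * pi / 180
    pos <- matrix(0, d, 2)
    ang <- 0
    for (k in 2:d) {
      ang <- ang + step
      pos[k, ] <- pos[k - 1, ] + seg[k - 1] * c(sin(ang), cos(ang))
    }
    distances <- as.matrix(stats::dist(pos))
    dimnames(distances) <- list(labels, labels)
  }
  if (!isTRUE(all.equal(distances, t(distances))))
    stop("template distances must be symmetric")
  if (any(diag(distances) != 0)) stop("template diagonal must be 0")
  if (any(distances[upper.tri(distances)] <= 0))
    stop("off-diagonal template distances must be positive")
  structure(list(labels = labels, distances = distances),
            class = "disc_template")
}

#' @export
print.disc_template <- function(x, ...) {
  cat(sprintf("<disc_template> %d discs (%s..%s), adjacent spacing %.1f mm\n",
              length(x$labels), x$labels[1], x$labels[length(x$labels)],
              mean(x$distances[cbind(seq_len(length(x$labels) - 1),
                                     2:length(x$labels))])))
  invisible(x)
}

# Flatten per-channel candidate lists into one data frame.
pool_candidates <- function(candidates) {
  if (is.data.frame(candidates)) return(candidates)
  do.call(rbind, candidates)
}

#' Find the caudal reference disc (L5/S1)
#'
#' The reference is the most caudal (minimum Z) candidate whose heat meets
#' the threshold; ties on Z within half a voxel go to the higher heat.
#'
#' @param candidates Per-channel candidate lists from [extract_candidates()],
#'   or a single data frame.
#' @param threshold Minimum heat.
#' @param z_tol Tie tolerance on Z in mm (half a voxel of the source grid).
#' @return One-row data frame (the reference candidate).
#' @export
find_reference_disc <- function(candidates, threshold = 128, z_tol = 0.75) {
  pool <- pool_candidates(candidates)
  pool <- pool[pool$heat >= threshold, , drop = FALSE]
  if (is.null(pool) || nrow(pool) == 0)
    stop("NoReferenceFound: no candidate at or above the heat threshold")
  zmin <- min(pool$z)
  tied <- pool[pool$z <= zmin + z_tol, , drop = FALSE]
  tied[which.max(tied$heat), , drop = FALSE]
}

#' Match candidate centres to the disc template
#'
#' Searches the injective, head-to-foot Z-ordered assignments of pooled
#' candidates to template labels and returns the one minimising the matching
#' error (sum over unordered label pairs of the absolute difference between
#' the candidate distance and the template distance). Candidates are pooled
#' across channels, so a network that swapped two channel outputs is still
#' labeled by spatial order. As many labels as candidates permit are
#' assigned (`min(d, n_candidates)`); the remainder are reported MISSING and
#' excluded from the error sum.
#'
#' @param candidates Per-channel candidate lists or one data frame.
#' @param template A [disc_template()].
#' @return Object of class `label_assignment`: `mapping` (data frame with
#'   one row per template label; NA coordinates = MISSING), `matching_error`
#'   (mm), `reference` (the candidate assigned to the most caudal label).
#' @export
match_template <- function(candidates, template) {
  pool <- pool_candidates(candidates)
  if (is.null(pool) || nrow(pool) == 0) stop("NoCandidates: all channels empty")
  d <- length(template$labels)
  # head -> foot ordering = Z descending
  pool <- pool[order(-pool$z), , drop = FALSE]
  rownames(pool) <- NULL
  m <- nrow(pool)
  k <- min(d, m)
  pts <- as.matrix(pool[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(pts))
  tmat <- template$distances

  best <- list(err = Inf, rows = NULL, labels = NULL)
  # depth-first search over order-preserving injections of k labels into the
  # Z-sorted candidates, with a running lower bound for pruning
  search <- function(lab_pos, cand_pos, chosen_labs, chosen_rows, err) {
    if (err >= best$err) return()
    if (length(chosen_labs) == k) {
      best <<- list(err = err, rows = chosen_rows, labels = chosen_labs)
      return()
    }
    labs_left <- k - length(chosen_labs)
    # labels and candidates both advance monotonically
    if ((d - lab_pos + 1) < labs_left || (m - cand_pos + 1) < labs_left) return()
    for (l in lab_pos:(d - labs_left + 1)) {
      for (c in cand_pos:(m - labs_left + 1)) {
        add <- 0
        if (length(chosen_labs)) {
          add <- sum(abs(dmat[chosen_rows, c] - tmat[chosen_labs, l]))
        }
        search(l + 1, c + 1, c(chosen_labs, l), c(chosen_rows, c), err + add)
      }
    }
  }
  search(1, 1, integer(0), integer(0), 0)

  rows <- rep(NA_integer_, d)
  rows[best$labels] <- best$rows
  mapping <- data.frame(label = template$labels,
                        x = pool$x[rows], y = pool$y[rows], z = pool$z[rows],
                        heat = pool$heat[rows],
                        missing = is.na(rows),
                        stringsAsFactors = FALSE)
  ref_row <- rows[max(which(!is.na(rows)))]
  structure(list(mapping = mapping,
                 matching_error = best$err,
                 reference = pool[ref_row, , drop = FALSE],
                 template = template),
            class = "label_assignment")
}

#' @export
print.label_assignment <- function(x, ...) {
  cat(sprintf("<label_assignment> %d/%d labels assigned, matching error %.2f mm\n",
              sum(!x$mapping$missing), nrow(x$mapping), x$matching_error))
  invisible(x)
}

#' Fuse disc segmentation with label assignment
#'
#' Each connected component of the generic disc segmentation receives the
#' label of the assigned candidate nearest its centroid, if that candidate
#' lies within `gate` mm; farther components stay unlabeled. When two
#' components claim the same label, the nearer one keeps it and the other is
#' demoted to unlabeled (a conflict message is emitted). Vertebra labels are
#' inferred from the flanking discs.
#'
#' @param disc_segmentation A [label_volume()] whose `disc` code (or any
#'   single-code map entry named `"disc"`) marks disc voxels.
#' @param assignment A `label_assignment`.
#' @param gate Gating distance in mm (default 15, about half a vertebral
#'   height).
#' @return A [label_volume()] with one code per assigned disc label plus a
#'   `disc_unlabeled` code, and inferred vertebra codes.
#' @export
fuse_labels <- function(disc_segmentation, assignment, gate = 15) {
  stopifnot(inherits(disc_segmentation, "label_volume"))
  mask <- structure_mask(disc_segmentation, "disc")
  comp <- connected_components_26(mask)
  ncomp <- comp$n
  if (ncomp < 1) stop("disc segmentation has no connected component")
  dims <- dim(mask)

  centroids <- t(vapply(seq_len(ncomp), function(ci) {
    idx <- which(comp$labels == ci)
    colMeans(index_to_world(arrayInd(idx, dims), disc_segmentation$spacing,
                            disc_segmentation$origin))
  }, numeric(3)))

  mp <- assignment$mapping[!assignment$mapping$missing, , drop = FALSE]
  # nearest assigned candidate per component, gated
  claim <- rep(NA_integer_, ncomp)   # index into mp
  dist_to <- rep(Inf, ncomp)
  for (ci in seq_len(ncomp)) {
    dd <- sqrt(colSums((t(as.matrix(mp[, c("x", "y", "z")])) - centroids[ci, ])^2))
    bi <- which.min(dd)
    if (dd[bi] <= gate) {
      claim[ci] <- bi
      dist_to[ci] <- dd[bi]
    }
  }
  # resolve label conflicts by proximity
  for (bi in unique(stats::na.omit(claim))) {
    owners <- which(claim == bi)
    if (length(owners) > 1) {
      keep <- owners[which.min(dist_to[owners])]
      lose <- setdiff(owners, keep)
      claim[lose] <- NA
      message(sprintf("fuse_labels: %d component(s) demoted in conflict over %s",
                      length(lose), mp$label[bi]))
    }
  }

  labs <- mp$label[claim]
  lm <- stats::setNames(10L + seq_along(assignment$mapping$label),
                        assignment$mapping$label)
  lm <- c(lm, disc_unlabeled = 99L)
  out <- array(0L, dims)
  for (ci in seq_len(ncomp)) {
    code <- if (is.na(claim[ci])) lm[["disc_unlabeled"]] else lm[[labs[ci]]]
    out[comp$labels == ci] <- code
  }

  # vertebra labels inferred from the flanking disc labels
  if ("vertebra" %in% names(disc_segmentation$label_map)) {
    vmask <- structure_mask(disc_segmentation, "vertebra")
    vcomp <- connected_components_26(vmask)
    disc_z <- mp$z
    vert_codes <- integer(0)
    for (ci in seq_len(vcomp$n)) {
      idx <- which(vcomp$labels == ci)
      cz <- mean(index_to_world(arrayInd(idx, dims), disc_segmentation$spacing,
                                disc_segmentation$origin)[, 3])
      below <- mp$label[mp$z < cz]
      vname <- if (length(below)) vertebra_above(below[which.max(mp$z[mp$z < cz])])
      else NA_character_
      if (!is.na(vname) && nzchar(vname)) {
        if (!vname %in% names(lm)) {
          lm <- c(lm, stats::setNames(max(lm) + 1L, vname))
        }
        out[idx] <- lm[[vname]]
      }
    }
  }

  label_volume(out, disc_segmentation$spacing, disc_segmentation$origin, lm)
}

# The vertebra sitting on top of a disc: "L4/5" -> "L4"; "L5/S1" -> "L5".
vertebra_above <- function(disc_label) {
  strsplit(disc_label, "/", fixed = TRUE)[[1]][1]
}

# 26-connected components of a logical 3D mask (breadth-first flood fill on
# the foreground voxels only).
connected_components_26 <- function(mask) {
  dims <- dim(mask)
  fg <- which(mask)
  labels <- array(0L, dims)
  if (length(fg) == 0) return(list(labels = labels, n = 0L))
  in_fg <- array(FALSE, dims)
  in_fg[fg] <- TRUE
  nstr <- dims[1]
  npl <- dims[1] * dims[2]
  offs <- NEIGHBOR_OFFSETS_26 %*% c(1, nstr, npl)
  comp <- 0L
  for (s in fg) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ind <- arrayInd(cur, dims)
      for (r in seq_len(nrow(NEIGHBOR_OFFSETS_26))) {
        nb <- sweep(ind, 2, NEIGHBOR_OFFSETS_26[r, ], FUN = "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * nstr + (nb[ok, 3] - 1L) * npl
        new <- lin[in_fg[lin] & labels[lin] == 0L]
        if (length(new)) {
          labels[new] <- comp
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  list(labels = labels, n = comp)
}

#' Identification rate
#'
#' A disc counts as correctly identified iff (a) the truth centroid closest
#' to its predicted centre carries the same label and (b) the localization
#' error is below `tolerance` in each of the three axes separately.
#'
#' @param predicted n x 3 matrix of predicted centres, row names = labels
#'   (rows of NA or absent labels count as not identified).
#' @param truth m x 3 matrix of true centres, row names = labels.
#' @param tolerance Per-axis tolerance in mm (default 6).
#' @return Identified fraction in [0, 1].
#' @export
identification_rate <- function(predicted, truth, tolerance = 6) {
  if (is.null(truth) || nrow(truth) == 0) stop("truth must be nonempty")
  total <- nrow(truth)
  hit <- 0L
  for (lbl in rownames(truth)) {
    if (!lbl %in% rownames(predicted)) next
    p <- predicted[lbl, ]
    if (anyNA(p)) next
    dd <- sqrt(colSums((t(truth) - p)^2))
    nearest <- rownames(truth)[which.min(dd)]
    if (nearest != lbl) next
    if (all(abs(p - truth[lbl, ]) < tolerance)) hit <- hit + 1L
  }
  hit / total
}
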