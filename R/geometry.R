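# Small 3D geometry helpers shared across modules.
#
# World frame convention (used everywhere in the package): RAS+, i.e.
# +X = patient right, +Y = anterior, +Z = superior (head). Voxel (i, j, k)
# (1-based R indices) has world coordinates origin + (index - 1) * spacing,
# so `origin` is the world position of the centre of voxel [1, 1, 1].

vec_norm <- function(v) sqrt(sum(v^2))

unit_vector <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("DegenerateDirection: cannot normalize a zero vector")
  v / n
}

#' Angle between two lines
#'
#' Treats the two direction vectors as undirected lines, so the result is
#' always in [0, 90] degrees and antiparallel vectors give 0.
#'
#' @param u,v Direction vectors (need not be unit length).
#' @return Angle in degrees in [0, 90].
#' @export
angle_between_lines <- function(u, v) {
  u <- unit_vector(u)
  v <- unit_vector(v)
  c_abs <- min(1, abs(sum(u * v)))
  acos(c_abs) * 180 / pi
}

# Angle between two (directed) unit vectors, in degrees [0, 180].
angle_between_vectors <- function(u, v) {
  u <- unit_vector(u)
  v <- unit_vector(v)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrices about the world axes; angles in degrees.
rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(t), -sin(t),
           0, sin(t), cos(t)), 3, 3, byrow = TRUE)
}

rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, sin(t),
           0, 1, 0,
           -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
}

rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), -sin(t), 0,
           sin(t), cos(t), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# Composite rotation used for rigid poses: R = Rz %*% Ry %*% Rx
# (intrinsic rotations applied about X first, then Y, then Z).
rotation_matrix <- function(rotation_deg) {
  rot_z(rotation_deg[3]) %*% rot_y(rotation_deg[2]) %*% rot_x(rotation_deg[1])
}

# Apply a rigid transform (rotation about `pivot`, then translation) to an
# n x 3 matrix of points or a length-3 vector.
apply_rigid <- function(points, rotation_deg, translation, pivot = c(0, 0, 0)) {
  R <- rotation_matrix(rotation_deg)
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else points
  out <- sweep(p, 2, pivot) %*% t(R)
  out <- sweep(out, 2, pivot + translation, FUN = "+")
  if (single) drop(out) else out
}

# World coordinates of every voxel centre in a grid, as an n x 3 matrix in
# array order (first index fastest).
voxel_world_coords <- function(dim3, spacing, origin) {
  idx <- arrayInd(seq_len(prod(dim3)), dim3)
  sweep(sweep(idx - 1, 2, spacing, FUN = "*"), 2, origin, FUN = "+")
}

world_to_index <- function(points, spacing, origin) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else points
  out <- sweep(sweep(p, 2, origin), 2, spacing, FUN = "/") + 1
  if (single) drop(out) else out
}

index_to_world <- function(index, spacing, origin) {
  single <- is.null(dim(index))
  p <- if (single) matrix(index, 1, 3) else index
  out <- sweep(sweep(p - 1, 2, spacing, FUN = "*"), 2, origin, FUN = "+")
  if (single) drop(out) else out
}
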