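#' @useDynLib kneepose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

# All coordinates are millimetres in a right-handed frame; rotations are
# proper (det +1). Points travel as n x 3 numeric matrices.

#' Coerce to an n x 3 point matrix
#'
#' Accepts a length-3 vector (one point), an n x 3 matrix, or a data.frame
#' with three numeric columns. All coordinates must be finite.
#'
#' @param x points in millimetres.
#' @return numeric matrix with 3 columns.
#' @export
as_points <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("a single point must have exactly 3 coordinates")
    x <- matrix(as.numeric(x), 1L, 3L)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("points must have 3 columns (x, y, z)")
  if (!all(is.finite(x))) stop("point coordinates must be finite")
  x
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) stop(sprintf("cannot normalise a zero-length %s", what))
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && det(R) > 0
}

#' Rigid transform (proper rotation + translation)
#'
#' Represents a mapping `p -> R p + t` between two millimetre frames. The
#' rotation must be orthonormal with determinant +1; reflections are
#' rejected so that anatomy is never mirrored by accident.
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 translation in mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be 3 finite numbers")
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation)))
    stop("rotation must be a finite 3 x 3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal (R'R != I within 1e-9)")
  if (det(rotation) < 0)
    stop("rotation matrix has negative determinant: reflections are not rigid transforms")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (mm)\n")
  cat(sprintf("  rotation angle: %.4f deg\n", rotation_angle_deg(x$rotation)))
  cat(sprintf("  translation:    [%.4f, %.4f, %.4f]\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity rigid transform
#' @return a `rigid_transform` that leaves points unchanged.
#' @export
identity_transform <- function() rigid_transform()

#' Axis-angle rotation transform
#'
#' @param axis rotation axis (need not be unit length).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @param translation optional translation, mm.
#' @return a `rigid_transform`.
#' @export
rotation_about <- function(axis, angle_deg, translation = c(0, 0, 0)) {
  a <- unitv(as.numeric(axis), "rotation axis")
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, translation)
}

rotation_angle_deg <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param points a point, n x 3 matrix, or data.frame (mm).
#' @return transformed points, n x 3 matrix (row names preserved).
#' @export
apply_transform <- function(transform, points) {
  if (!inherits(transform, "rigid_transform"))
    stop("transform must be a rigid_transform")
  p <- as_points(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3L, byrow = TRUE)
  rownames(out) <- rownames(p)
  out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform that first applies `b`, then
#' `a`: `apply(compose(a, b), p) == apply(a, apply(b, p))`.
#'
#' @param t_outer,t_inner `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(t_outer, t_inner) {
  if (!inherits(t_outer, "rigid_transform") || !inherits(t_inner, "rigid_transform"))
    stop("both arguments must be rigid_transform objects")
  rigid_transform(t_outer$rotation %*% t_inner$rotation,
                  as.numeric(t_outer$rotation %*% t_inner$translation) +
                    t_outer$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  if (!inherits(transform, "rigid_transform"))
    stop("transform must be a rigid_transform")
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Oriented plane
#'
#' A plane through `point` with unit `normal`; the normal orientation is
#' meaningful (resection-plane normals point toward the removed bone).
#'
#' @param point a point on the plane, mm.
#' @param normal plane normal (normalised internally).
#' @return an object of class `plane`.
#' @export
plane <- function(point, normal) {
  point <- as.numeric(point)
  if (length(point) != 3L || !all(is.finite(point)))
    stop("plane point must be 3 finite numbers")
  normal <- unitv(as.numeric(normal), "plane normal")
  structure(list(point = point, normal = normal), class = "plane")
}

#' Signed distance from points to a plane
#'
#' Positive on the side the normal points to.
#'
#' @param pl a `plane`.
#' @param points a point or n x 3 matrix, mm.
#' @return numeric vector of signed distances in mm.
#' @export
signed_plane_distance <- function(pl, points) {
  if (!inherits(pl, "plane")) stop("pl must be a plane")
  p <- as_points(points)
  as.numeric((p - matrix(pl$point, nrow(p), 3L, byrow = TRUE)) %*% pl$normal)
}

#' Transform a plane by a rigid transform
#' @param transform a `rigid_transform`.
#' @param pl a `plane`.
#' @return the transformed `plane`.
#' @export
transform_plane <- function(transform, pl) {
  plane(as.numeric(apply_transform(transform, pl$point)),
        as.numeric(transform$rotation %*% pl$normal))
}

#' Midpoint of two points
#' @param a,b points (length-3), mm.
#' @return length-3 numeric vector, the component-wise mean.
#' @export
midpoint <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L || !all(is.finite(c(a, b))))
    stop("midpoint needs two finite 3D points")
  (a + b) / 2
}
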