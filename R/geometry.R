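# Exact 3D geometry kernel: planes, distances, rigid superimposition.
# Coordinates are millimetres in a right-handed subject frame:
# X = lateral (positive toward the subject's right), Y = vertical
# (positive superior), Z = transverse (positive anterior).

#' Construct an oriented plane
#'
#' A plane is stored as a unit normal `n` and scalar offset `d` such that the
#' plane is the point set `{p : n . p = d}`. The signed distance of a point to
#' the plane is `n . p - d`.
#'
#' @param normal Numeric length-3 normal vector (need not be unit length).
#' @param offset Scalar offset on the same scale as `normal`; it is rescaled
#'   together with the normal during normalisation.
#' @return An object of class `ceph_plane` with elements `normal` (unit
#'   3-vector) and `offset` (mm).
#' @export
plane3 <- function(normal, offset) {
  n <- as.numeric(normal)
  if (length(n) != 3L || !all(is.finite(n))) {
    stop_usage("plane normal must be a finite length-3 numeric vector")
  }
  len <- sqrt(sum(n^2))
  if (len < 1e-12) stop_degenerate("plane normal has (near-)zero length")
  offset <- as.numeric(offset) / len
  if (!is.finite(offset)) stop_usage("plane offset must be finite")
  structure(list(normal = n / len, offset = offset), class = "ceph_plane")
}

#' @export
print.ceph_plane <- function(x, ...) {
  cat(sprintf("<plane> normal = (%.6f, %.6f, %.6f), offset = %.6f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

is_plane <- function(x) inherits(x, "ceph_plane")

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Plane through three points
#'
#' Builds the unique plane containing three non-collinear points. The raw
#' normal direction is `cross(b - a, c - a)`; an orientation rule can then pin
#' the sign so that signed distances are reproducible: `"superior"` flips the
#' normal to have a positive Y component (used for horizontal reference
#' planes), `"right"` to have a positive X component (used for midsagittal
#' planes), `"none"` keeps the winding-determined sign.
#'
#' @param a,b,c Numeric length-3 points (mm).
#' @param orient One of `"none"`, `"superior"`, `"right"`.
#' @param labels Optional character vector of three landmark names, used in
#'   error messages when the points are degenerate.
#' @param eps_area Collinearity threshold: triangle area (mm^2) below which
#'   the construction is rejected.
#' @return A [plane3()] object.
#' @export
plane_from_points <- function(a, b, c, orient = c("none", "superior", "right"),
                              labels = NULL, eps_area = 1e-6) {
  orient <- match.arg(orient)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  n <- cross3(b - a, c - a)
  area <- sqrt(sum(n^2)) / 2
  if (!is.finite(area) || area <= eps_area) {
    who <- if (is.null(labels)) "the three defining points" else
      paste(labels, collapse = ", ")
    stop_degenerate(sprintf(
      "%s are coincident or collinear (triangle area %.3g mm^2)", who, area))
  }
  n <- n / sqrt(sum(n^2))
  flip_axis <- switch(orient, none = 0L, superior = 2L, right = 1L)
  if (flip_axis > 0L && n[flip_axis] < 0) n <- -n
  plane3(n, sum(n * a))
}

#' Point-to-plane distance
#'
#' @param p A length-3 point or an n x 3 matrix of points (mm).
#' @param plane A [plane3()] object.
#' @param signed If `TRUE` return the signed distance `n . p - d` (positive on
#'   the side the normal points to); otherwise its absolute value.
#' @return Numeric vector of distances in mm.
#' @export
point_plane_distance <- function(p, plane, signed = FALSE) {
  if (!is_plane(plane)) stop_usage("`plane` must be a ceph_plane")
  p <- if (is.matrix(p)) p else matrix(as.numeric(p), ncol = 3L)
  d <- drop(p %*% plane$normal) - plane$offset
  if (signed) d else abs(d)
}

#' Midpoint of two points
#'
#' Componentwise mean, used for the averaged orbitale (OrA) and porion (PoA)
#' landmarks.
#'
#' @param a,b Length-3 points.
#' @return Length-3 point.
#' @export
midpoint3 <- function(a, b) (as.numeric(a) + as.numeric(b)) / 2

#' Dihedral angle between two planes
#'
#' @param a,b [plane3()] objects.
#' @return Angle between the plane normals in radians, folded to `[0, pi/2]`
#'   so the result does not depend on normal orientation.
#' @export
plane_angle <- function(a, b) {
  d <- abs(sum(a$normal * b$normal))
  acos(min(1, max(-1, d)))
}

## ---- rigid transforms -----------------------------------------------------

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation Length-3 vector (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- matrix(as.numeric(rotation), 3L, 3L)
  t <- as.numeric(translation)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    stop_usage("rotation must be proper orthogonal (R'R = I, det R = +1)")
  }
  structure(list(rotation = R, translation = t), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param p Length-3 point or n x 3 matrix.
#' @return Transformed points, same shape as the input.
#' @export
apply_rigid <- function(transform, p) {
  was_vec <- !is.matrix(p)
  m <- if (was_vec) matrix(as.numeric(p), ncol = 3L) else p
  out <- m %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, "+")
  if (was_vec) drop(out) else out
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation))
}

#' Transform a plane by a rigid motion
#'
#' Transforms the plane so that `apply_rigid` of any point on the original
#' plane lies on the transformed plane.
#'
#' @param transform A [rigid_transform()].
#' @param plane A [plane3()].
#' @return A [plane3()].
#' @export
transform_plane <- function(transform, plane) {
  n <- drop(transform$rotation %*% plane$normal)
  plane3(n, plane$offset + sum(n * transform$translation))
}

#' Rotation angle of a rigid transform
#' @param transform A [rigid_transform()].
#' @return Rotation angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(transform) {
  tr <- sum(diag(transform$rotation))
  acos(min(1, max(-1, (tr - 1) / 2)))
}

#' Least-squares rigid superimposition (Kabsch algorithm)
#'
#' Finds the rotation and translation minimising the root-mean-square
#' deviation between corresponding source and target points, via the SVD of
#' the cross-covariance matrix with reflection correction (the singular
#' direction with the smallest singular value is negated when the determinant
#' would otherwise be -1), so the result is always a proper rotation.
#'
#' @param source,target n x 3 matrices of corresponding points (mm), n >= 3,
#'   not collinear.
#' @return A list with `transform` (a [rigid_transform()] mapping source onto
#'   target) and `rmsd` (mm).
#' @export
kabsch_superimpose <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!identical(dim(source), dim(target)) || ncol(source) != 3L) {
    stop_usage("source and target must be n x 3 matrices of equal size")
  }
  n <- nrow(source)
  if (n < 3L) {
    stop_degenerate(sprintf("rigid superimposition needs >= 3 points, got %d", n))
  }
  cs <- colMeans(source); ct <- colMeans(target)
  X <- sweep(source, 2L, cs); Y <- sweep(target, 2L, ct)
  sv_x <- svd(X, nu = 0, nv = 0)$d
  if (sv_x[2] <= 1e-8 * max(sv_x[1], 1e-300)) {
    stop_degenerate("source points are (near-)collinear; rotation is not determined")
  }
  H <- crossprod(X, Y)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(R, ct - drop(R %*% cs))
  fitted <- apply_rigid(tr, source)
  list(transform = tr,
       rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}
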