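# Rigid-transform algebra: unit quaternions, Euler angles, 4x4 matrices, and
# the closed-form SVD paired-point solve used by coarse registration, the ICP
# inner loop, and training-label construction.
#
# Conventions (used everywhere in the package):
#   * points are column vectors, p' = R p + t; homogeneous matrices act on the
#     left; point matrices in R are N x 3 so application is  P %*% t(R) + t.
#   * quaternions are [w, x, y, z], unit norm, canonicalized to w >= 0.
#   * Euler angles are intrinsic z-y'-x'' (yaw, pitch, roll), in degrees.

#' Construct a rigid transform
#'
#' A rigid transform is the universal currency of every registration stage:
#' it stores a unit quaternion `q = [w, x, y, z]` and a translation vector in
#' mm. The quaternion is normalized and canonicalized (`w >= 0`) on
#' construction.
#'
#' @param quaternion Numeric length-4 `[w, x, y, z]`. Need not be unit norm;
#'   it is normalized (zero norm is an error).
#' @param translation Numeric length-3 translation in mm.
#' @return An object of class `rigid_transform` with elements `q` and `t`.
#' @examples
#' rigid_transform(c(1, 0, 0, 0), c(5, 0, 0))
#' @export
rigid_transform <- function(quaternion = c(1, 0, 0, 0), translation = c(0, 0, 0)) {
  q <- as.numeric(quaternion)
  t <- as.numeric(translation)
  if (length(q) != 4L) stop("quaternion must have 4 components [w, x, y, z]")
  if (length(t) != 3L) stop("translation must have 3 components (mm)")
  if (!all(is.finite(q)) || !all(is.finite(t))) {
    stop("rigid_transform components must be finite")
  }
  q <- quat_normalize(q)
  structure(list(q = q, t = t), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform(c(1, 0, 0, 0), c(0, 0, 0))

#' @export
print.rigid_transform <- function(x, ...) {
  eul <- quat_to_euler(x$q)
  cat("<rigid_transform>\n")
  cat(sprintf("  q  (w,x,y,z): % .6f % .6f % .6f % .6f\n",
              x$q[1], x$q[2], x$q[3], x$q[4]))
  cat(sprintf("  euler (deg) : yaw % .3f  pitch % .3f  roll % .3f\n",
              eul[1], eul[2], eul[3]))
  cat(sprintf("  t  (mm)     : % .4f % .4f % .4f\n", x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Normalize a quaternion
#'
#' Scales to unit norm and canonicalizes the sign so that `w >= 0` (the two
#' antipodal quaternions encode the same rotation; a fixed sign makes
#' comparisons deterministic).
#'
#' @param q Numeric length-4 `[w, x, y, z]`.
#' @return Unit quaternion with `w >= 0`.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (!is.finite(n) || n < 1e-12) stop("cannot normalize a zero-norm quaternion")
  q <- q / n
  if (q[1] < 0) q <- -q
  q
}

# Hamilton product a (x) b, both [w,x,y,z].
quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Convert a unit quaternion to a 3x3 rotation matrix
#'
#' @param q Unit quaternion `[w, x, y, z]` (normalized internally).
#' @return 3x3 rotation matrix with determinant +1.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Shepperd's method (numerically stable branch selection). The result is
#' canonicalized to `w >= 0`.
#'
#' @param R 3x3 rotation matrix.
#' @return Unit quaternion `[w, x, y, z]`.
#' @export
matrix_to_quat <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  quat_normalize(q)
}

#' Quaternion / Euler-angle conversions
#'
#' Euler convention: intrinsic z-y'-x'' (yaw about z, then pitch about the new
#' y, then roll about the new x), angles in degrees, i.e.
#' `R = Rz(yaw) Ry(pitch) Rx(roll)`. Away from gimbal lock
#' (`|pitch| = 90` deg) the round trip quaternion -> Euler -> quaternion
#' reproduces the rotation.
#'
#' @param q Unit quaternion `[w, x, y, z]`.
#' @param euler Numeric length-3 `c(yaw, pitch, roll)` in degrees.
#' @return `quat_to_euler`: length-3 `c(yaw, pitch, roll)` in degrees;
#'   `euler_to_quat`: unit quaternion.
#' @export
quat_to_euler <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  yaw <- atan2(2 * (x * y + w * z), 1 - 2 * (y^2 + z^2))
  sp <- 2 * (w * y - x * z)
  sp <- min(1, max(-1, sp))
  pitch <- asin(sp)
  roll <- atan2(2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  c(yaw = yaw, pitch = pitch, roll = roll) * 180 / pi
}

#' @rdname quat_to_euler
#' @export
euler_to_quat <- function(euler) {
  e <- as.numeric(euler) * pi / 180
  qz <- c(cos(e[1] / 2), 0, 0, sin(e[1] / 2))
  qy <- c(cos(e[2] / 2), 0, sin(e[2] / 2), 0)
  qx <- c(cos(e[3] / 2), sin(e[3] / 2), 0, 0)
  quat_normalize(quat_multiply(quat_multiply(qz, qy), qx))
}

#' Compose two rigid transforms
#'
#' `rt_compose(outer, inner)` is the transform "apply `inner` first, then
#' `outer`": `rt_apply(rt_compose(A, B), p) == rt_apply(A, rt_apply(B, p))`.
#' Chained stage transforms compose right to left, e.g. a cumulative
#' refinement `T = T(n) x ... x T(1)`.
#'
#' @param outer,inner `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(outer, inner) {
  stopifnot(is_rigid_transform(outer), is_rigid_transform(inner))
  q <- quat_multiply(outer$q, inner$q)
  Ro <- quat_to_matrix(outer$q)
  t <- as.numeric(Ro %*% inner$t) + outer$t
  rigid_transform(q, t)
}

#' Invert a rigid transform
#'
#' @param x A `rigid_transform`.
#' @return The inverse transform: `rt_compose(x, rt_invert(x))` is the
#'   identity.
#' @export
rt_invert <- function(x) {
  stopifnot(is_rigid_transform(x))
  qi <- quat_conjugate(x$q)
  Ri <- quat_to_matrix(qi)
  rigid_transform(qi, -as.numeric(Ri %*% x$t))
}

#' Apply a rigid transform to points
#'
#' @param x A `rigid_transform`.
#' @param points An N x 3 matrix of coordinates (mm), a length-3 vector, or a
#'   [point_cloud()] (normals, if present, are rotated).
#' @return Same shape/class as `points`, transformed by `p' = R p + t`.
#' @export
rt_apply <- function(x, points) {
  stopifnot(is_rigid_transform(x))
  if (inherits(points, "point_cloud")) {
    out <- points
    out$points <- rt_apply(x, points$points)
    if (!is.null(points$normals)) {
      out$normals <- points$normals %*% t(quat_to_matrix(x$q))
    }
    return(out)
  }
  vec <- is.null(dim(points))
  P <- if (vec) matrix(points, ncol = 3) else as.matrix(points)
  stopifnot(ncol(P) == 3)
  R <- quat_to_matrix(x$q)
  out <- P %*% t(R)
  out <- sweep(out, 2, x$t, "+")
  if (vec) as.numeric(out) else out
}

#' @export
as.matrix.rigid_transform <- function(x, ...) {
  M <- diag(4)
  M[1:3, 1:3] <- quat_to_matrix(x$q)
  M[1:3, 4] <- x$t
  M
}

#' Build a rigid transform from a 4x4 (or 3x4) homogeneous matrix
#'
#' @param M Homogeneous matrix whose upper-left 3x3 block is a rotation.
#' @return A `rigid_transform`.
#' @export
rt_from_matrix <- function(M) {
  M <- as.matrix(M)
  stopifnot(nrow(M) >= 3, ncol(M) == 4)
  R <- M[1:3, 1:3]
  if (abs(det(R) - 1) > 1e-6) stop("matrix rotation block must have det +1")
  rigid_transform(matrix_to_quat(R), M[1:3, 4])
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' The JSON object carries the quaternion, the translation in mm, and the
#' 4x4 homogeneous matrix (row-major) for interoperability.
#'
#' @param x A `rigid_transform`.
#' @param json A JSON string produced by `rt_to_json()`.
#' @return `rt_to_json`: a JSON string; `rt_from_json`: a `rigid_transform`.
#' @export
rt_to_json <- function(x) {
  stopifnot(is_rigid_transform(x))
  M <- as.matrix(x)
  jsonlite::toJSON(
    list(
      quaternion = x$q,
      translation_mm = x$t,
      matrix = lapply(seq_len(4), function(i) M[i, ])
    ),
    digits = NA, auto_unbox = FALSE
  )
}

#' @rdname rt_to_json
#' @export
rt_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  rigid_transform(obj$quaternion, obj$translation_mm)
}

#' SVD-based paired-point rigid registration (Arun/Kabsch solve)
#'
#' Closed-form least-squares rigid alignment of two point sets with known
#' index-wise correspondence: centroids are subtracted, the cross-covariance
#' `H = sum_i (x_i - xbar)(y_i - ybar)^T` is decomposed `H = U S V^T`, and the
#' optimal rotation is `R = V D U^T` with `D = diag(1, 1, det(V U^T))` — the
#' sign flip guards against reflections for near-planar configurations. The
#' translation aligns the rotated source centroid with the target centroid.
#'
#' @param source,target N x 3 matrices (or objects with a `points` matrix, or
#'   landmark tibbles with x/y/z columns) of corresponding points, N >= 3,
#'   source not collinear.
#' @return A `rigid_transform` minimizing the mean squared index-wise
#'   distance `mean(||R x_i + t - y_i||^2)`.
#' @export
svd_paired_point_register <- function(source, target) {
  X <- as_point_matrix(source)
  Y <- as_point_matrix(target)
  if (nrow(X) != nrow(Y)) {
    stop("correspondence error: source and target must have the same number of points")
  }
  if (nrow(X) < 3) {
    stop("rank-deficiency error: paired-point registration needs at least 3 points")
  }
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  # collinear source points leave the rotation about the line unconstrained
  sv_x <- svd(Xc, nu = 0, nv = 0)$d
  if (sv_x[2] < 1e-9 * max(sv_x[1], 1)) {
    stop("rank-deficiency error: source points are collinear (or coincident)")
  }
  H <- t(Xc) %*% Yc
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  t <- cy - as.numeric(R %*% cx)
  rigid_transform(matrix_to_quat(R), t)
}

# Coerce the shapes users hand to registration functions into an N x 3 matrix.
as_point_matrix <- function(x) {
  if (inherits(x, "point_cloud")) return(x$points)
  if (is.data.frame(x)) {
    if (!all(c("x", "y", "z") %in% names(x))) {
      stop("data-frame input needs x, y, z columns")
    }
    return(cbind(x = x$x, y = x$y, z = x$z))
  }
  m <- as.matrix(x)
  if (is.null(dim(m)) || ncol(m) != 3) stop("points must be an N x 3 matrix")
  storage.mode(m) <- "double"
  m
}

#' Mean squared / root-mean-square paired residuals
#'
#' Utility used throughout tests and evaluation: index-wise residuals between
#' two equally sized point sets.
#'
#' @param a,b N x 3 matrices (or coercible via landmark/cloud accessors).
#' @return `paired_mse`: mean squared distance (mm^2); `paired_rms`: its root
#'   (mm).
#' @export
paired_mse <- function(a, b) {
  A <- as_point_matrix(a); B <- as_point_matrix(b)
  stopifnot(nrow(A) == nrow(B))
  mean(rowSums((A - B)^2))
}

#' @rdname paired_mse
#' @export
paired_rms <- function(a, b) sqrt(paired_mse(a, b))

#' Angular difference between two rotations
#'
#' @param qa,qb Unit quaternions.
#' @return Geodesic angle in degrees between the two rotations.
#' @export
quat_angle_deg <- function(qa, qb = c(1, 0, 0, 0)) {
  qa <- quat_normalize(qa); qb <- quat_normalize(qb)
  d <- abs(sum(qa * qb))
  2 * acos(min(1, d)) * 180 / pi
}

#' Random rotation / rigid transform (uniform on SO(3))
#'
#' Draws from the current RNG stream; seed management is left to the caller.
#'
#' @param max_translation_mm Translations are drawn uniformly in
#'   `[-max_translation_mm, max_translation_mm]` per axis.
#' @return `random_quaternion`: unit quaternion; `random_rigid_transform`: a
#'   `rigid_transform`.
#' @export
random_quaternion <- function() {
  # Shoemake subgroup algorithm: uniform on SO(3)
  u <- stats::runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  quat_normalize(c(q[4], q[1], q[2], q[3]))
}

#' @rdname random_quaternion
#' @export
random_rigid_transform <- function(max_translation_mm = 100) {
  rigid_transform(random_quaternion(),
                  stats::runif(3, -max_translation_mm, max_translation_mm))
}
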