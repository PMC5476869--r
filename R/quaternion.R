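#' Quaternion and Euler-angle kinematics
#'
#' Orientation samples from the headset are unit quaternions stored scalar-last
#' as `(qx, qy, qz, qw)` — the convention of the Unity/GearVR source devices.
#' Head pose is reported as Euler angles in the intrinsic Y-Z-X rotation
#' sequence: yaw about the vertical Y axis (left/right), then pitch about Z
#' (up/down), then roll about X (head tilt). Angles are in degrees with
#' yaw, roll in (-180, 180] and pitch in [-90, 90].
#'
#' @name kinematics
NULL

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  q <- as.matrix(q)
  if (ncol(q) != 4L) stop("quaternions must have 4 components (qx, qy, qz, qw)")
  storage.mode(q) <- "double"
  colnames(q) <- c("qx", "qy", "qz", "qw")
  q
}

#' Normalize quaternions to unit norm with a fixed sign convention
#'
#' Scales each quaternion to unit norm and flips its sign so that `qw >= 0`
#' (`q` and `-q` encode the same rotation; a fixed hemisphere makes outputs
#' deterministic).
#'
#' @param q numeric vector of length 4 `(qx, qy, qz, qw)` or an n x 4 matrix,
#'   one quaternion per row.
#' @return Same shape as the input, unit-norm, `qw >= 0`.
#' @examples
#' normalize_quaternion(c(0, 0, 0, 2))   # -> (0, 0, 0, 1)
#' normalize_quaternion(c(0, 0, 0, -1))  # -> (0, 0, 0, 1)
#' @export
normalize_quaternion <- function(q) {
  vec_in <- is.null(dim(q))
  m <- as_quat_matrix(q)
  nrm <- sqrt(rowSums(m^2))
  bad <- which(nrm == 0 | !is.finite(nrm))
  if (length(bad) > 0L) {
    stop("quaternion sample ", bad[1L], " is all-zero or non-finite and cannot be normalized")
  }
  m <- m / nrm
  flip <- m[, 4L] < 0
  m[flip, ] <- -m[flip, ]
  if (vec_in) drop(m) else m
}

quat_norm_check <- function(m, tol = 1e-3) {
  dev <- abs(sqrt(rowSums(m^2)) - 1)
  if (any(dev > tol)) {
    stop("quaternion norm deviates from 1 by more than ", tol,
         " (max deviation ", format(max(dev)), "); call normalize_quaternion() first")
  }
}

# rows of the rotation matrix needed for the Y-Z-X factorization, vectorized.
# R maps body coordinates to world coordinates for the rotation q.
quat_rotmat_elements <- function(m) {
  qx <- m[, 1L]; qy <- m[, 2L]; qz <- m[, 3L]; qw <- m[, 4L]
  list(
    r11 = 1 - 2 * (qy^2 + qz^2),
    r13 = 2 * (qx * qz + qy * qw),
    r21 = 2 * (qx * qy + qz * qw),
    r22 = 1 - 2 * (qx^2 + qz^2),
    r23 = 2 * (qy * qz - qx * qw),
    r31 = 2 * (qx * qz - qy * qw),
    r33 = 1 - 2 * (qx^2 + qy^2)
  )
}

#' Convert unit quaternions to Euler angles (intrinsic Y-Z-X)
#'
#' Factors each rotation as yaw about Y, then pitch about Z, then roll about X
#' (intrinsic), using the two-argument arctangent throughout so yaw and roll
#' cover the full (-180, 180] range. Near gimbal lock (|pitch| within
#' `gimbal_tol_deg` of 90 degrees) yaw and roll are not separately observable;
#' the convention used here sets roll to 0 and absorbs the residual rotation
#' into yaw, which keeps the output deterministic.
#'
#' @param q length-4 vector or n x 4 matrix of unit quaternions, scalar-last.
#' @param gimbal_tol_deg width of the gimbal-lock band around |pitch| = 90
#'   degrees (default 0.1).
#' @return For a single quaternion, a named vector `c(yaw, pitch, roll)` in
#'   degrees; for a matrix, an n x 3 matrix with those columns.
#' @examples
#' quat_to_euler_yzx(c(0, 0, 0, 1))                   # identity -> (0, 0, 0)
#' quat_to_euler_yzx(c(0, sin(pi / 4), 0, cos(pi / 4))) # 90 deg about Y -> yaw 90
#' @export
quat_to_euler_yzx <- function(q, gimbal_tol_deg = 0.1) {
  vec_in <- is.null(dim(q))
  m <- as_quat_matrix(q)
  quat_norm_check(m)
  # re-normalize to suppress O(tol) rounding before the asin
  m <- m / sqrt(rowSums(m^2))
  e <- quat_rotmat_elements(m)
  s <- pmin(pmax(e$r21, -1), 1)
  pitch <- asin(s)
  yaw <- atan2(-e$r31, e$r11)
  roll <- atan2(-e$r23, e$r22)
  locked <- abs(abs(pitch) - pi / 2) < deg2rad(gimbal_tol_deg)
  if (any(locked)) {
    # with roll fixed at 0 the remaining rotation satisfies
    # r13 = sin(yaw), r33 = cos(yaw) regardless of the pitch sign
    yaw[locked] <- atan2(e$r13[locked], e$r33[locked])
    roll[locked] <- 0
  }
  out <- cbind(yaw = rad2deg(yaw), pitch = rad2deg(pitch), roll = rad2deg(roll))
  if (vec_in) drop(out) else out
}

# Hamilton product, scalar-last storage; vectorized over rows
quat_multiply <- function(a, b) {
  a <- as_quat_matrix(a); b <- as_quat_matrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  ax <- a[, 1L]; ay <- a[, 2L]; az <- a[, 3L]; aw <- a[, 4L]
  bx <- b[, 1L]; by <- b[, 2L]; bz <- b[, 3L]; bw <- b[, 4L]
  cbind(
    qx = aw * bx + ax * bw + ay * bz - az * by,
    qy = aw * by - ax * bz + ay * bw + az * bx,
    qz = aw * bz + ax * by - ay * bx + az * bw,
    qw = aw * bw - ax * bx - ay * by - az * bz
  )
}

#' Compose Euler angles (intrinsic Y-Z-X) into a unit quaternion
#'
#' Inverse of [quat_to_euler_yzx()]: composes the elemental rotations
#' Y(yaw) * Z(pitch) * X(roll) as a quaternion product. Output is unit-norm
#' with `qw >= 0`.
#'
#' @param yaw,pitch,roll angles in degrees; vectors are recycled to a common
#'   length. Alternatively `yaw` may be a length-3 vector or n x 3 matrix
#'   holding all three angles.
#' @return length-4 vector `(qx, qy, qz, qw)` or n x 4 matrix.
#' @examples
#' euler_yzx_to_quat(0, 0, 0)  # -> (0, 0, 0, 1)
#' @export
euler_yzx_to_quat <- function(yaw, pitch = NULL, roll = NULL) {
  if (is.null(pitch) && is.null(roll)) {
    m <- if (is.null(dim(yaw))) matrix(yaw, ncol = 3L, byrow = TRUE) else as.matrix(yaw)
    yaw <- m[, 1L]; pitch <- m[, 2L]; roll <- m[, 3L]
  }
  k <- max(length(yaw), length(pitch), length(roll))
  yaw <- rep_len(yaw, k); pitch <- rep_len(pitch, k); roll <- rep_len(roll, k)
  if (!all(is.finite(c(yaw, pitch, roll)))) stop("Euler angles must be finite")
  hy <- deg2rad(yaw) / 2; hp <- deg2rad(pitch) / 2; hr <- deg2rad(roll) / 2
  qy <- cbind(0, sin(hy), 0, cos(hy))
  qz <- cbind(0, 0, sin(hp), cos(hp))
  qx <- cbind(sin(hr), 0, 0, cos(hr))
  out <- quat_multiply(quat_multiply(qy, qz), qx)
  out <- normalize_quaternion(out)
  if (k == 1L) drop(out) else out
}

#' Rotate 3-vectors by a quaternion
#'
#' Applies the rotation encoded by unit quaternion `q` to vector `v`
#' (body-to-world). Used mostly in tests and as an independent check of the
#' Euler conversions.
#'
#' @param q length-4 unit quaternion, scalar-last.
#' @param v length-3 numeric vector.
#' @return length-3 rotated vector.
#' @export
quat_rotate_vector <- function(q, v) {
  q <- normalize_quaternion(as.numeric(q))
  p <- c(v, 0)
  qc <- c(-q[1:3], q[4])
  unname(drop(quat_multiply(quat_multiply(q, p), qc))[1:3])
}
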