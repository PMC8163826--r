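#' Euler angle conventions
#'
#' All orientations in the package use intrinsic ZXZ Euler angles in degrees:
#' `R = Rz(phi) %*% Rx(theta) %*% Rz(psi)`. The unit normal of a lattice unit
#' is the rotated z axis, `R %*% c(0, 0, 1)`, so it depends on `phi` and
#' `theta` only; `psi` is the in-plane spin. Canonical triplets have
#' `theta` in `[0, 180]` and `phi`, `psi` in `[0, 360)`.
#'
#' @name euler-conventions
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_z <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' Rotation matrix from a ZXZ Euler triplet
#'
#' @param phi,theta,psi Euler angles in degrees (intrinsic ZXZ).
#' @return 3x3 proper rotation matrix.
#' @export
rotation_from_euler <- function(phi, theta, psi) {
  rot_z(phi) %*% rot_x(theta) %*% rot_z(psi)
}

#' Canonicalized Euler triplet from a rotation matrix
#'
#' Inverse of [rotation_from_euler]. At the gimbal degeneracies
#' (`theta = 0` or `180`) `psi` is fixed to 0 and the spin is absorbed
#' into `phi`.
#'
#' @param R 3x3 rotation matrix.
#' @return Named numeric vector `c(phi, theta, psi)` in degrees, canonical.
#' @export
euler_from_rotation <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  ct <- max(-1, min(1, R[3, 3]))
  theta <- rad2deg(acos(ct))
  st <- sqrt(max(0, 1 - ct^2))
  if (st < 1e-9) {
    # R reduces to an in-plane rotation Rz(phi +/- psi)
    phi <- rad2deg(atan2(R[2, 1], R[1, 1]))
    if (ct < 0) phi <- -phi
    psi <- 0
  } else {
    phi <- rad2deg(atan2(R[1, 3], -R[2, 3]))
    psi <- rad2deg(atan2(R[3, 1], R[3, 2]))
  }
  canonical_euler(phi, theta, psi)
}

#' Canonicalize a ZXZ Euler triplet
#'
#' Maps `theta` into `[0, 180]` and `phi`, `psi` into `[0, 360)` without
#' changing the rotation.
#'
#' @inheritParams rotation_from_euler
#' @return Named numeric vector `c(phi, theta, psi)`.
#' @export
canonical_euler <- function(phi, theta, psi) {
  phi <- as.numeric(phi); theta <- as.numeric(theta); psi <- as.numeric(psi)
  theta <- theta %% 360
  if (theta > 180) {
    # Rz(phi) Rx(theta) Rz(psi) == Rz(phi+180) Rx(360-theta) Rz(psi+180)
    theta <- 360 - theta
    phi <- phi + 180
    psi <- psi + 180
  }
  c(phi = phi %% 360, theta = theta, psi = psi %% 360)
}

#' Unit normal vector from a ZXZ Euler triplet
#'
#' The rotated z axis `R %*% c(0,0,1)`; independent of `psi`.
#'
#' @inheritParams rotation_from_euler
#' @return Unit 3-vector.
#' @export
normal_from_euler <- function(phi, theta, psi = 0) {
  tr <- deg2rad(theta); pr <- deg2rad(phi)
  c(sin(pr) * sin(tr), -cos(pr) * sin(tr), cos(tr))
}

#' Euler triplet for a full orthonormal frame
#'
#' Builds the rotation whose columns are `(x_axis, z cross x, z_axis)` and
#' returns its canonical Euler triplet. `x_axis` is orthogonalized against
#' `z_axis` first.
#'
#' @param z_axis Unit normal direction.
#' @param x_axis In-plane reference direction (defaults to a deterministic
#'   tangent).
#' @return Named numeric vector `c(phi, theta, psi)`.
#' @export
euler_from_frame <- function(z_axis, x_axis = NULL) {
  z <- z_axis / sqrt(sum(z_axis^2))
  if (is.null(x_axis)) {
    ref <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    x_axis <- ref - sum(ref * z) * z
  } else {
    x_axis <- x_axis - sum(x_axis * z) * z
  }
  nx <- sqrt(sum(x_axis^2))
  if (nx < 1e-12) stop("x_axis is parallel to z_axis", call. = FALSE)
  x <- x_axis / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  euler_from_rotation(cbind(x, y, z))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

angle_between <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  rad2deg(acos(max(-1, min(1, sum(a * b) / (na * nb)))))
}

# Minimal rotation taking unit vector `from` onto unit vector `to`
# (Rodrigues). Identity when already aligned; 180-degree flip handled with an
# arbitrary perpendicular axis.
align_rotation <- function(from, to) {
  v <- cross3(from, to)
  s <- sqrt(sum(v^2))
  c_ <- sum(from * to)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    axis <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * from) * from
    axis <- axis / sqrt(sum(axis^2))
    return(2 * tcrossprod(axis) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Pairwise geometry of two lattice units
#'
#' Computes the descriptors used by the connectivity criteria and the
#' class-geometry statistics:
#' \describe{
#'   \item{distance}{centre-to-centre separation in angstroms.}
#'   \item{tilt}{angle between the two unit normals, degrees in `[0, 180]`
#'     (also reported as `normal_diff`, the connectivity-criterion name).}
#'   \item{curvature}{how far neighbour B sits below A's tangential plane:
#'     `angle(n_a, B - A) - 90` degrees. Positive on a convex-outward
#'     surface (neighbour bends away from the outward normal).}
#'   \item{twist}{signed in-plane rotation difference, degrees in
#'     `(-180, 180]`: B's in-plane x axis is parallel-transported onto A's
#'     tangential plane (minimal rotation taking `n_b` to `n_a`) and compared
#'     with A's x axis about `n_a`.}
#' }
#'
#' @param a,b One-row data frames (or named lists) with `x, y, z` in voxels
#'   and `phi, theta, psi` in degrees.
#' @param voxel_size Angstroms per voxel.
#' @return One-row tibble with `distance`, `tilt`, `twist`, `curvature`,
#'   `normal_diff`.
#' @export
pair_geometry <- function(a, b, voxel_size) {
  pa <- c(a$x, a$y, a$z) * voxel_size
  pb <- c(b$x, b$y, b$z) * voxel_size
  d <- pb - pa
  dist <- sqrt(sum(d^2))
  if (dist < 1e-9) stop("units have coincident positions", call. = FALSE)
  na_ <- normal_from_euler(a$phi, a$theta)
  nb_ <- normal_from_euler(b$phi, b$theta)
  tilt <- angle_between(na_, nb_)
  curvature <- angle_between(na_, d) - 90
  Ra <- rotation_from_euler(a$phi, a$theta, a$psi)
  Rb <- rotation_from_euler(b$phi, b$theta, b$psi)
  xb_t <- align_rotation(nb_, na_) %*% Rb[, 1]
  xa <- Ra[, 1]
  tw <- rad2deg(atan2(sum(cross3(xa, xb_t) * na_), sum(xa * xb_t)))
  if (tw <= -180) tw <- tw + 360
  tibble(distance = dist, tilt = tilt, twist = tw,
         curvature = curvature, normal_diff = tilt)
}
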