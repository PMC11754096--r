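#' Euler triplet to rotation matrix
#'
#' Converts a ZYZ Euler triplet in degrees to a 3x3 rotation matrix using
#' the intrinsic composition `R = Rz(phi) %*% Ry(theta) %*% Rz(psi)` — the
#' rot/tilt/psi composition of RELION particle tables. Angles act on column
#' vectors; the matrix maps reference-frame coordinates to the particle
#' frame.
#'
#' @param phi,theta,psi Euler angles in degrees. Alternatively `phi` may be
#'   a length-3 numeric vector `c(phi, theta, psi)`.
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @examples
#' euler_to_matrix(0, 0, 0)        # identity
#' euler_to_matrix(0, 180, 0)      # diag(-1, 1, -1)
#' @export
euler_to_matrix <- function(phi, theta = NULL, psi = NULL) {
  if (is.null(theta) && length(phi) == 3) {
    theta <- phi[2]; psi <- phi[3]; phi <- phi[1]
  }
  stopifnot(is.finite(phi), is.finite(theta), is.finite(psi))
  rot_z(phi) %*% rot_y(theta) %*% rot_z(psi)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)) || !all(is.finite(R))) {
    stop("not a 3x3 numeric matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("matrix is not a rotation (orthonormality/det check failed)")
  }
  invisible(R)
}

#' Rotation matrix to Euler triplet
#'
#' Inverse of [euler_to_matrix()]. At gimbal degeneracy (`theta` within
#' ~1e-7 degrees of 0 or 180) the decomposition is not unique; the
#' convention `psi = 0` is applied and the result carries attribute
#' `degenerate = TRUE`.
#'
#' @param R a valid rotation matrix (orthonormal to 1e-6, det +1).
#' @return numeric vector `c(phi, theta, psi)` in degrees, `theta` in
#'   `[0, 180]`, `phi`/`psi` in `[-180, 180)`.
#' @export
matrix_to_euler <- function(R) {
  check_rotation(R)
  r2d <- 180 / pi
  ct <- min(max(R[3, 3], -1), 1)
  theta <- acos(ct) * r2d
  degenerate <- sin(theta * pi / 180) < 1e-9
  if (degenerate) {
    psi <- 0
    # theta=0: R = Rz(phi+psi); theta=180: R = Rz(phi-psi) %*% diag(-1,1,-1)
    phi <- atan2(R[2, 1], R[1, 1]) * r2d
    if (ct < 0) phi <- phi - 180
  } else {
    phi <- atan2(R[2, 3], R[1, 3]) * r2d
    psi <- atan2(R[3, 2], -R[3, 1]) * r2d
  }
  out <- c(phi = wrap_angle(phi), theta = theta, psi = wrap_angle(psi))
  attr(out, "degenerate") <- degenerate
  out
}

#' Relative rotation between two oriented particles
#'
#' Returns the rotation carrying the reference particle's frame onto the
#' neighbour's: `R(reference)^-1 %*% R(neighbor)`. Equal orientations give
#' the identity, so in hemisphere maps "no relative rotation" sits at the
#' north pole.
#'
#' @param neighbor,reference Euler triplets `c(phi, theta, psi)` in degrees,
#'   or 3x3 rotation matrices.
#' @return a 3x3 rotation matrix.
#' @export
relative_rotation <- function(neighbor, reference) {
  Rn <- if (is.matrix(neighbor)) check_rotation(neighbor) else
    euler_to_matrix(neighbor)
  Rr <- if (is.matrix(reference)) check_rotation(reference) else
    euler_to_matrix(reference)
  t(Rr) %*% Rn
}

#' Rotate the reference pole
#'
#' Applies a rotation to the unit vector `(0, 0, 1)`. Under the identity
#' the pole stays put; the image's z-sign decides the hemisphere in
#' [stereographic_project()].
#'
#' @param R a rotation matrix.
#' @return unit 3-vector `R %*% c(0, 0, 1)`.
#' @export
rotated_pole <- function(R) {
  check_rotation(R)
  as.numeric(R[, 3])
}

#' Stereographic hemisphere projection
#'
#' Projects a unit vector onto a planar disc, splitting the sphere into a
#' northern map (`z > 0`, projected from the south pole:
#' `(u, v) = (x, y) / (1 + z)`) and a southern map (`z <= 0`, projected
#' from the north pole: `(u, v) = (x, y) / (1 - z)`). Each map sends its
#' hemisphere into the closed unit disc; the equator, including the `z = 0`
#' boundary itself, belongs to the southern map. The north pole — zero
#' relative rotation — maps to `(0, 0)` on the northern disc.
#'
#' @param v unit 3-vector (norm within 1e-6 of 1).
#' @return list with `u`, `v` (planar coordinates, `u^2 + v^2 <= 1`) and
#'   `hemisphere` (`"north"` or `"south"`).
#' @export
stereographic_project <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) == 3)
  nrm <- sqrt(sum(v^2))
  if (abs(nrm - 1) > 1e-6) stop("input is not a unit vector")
  v <- v / nrm
  if (v[3] > 0) {
    list(u = v[1] / (1 + v[3]), v = v[2] / (1 + v[3]), hemisphere = "north")
  } else {
    list(u = v[1] / (1 - v[3]), v = v[2] / (1 - v[3]), hemisphere = "south")
  }
}

# Haar-uniform random rotation matrices via uniform quaternions.
random_rotation <- function(n = 1) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) quat_to_matrix(q[i, ]))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Haar-uniform Euler triplets (degrees), vectorised; returns n x 3 matrix.
random_euler <- function(n) {
  m <- t(vapply(random_rotation(n), matrix_to_euler, numeric(3)))
  colnames(m) <- c("phi", "theta", "psi")
  m
}
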