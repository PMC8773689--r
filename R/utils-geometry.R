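# Small 3D geometry toolkit shared by the glycan builder, docking and scoring.
# Coordinates are plain numeric matrices (n x 3) in Angstrom; angles in degrees
# unless a function name says otherwise.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation about a (not necessarily unit) axis through the origin.
#'
#' @param axis numeric length-3 axis vector.
#' @param angle_deg rotation angle in degrees (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- angle_deg * DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

rot_x <- function(a) rotation_about_axis(c(1, 0, 0), a)
rot_y <- function(a) rotation_about_axis(c(0, 1, 0), a)
rot_z <- function(a) rotation_about_axis(c(0, 0, 1), a)

# Unit quaternion helpers (w, x, y, z). Used to parameterize docking poses.
quat_normalize <- function(q) q / vnorm(q)

quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_axis_angle <- function(axis, angle_rad) {
  u <- unitv(axis)
  c(cos(angle_rad / 2), sin(angle_rad / 2) * u)
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  quat_normalize(q)
}

#' Dihedral angle of four points
#'
#' Signed torsion angle p1-p2-p3-p4 using the IUPAC convention (cis = 0,
#' positive clockwise looking from p2 towards p3).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return angle in degrees in (-180, 180], or `NA` when the construction is
#'   degenerate (collinear backbone atoms).
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) return(NA_real_)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

bond_angle <- function(p1, p2, p3) {
  u <- unitv(p1 - p2); v <- unitv(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

#' Place an atom from internal coordinates
#'
#' Position a point `d` at distance `r` from `c`, bond angle `theta` (d-c-b)
#' and dihedral `chi` (d-c-b-a), the standard NeRF construction.
#'
#' @param a,b,c reference coordinates (dihedral measured as d-c-b-a).
#' @param r bond length (Angstrom), `theta` angle (deg), `chi` dihedral (deg).
#' @return length-3 coordinate.
#' @keywords internal
place_atom_zmat <- function(a, b, c, r, theta, chi) {
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  th <- theta * DEG; ch <- chi * DEG
  d_local <- c(-r * cos(th), r * sin(th) * cos(ch), -r * sin(th) * sin(ch))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# The two missing tetrahedral directions at a center bonded to neighbors along
# unit vectors u1, u2. Returns a 2 x 3 matrix of unit vectors.
tetrahedral_directions <- function(u1, u2, angle = 109.47) {
  ct <- cos(angle * DEG)
  c12 <- sum(u1 * u2)
  s <- u1 + u2
  a <- ct / (1 + c12)
  w <- cross3(u1, u2)
  w2 <- sum(w * w)
  rem <- 1 - a^2 * sum(s * s)
  b <- if (rem > 0 && w2 > 1e-12) sqrt(rem / w2) else 0
  rbind(a * s + b * w, a * s - b * w)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation of `mobile` onto `fixed` via SVD, with
#' the usual determinant correction to exclude reflections.
#'
#' @param mobile,fixed n x 3 coordinate matrices with matched rows.
#' @return list with `R` (3x3 rotation), `t` (translation applied after
#'   rotation), `rmsd` (Angstrom) and `coords` (superposed mobile).
#' @export
kabsch <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (!all(dim(mobile) == dim(fixed)))
    stop("atom-count mismatch between mobile and fixed coordinate sets")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- sweep(A %*% t(R), 2, cf, `+`)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  list(R = R, t = cf - as.vector(R %*% cm), rmsd = rmsd, coords = moved)
}

#' Root-mean-square deviation without superposition
#' @param a,b matched n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_raw <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("atom-count mismatch")
  sqrt(mean(rowSums((a - b)^2)))
}
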