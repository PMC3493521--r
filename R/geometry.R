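# Low-level vector geometry shared by the peptide builder, docking and
# ensemble statistics. All coordinates are in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Places a new point bonded to `c` at distance `bond`, with angle
#' `angle` at `c` measured from `b`, and torsion `torsion` about the
#' `b`-`c` axis measured from `a` (natural extension reference frame).
#'
#' @param a,b,c Reference points (numeric 3-vectors), most distal first.
#' @param bond Bond length in Angstrom.
#' @param angle Bond angle in degrees (a priori the angle b-c-new).
#' @param torsion Dihedral a-b-c-new in degrees.
#' @return Numeric 3-vector.
#' @keywords internal
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}

#' Dihedral angle of four points, degrees in (-180, 180]
#' @keywords internal
dihedral4 <- function(p0, p1, p2, p3) {
  b0 <- p0 - p1
  b1 <- unitv(p2 - p1)
  b2 <- p3 - p2
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(vcross(b1, v) * w)
  atan2(y, x) * 180 / pi
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis Direction (3-vector, need not be normalised).
#' @param angle Rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- unitv(axis)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
               3L, 3L, byrow = TRUE)
  ct * diag(3L) + st * ux + (1 - ct) * (u %*% t(u))
}

euler_zyz <- function(alpha, beta, gamma) {
  rotation_about_axis(c(0, 0, 1), alpha) %*%
    rotation_about_axis(c(0, 1, 0), beta) %*%
    rotation_about_axis(c(0, 0, 1), gamma)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral);
# used for the Shrake-Rupley sphere sampling.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z * z))
  cbind(r * cos(phi), r * sin(phi), z)
}
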