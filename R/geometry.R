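# Small vector-geometry helpers used by peptide construction and torsion
# measurement.  All angles in degrees.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.vcross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Dihedral angle of four points
#'
#' Signed torsion angle a-b-c-d in degrees, in (-180, 180].
#'
#' @param a,b,c,d Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @keywords internal
.dihedral <- function(a, b, c, d) {
  b0 <- a - b
  b1 <- c - b
  b1 <- b1 / .vnorm(b1)
  b2 <- d - c
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  .rad2deg(atan2(sum(.vcross(b1, v) * w), sum(v * w)))
}

.bond_angle <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  cs <- sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))
  .rad2deg(acos(max(-1, min(1, cs))))
}

# NeRF placement: position atom X bonded to c with |X-c| = bond,
# angle(b, c, X) = ang and dihedral(a, b, c, X) = dih (degrees).
.place_atom <- function(a, b, c, bond, ang, dih) {
  ang <- .deg2rad(ang)
  dih <- .deg2rad(dih)
  bc <- c - b
  bc <- bc / .vnorm(bc)
  ab <- b - a
  n <- .vcross(ab, bc)
  n <- n / .vnorm(n)
  m <- .vcross(n, bc)
  d2 <- c(
    -bond * cos(ang),
    bond * sin(ang) * cos(dih),
    bond * sin(ang) * sin(dih)
  )
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix for rotation by theta degrees about unit axis u
# (right-hand rule).
.rot_matrix <- function(u, theta) {
  th <- .deg2rad(theta)
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1]
  uy <- u[2]
  uz <- u[3]
  matrix(
    c(
      ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
      uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
      uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
    ),
    nrow = 3, byrow = TRUE
  )
}
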