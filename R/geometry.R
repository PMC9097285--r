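## Small 3D geometry kernel shared by topology, maps and fixtures.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

#' Dihedral angle of four points
#'
#' Signed torsion about the b--c axis using the standard atan2 construction,
#' following the IUPAC sign convention (cis = 0, trans = +-180).
#'
#' @param a,b,c,d Numeric length-3 coordinates.
#' @return Angle in degrees in `[-180, 180)`.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang >= 180) ang <- ang - 360
  ang
}

## Natural-extension (NeRF) atom placement: position atom D bonded to C with
## |CD| = bond, angle(BCD) = angle (deg), dihedral(ABCD) = torsion (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  d_loc <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  bc <- vunit(c - b)
  n  <- vunit(vcross(b - a, bc))
  m  <- vcross(n, bc)
  as.numeric(c + cbind(bc, m, n) %*% d_loc)
}

## Rotation matrix about a unit axis (Rodrigues), used in tests and fixtures.
rotation_matrix <- function(axis, angle_deg) {
  u <- vunit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Orthonormal frame of an amide group: x along C->O, z normal to the
## O=C-N plane, y completing a right-handed set (in-plane, toward N).
amide_frame <- function(rC, rO, rN) {
  ex <- vunit(rO - rC)
  cn <- rN - rC
  nz <- vcross(ex, cn)
  if (vnorm(nz) < 1e-8 * vnorm(cn))
    stop("degenerate amide geometry: C, O, N are collinear")
  ez <- vunit(nz)
  ey <- vcross(ez, ex)
  cbind(ex, ey, ez)
}
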