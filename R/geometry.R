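## Small 3D geometry helpers shared by the peptide builder, the mutant
## builder and the secondary-structure assignment.  Angles are in degrees.

deg2rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle defined by four points
#'
#' Signed torsion angle a-b-c-d following the standard convention
#' (cis = 0, trans = 180/-180).
#'
#' @param a,b,c,d numeric length-3 coordinate vectors.
#' @return angle in degrees in (-180, 180].
#' @export
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

bond_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

## Natural-extension-reference-frame placement: position a new atom D at
## distance `length` from C, with angle(B-C-D) = `angle` and torsion
## (A-B-C-D) = `torsion`.
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          -length * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## CB placement from backbone N, CA, C using the tetrahedral construction;
## the out-of-plane side is chosen to give the L configuration.
place_cb <- function(n, ca, c, length = 1.53, angle = 110.5) {
  u1 <- unit(n - ca)
  u2 <- unit(c - ca)
  bis <- unit(u1 + u2)
  perp <- unit(cross3(u1, u2))
  half <- acos(sum(u1 * bis))           # half the N-CA-C angle
  cos_alpha <- -cos(deg2rad(angle)) / cos(half)
  cos_alpha <- max(-1, min(1, cos_alpha))
  alpha <- acos(cos_alpha)
  dir <- -cos(alpha) * bis + sin(alpha) * perp
  ca + length * unit(dir)
}

## Rotation matrix for angle `theta` (degrees) about unit axis `axis`.
rotation_matrix <- function(axis, theta) {
  u <- unit(axis)
  th <- deg2rad(theta)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

## Fibonacci (golden-spiral) quasi-uniform points on the unit sphere.
## Deterministic for a given n, which makes the SASA estimate reproducible.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
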