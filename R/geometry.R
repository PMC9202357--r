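# Elementary vector geometry used by the builder and the assessment code.
# All angles in degrees at the interfaces; radians internally.

.deg <- pi / 180

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

#' Distance between two points
#' @param a,b numeric xyz vectors.
#' @return distance in the coordinate units (\enc{Å}{Angstrom} throughout).
#' @keywords internal
.dist3 <- function(a, b) .vnorm(a - b)

#' Bond angle a-b-c in degrees
#' @keywords internal
.angle3 <- function(a, b, c) {
  u <- .unit(a - b); v <- .unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) / .deg
}

#' Torsion angle a-b-c-d in degrees, IUPAC sign convention
#' @keywords internal
.torsion4 <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / .vnorm(b2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) / .deg
}

# Natural extension reference frame (NeRF) placement: position atom X so that
# |X-C| = b, angle(X,C,B) = ang and torsion(X,C,B,A) = tor.
.nerf <- function(A, B, C, b, ang, tor) {
  ang <- ang * .deg
  tor <- tor * .deg
  bc <- .unit(C - B)
  n <- .unit(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  d <- b * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Rotate vector v about unit axis k by theta degrees (Rodrigues).
.rot_axis <- function(v, k, theta) {
  th <- theta * .deg
  v * cos(th) + .cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}
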