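# Small 3D geometry helpers (internal).

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

.angle_deg <- function(a, b, c) {
  u <- .unit(a - b); v <- .unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

.dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(.unit(b2), n1)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Natural-extension placement: position a new atom bonded to c, with bond
# length `bond`, angle b-c-new `angle` (deg) and dihedral a-b-c-new
# `dihedral` (deg).
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(dih),
         bond * sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}
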