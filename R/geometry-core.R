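# Low-level vector geometry shared by the backbone builders and the
# per-residue descriptor calculations.  All functions operate on plain
# numeric 3-vectors or n x 3 matrices of coordinates in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vangle <- function(a, b) {
  # angle between two vectors in degrees, robust to rounding at 0/180
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

#' Signed torsion angle of four points
#'
#' Computes the dihedral angle defined by four points, using the IUPAC sign
#' convention: looking from `p2` towards `p3`, a clockwise rotation of the
#' far bond relative to the near bond is positive.  The cis arrangement is 0
#' degrees, trans is 180.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in `[-180, 180]`, or `NA` when the angle is
#'   undefined because consecutive points coincide or three defining points
#'   are collinear.
#' @examples
#' dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1)) # cis, 0
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9) return(NA_real_)
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) return(NA_real_)
  b2u <- b2 / vnorm(b2)
  m1 <- vcross(n1, b2u)
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Place atom D given three reference atoms A-B-C, the C-D bond length, the
# B-C-D bond angle (degrees) and the A-B-C-D torsion (degrees).  Standard
# internal-coordinate (NeRF-style) construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Euclidean distance between two 3-vectors.
adist <- function(a, b) sqrt(sum((a - b)^2))
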