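# Internal-coordinate geometry: NeRF atom placement, angles and dihedrals.

#' @keywords internal
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
vnorm <- function(a) sqrt(sum(a * a))

#' @keywords internal
vunit <- function(a) a / vnorm(a)

#' Place an atom from internal coordinates (NeRF)
#'
#' Places atom D given three reference positions so that |C-D| = r, the
#' angle B-C-D equals `theta` and the dihedral A-B-C-D equals `phi`
#' (IUPAC sign convention, degrees).
#'
#' @param a,b,c3 numeric xyz of the three reference atoms (A, B, C).
#' @param r bond length in Angstrom.
#' @param theta bond angle B-C-D in degrees.
#' @param phi dihedral A-B-C-D in degrees.
#' @return numeric xyz of the placed atom.
#' @keywords internal
place_atom <- function(a, b, c3, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- vunit(c3 - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- r * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c3 + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Dihedral angle of four points, degrees, IUPAC sign convention
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Bond angle at p2 of three points, degrees
#' @keywords internal
bond_angle <- function(p1, p2, p3) {
  v1 <- vunit(p1 - p2)
  v2 <- vunit(p3 - p2)
  acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi
}

#' @keywords internal
element_of <- function(atom_name) {
  substr(gsub("[0-9]", "", atom_name), 1, 1)
}
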