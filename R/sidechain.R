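# Side-chain templates: idealized internal-coordinate atom trees for the 20
# standard residues. Each atom is placed by NeRF from three previously placed
# atoms; dihedrals are either fixed (ring / planar-group geometry) or tied to
# a rotatable chi angle with an additive offset (branch atoms).

# Row format: name, a/b/c = dihedral reference atoms (dihedral a-b-c-name),
# r bond length (A), theta bond angle b-c-name (deg), chi (0 = fixed
# dihedral), offset (deg; dihedral = chi_k + offset, or just offset if fixed).
#' @keywords internal
sc_row <- function(name, a, b, c, r, theta, chi, offset) {
  data.frame(name = name, a = a, b = b, c = c, r = r, theta = theta,
             chi = chi, offset = offset, stringsAsFactors = FALSE)
}

#' @keywords internal
CB_ROW <- sc_row("CB", "C", "N", "CA", 1.53, 110.4, 0L, 122.6)

#' @keywords internal
SIDECHAIN_TEMPLATES <- local({
  g <- function(name, r, theta, chi = 1L, offset = 0)  # gamma-level atom
    sc_row(name, "N", "CA", "CB", r, theta, chi, offset)
  tpl <- list()
  tpl$G <- CB_ROW[0, ]
  tpl$A <- CB_ROW
  tpl$S <- rbind(CB_ROW, g("OG", 1.42, 110.5))
  tpl$C <- rbind(CB_ROW, g("SG", 1.81, 114.0))
  tpl$T <- rbind(CB_ROW, g("OG1", 1.43, 109.5), g("CG2", 1.52, 110.5, 1L, -120))
  tpl$V <- rbind(CB_ROW, g("CG1", 1.52, 110.5), g("CG2", 1.52, 110.5, 1L, 120))
  tpl$L <- rbind(CB_ROW, g("CG", 1.53, 116.3),
                 sc_row("CD1", "CA", "CB", "CG", 1.52, 110.7, 2L, 0),
                 sc_row("CD2", "CA", "CB", "CG", 1.52, 110.7, 2L, 120))
  tpl$I <- rbind(CB_ROW, g("CG1", 1.53, 110.4), g("CG2", 1.52, 110.5, 1L, -120),
                 sc_row("CD1", "CA", "CB", "CG1", 1.52, 113.8, 2L, 0))
  tpl$M <- rbind(CB_ROW, g("CG", 1.52, 114.1),
                 sc_row("SD", "CA", "CB", "CG", 1.81, 112.7, 2L, 0),
                 sc_row("CE", "CB", "CG", "SD", 1.79, 100.8, 3L, 0))
  tpl$P <- rbind(CB_ROW, g("CG", 1.49, 104.5, 0L, 28),
                 sc_row("CD", "CA", "CB", "CG", 1.50, 105.5, 0L, -35))
  ring6 <- function(prefix_d1 = "CD1", prefix_d2 = "CD2") rbind(
    sc_row(prefix_d1, "CA", "CB", "CG", 1.39, 120.8, 2L, 0),
    sc_row(prefix_d2, "CA", "CB", "CG", 1.39, 120.8, 2L, 180),
    sc_row("CE1", "CB", "CG", prefix_d1, 1.39, 120.0, 0L, 180),
    sc_row("CE2", "CB", "CG", prefix_d2, 1.39, 120.0, 0L, 180),
    sc_row("CZ", "CG", prefix_d1, "CE1", 1.39, 120.0, 0L, 0))
  tpl$F <- rbind(CB_ROW, g("CG", 1.50, 113.8), ring6())
  tpl$Y <- rbind(CB_ROW, g("CG", 1.50, 113.8), ring6(),
                 sc_row("OH", "CD1", "CE1", "CZ", 1.38, 120.0, 0L, 180))
  tpl$W <- rbind(CB_ROW, g("CG", 1.50, 113.6),
                 sc_row("CD1", "CA", "CB", "CG", 1.37, 126.9, 2L, 0),
                 sc_row("CD2", "CA", "CB", "CG", 1.43, 126.9, 2L, 180),
                 sc_row("NE1", "CB", "CG", "CD1", 1.38, 110.2, 0L, 180),
                 sc_row("CE2", "CG", "CD1", "NE1", 1.37, 109.0, 0L, 0),
                 sc_row("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0L, 180),
                 sc_row("CZ2", "CG", "CD2", "CE2", 1.40, 122.3, 0L, 180),
                 sc_row("CZ3", "CG", "CD2", "CE3", 1.39, 118.6, 0L, 180),
                 sc_row("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0L, 0))
  tpl$D <- rbind(CB_ROW, g("CG", 1.52, 113.1),
                 sc_row("OD1", "CA", "CB", "CG", 1.25, 118.5, 2L, 0),
                 sc_row("OD2", "CA", "CB", "CG", 1.25, 118.5, 2L, 180))
  tpl$N <- rbind(CB_ROW, g("CG", 1.52, 112.7),
                 sc_row("OD1", "CA", "CB", "CG", 1.23, 120.8, 2L, 0),
                 sc_row("ND2", "CA", "CB", "CG", 1.33, 116.4, 2L, 180))
  tpl$E <- rbind(CB_ROW, g("CG", 1.52, 114.1),
                 sc_row("CD", "CA", "CB", "CG", 1.52, 112.6, 2L, 0),
                 sc_row("OE1", "CB", "CG", "CD", 1.25, 118.5, 3L, 0),
                 sc_row("OE2", "CB", "CG", "CD", 1.25, 118.5, 3L, 180))
  tpl$Q <- rbind(CB_ROW, g("CG", 1.52, 114.1),
                 sc_row("CD", "CA", "CB", "CG", 1.52, 112.6, 2L, 0),
                 sc_row("OE1", "CB", "CG", "CD", 1.23, 120.8, 3L, 0),
                 sc_row("NE2", "CB", "CG", "CD", 1.33, 116.4, 3L, 180))
  tpl$H <- rbind(CB_ROW, g("CG", 1.49, 113.8),
                 sc_row("ND1", "CA", "CB", "CG", 1.38, 122.7, 2L, 0),
                 sc_row("CD2", "CA", "CB", "CG", 1.35, 131.0, 2L, 180),
                 sc_row("CE1", "CB", "CG", "ND1", 1.32, 109.3, 0L, 180),
                 sc_row("NE2", "CB", "CG", "CD2", 1.37, 107.2, 0L, 180))
  tpl$K <- rbind(CB_ROW, g("CG", 1.52, 114.1),
                 sc_row("CD", "CA", "CB", "CG", 1.52, 111.3, 2L, 0),
                 sc_row("CE", "CB", "CG", "CD", 1.52, 111.3, 3L, 0),
                 sc_row("NZ", "CG", "CD", "CE", 1.49, 112.0, 4L, 0))
  tpl$R <- rbind(CB_ROW, g("CG", 1.52, 114.1),
                 sc_row("CD", "CA", "CB", "CG", 1.52, 111.3, 2L, 0),
                 sc_row("NE", "CB", "CG", "CD", 1.46, 112.0, 3L, 0),
                 sc_row("CZ", "CG", "CD", "NE", 1.33, 124.2, 4L, 0),
                 sc_row("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0L, 0),
                 sc_row("NH2", "CD", "NE", "CZ", 1.33, 120.0, 0L, 180))
  tpl[AA1]
})

# Default chi angles used when a side chain is first built (degrees).
#' @keywords internal
DEFAULT_CHIS <- list(
  A = numeric(0), G = numeric(0), P = numeric(0),
  S = -65, C = -65, T = -65, V = 175,
  L = c(-65, 175), I = c(-65, 170), M = c(-65, 175, 175),
  F = c(-65, 90), Y = c(-65, 90), W = c(-65, 95), H = c(-65, 90),
  D = c(-65, -20), N = c(-65, -20),
  E = c(-65, 180, -20), Q = c(-65, 180, -20),
  K = c(-65, 180, 180, 180), R = c(-65, 180, 180, 180))

#' Build side-chain heavy-atom coordinates for one residue
#'
#' @param aa one-letter amino-acid code.
#' @param backbone named list with numeric xyz for N, CA, C.
#' @param chis chi angles in degrees (defaults per residue type).
#' @return matrix of side-chain coordinates with atom-name rownames (may have
#'   zero rows for glycine).
#' @keywords internal
build_side_chain <- function(aa, backbone, chis = NULL) {
  tpl <- SIDECHAIN_TEMPLATES[[aa]]
  if (is.null(tpl)) stop("no side-chain template for residue type ", aa)
  if (is.null(chis)) chis <- DEFAULT_CHIS[[aa]]
  pos <- backbone
  if (nrow(tpl) == 0) {
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  out <- matrix(NA_real_, nrow(tpl), 3,
                dimnames = list(tpl$name, c("x", "y", "z")))
  for (i in seq_len(nrow(tpl))) {
    row <- tpl[i, ]
    phi <- if (row$chi > 0L) chis[row$chi] + row$offset else row$offset
    p <- place_atom(pos[[row$a]], pos[[row$b]], pos[[row$c]],
                    row$r, row$theta, phi)
    pos[[row$name]] <- p
    out[i, ] <- p
  }
  out
}

#' Number of chi angles a residue template exposes to repacking
#' @keywords internal
n_template_chis <- function(aa) {
  tpl <- SIDECHAIN_TEMPLATES[[aa]]
  if (is.null(tpl) || nrow(tpl) == 0) return(0L)
  max(0L, max(tpl$chi))
}
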