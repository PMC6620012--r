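# Embedded constant tables: amino-acid alphabets, physico-chemical property
# vectors, substitution matrices, reference SASA maxima, atomic radii and the
# parameters of the native energy model.

#' @keywords internal
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @keywords internal
AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' Normalize an amino-acid code to one-letter form
#'
#' Accepts one-letter or three-letter codes (any case); selenomethionine
#' (MSE / U) maps to M. Returns NA for anything else.
#'
#' @param aa character vector of amino-acid codes.
#' @return character vector of one-letter codes, NA where unrecognized.
#' @export
aa_normalize <- function(aa) {
  aa <- toupper(trimws(aa))
  three_to_one <- stats::setNames(names(AA3), unname(AA3))
  out <- ifelse(aa %in% AA1, aa,
         ifelse(aa %in% names(three_to_one), three_to_one[aa],
         ifelse(aa %in% c("MSE", "U"), "M", NA_character_)))
  unname(out)
}

# The six topology codes of the human transmembrane proteome annotation:
# M membrane, L membrane reentrant loop, I inside, O outside, S signal,
# T transit.
#' @keywords internal
REGION_CODES <- c("M", "L", "I", "O", "S", "T")

# ---------------------------------------------------------------------------
# 12 AAindex physico-chemical property vectors (order AA1).
# hydrophilicity, amphiphilicity, bulkiness, polarity, polarizability,
# isoelectric point, tripeptide accessible surface, H-bond donors, net
# charge, side-chain radius of gyration, membrane-protein composition,
# side-chain contribution to stability.
#' @keywords internal
AAINDEX_TABLE <- local({
  m <- rbind(
    KUHL950101 = c(0.78, 1.58, 1.20, 1.35, 0.55, 1.19, 1.45, 0.68, 0.99, 0.47,
                   0.56, 1.10, 0.66, 0.47, 0.69, 1.00, 1.05, 0.70, 1.00, 0.51),
    MITS020101 = c(0.00, 2.45, 0.00, 0.00, 0.00, 1.25, 1.27, 0.00, 1.45, 0.00,
                   0.00, 3.67, 0.00, 0.00, 0.00, 0.00, 0.00, 6.93, 5.06, 0.00),
    ZIMJ680102 = c(11.50, 14.28, 12.82, 11.68, 13.46, 14.45, 13.57, 3.40,
                   13.69, 21.40, 21.40, 15.71, 16.25, 19.80, 17.43, 9.47,
                   15.77, 21.67, 18.03, 21.57),
    GRAR740102 = c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
                   4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9),
    CHAM820101 = c(0.046, 0.291, 0.134, 0.105, 0.128, 0.180, 0.151, 0.000,
                   0.230, 0.186, 0.186, 0.219, 0.221, 0.290, 0.131, 0.062,
                   0.108, 0.409, 0.298, 0.140),
    ZIMJ680104 = c(6.00, 10.76, 5.41, 2.77, 5.05, 5.65, 3.22, 5.97, 7.59,
                   6.02, 5.98, 9.74, 5.74, 5.48, 6.30, 5.68, 5.66, 5.89,
                   5.66, 5.96),
    CHOC760101 = c(115, 225, 160, 150, 135, 180, 190, 75, 195, 175, 170, 200,
                   185, 210, 145, 115, 140, 255, 230, 155),
    FAUJ880109 = c(0, 4, 2, 1, 0, 2, 1, 0, 1, 0, 0, 2, 0, 0, 0, 1, 1, 1, 1, 0),
    KLEP840101 = c(0, 1, 0, -1, 0, 0, -1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0,
                   0, 0),
    LEVM760105 = c(0.77, 2.38, 1.45, 1.43, 1.22, 1.75, 1.77, 0.58, 1.78, 1.56,
                   1.54, 2.08, 1.80, 1.90, 1.25, 1.08, 1.24, 2.21, 2.13, 1.29),
    CEDJ970103 = c(8.1, 4.6, 3.7, 3.8, 2.0, 3.1, 4.6, 7.0, 2.0, 6.7, 11.0,
                   4.4, 2.8, 5.6, 4.7, 7.3, 5.6, 1.8, 3.3, 7.7),
    TAKK010101 = c(9.8, 7.3, 3.6, 4.9, 3.0, 2.4, 4.4, 0.0, 11.9, 17.2, 17.0,
                   10.5, 11.9, 23.0, 15.0, 2.6, 6.9, 24.2, 17.2, 15.3))
  colnames(m) <- AA1
  m
})

# ---------------------------------------------------------------------------
# BLOSUM62 (NCBI half-bit scores), rows/cols in AA1 order.
#' @keywords internal
BLOSUM62_TABLE <- local({
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4)
  matrix(v, 20, 20, byrow = TRUE, dimnames = list(AA1, AA1))
})

# ---------------------------------------------------------------------------
# Membrane-context substitution table (synthetic stand-in).
#
# The published membrane-specific PHAT matrix is not redistributable here, so
# this table is a documented synthetic analogue: BLOSUM62 plus a symmetric
# hydrophobic-context adjustment (+1 when both residues belong to the strongly
# hydrophobic set {A,C,F,I,L,M,V,W}, reflecting the higher conservation of
# hydrophobic identity inside the bilayer; -1 when exactly one does).
# It preserves the contract of the real table: 20x20, integer, symmetric.
#' @keywords internal
PHAT_TABLE <- local({
  hydro <- AA1 %in% c("A", "C", "F", "I", "L", "M", "V", "W")
  adj <- outer(hydro, hydro, function(a, b) ifelse(a & b, 1L,
                                            ifelse(xor(a, b), -1L, 0L)))
  m <- BLOSUM62_TABLE + adj
  dimnames(m) <- list(AA1, AA1)
  m
})

# Directional substitution tables (synthetic stand-ins for the asymmetric
# SLIM pair). Direction term: substitutions toward residue types more common
# in membrane proteins (CEDJ970103 composition) score one point higher, and
# one point lower in the reverse direction, making the pair asymmetric while
# SLIM_FWD[a,b] == SLIM_REV[b,a] by construction.
#' @keywords internal
SLIM_FWD_TABLE <- local({
  comp <- AAINDEX_TABLE["CEDJ970103", ]
  dir_term <- outer(comp, comp, function(a, b) sign(b - a))
  m <- PHAT_TABLE + dir_term
  dimnames(m) <- list(AA1, AA1)
  m
})

#' @keywords internal
SLIM_REV_TABLE <- t(SLIM_FWD_TABLE)

# ---------------------------------------------------------------------------
# Theoretical maximum SASA per residue (Gly-X-Gly tripeptide maxima, A^2).
#' @keywords internal
MAX_SASA <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
              Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
              L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
              S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# Side-chain volumes (A^3): residue volume minus the glycine volume.
#' @keywords internal
SIDECHAIN_VOLUME <- c(A = 28.5, R = 113.3, N = 54.0, D = 51.0, C = 48.4,
                      Q = 83.7, E = 78.3, G = 0.0, H = 93.1, I = 106.6,
                      L = 106.6, K = 108.5, M = 102.8, F = 129.8, P = 52.6,
                      S = 28.9, T = 56.0, W = 167.7, Y = 133.5, V = 79.9)

# van der Waals radii by element (A).
#' @keywords internal
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# Number of rotatable side-chain chi angles (proline ring treated as rigid).
#' @keywords internal
N_CHI <- c(A = 0L, R = 4L, N = 2L, D = 2L, C = 1L, Q = 3L, E = 3L, G = 0L,
           H = 2L, I = 2L, L = 2L, K = 4L, M = 3L, F = 2L, P = 0L, S = 1L,
           T = 1L, W = 2L, Y = 2L, V = 1L)

# Contact category membership (Tyr and His belong to two categories).
#' @keywords internal
CONTACT_CATEGORIES <- list(
  polar     = c("N", "Q", "T", "S", "Y", "H"),
  charged   = c("K", "R", "D", "E"),
  aromatic  = c("F", "W", "Y", "H"),
  aliphatic = c("A", "L", "I", "V", "M"),
  special   = c("C", "P", "G"))

# ---------------------------------------------------------------------------
# Native energy model parameters.
#
# Electrostatics: Coulomb with distance-dependent dielectric eps = 4r,
#   E = 332 * q_i q_j / (4 r^2) (kcal/mol with q in elementary charges, r in
#   A). Partial charges on formally charged groups only.
# van der Waals: Lennard-Jones 6-12 with rmin = sum of vdW radii and a single
#   well depth.
# H-bond: -1 energy unit per geometric hydrogen bond.
# Solvation: atomic solvation parameter x atomic SASA (Eisenberg-McLachlan
#   style coefficients, kcal/mol/A^2).
# Entropic: ENTROPY_PER_CHI x number of rotatable side-chain chi angles.
#' @keywords internal
ENERGY_PARAMS <- list(
  coulomb_k = 332.0,
  dielectric_slope = 4.0,
  lj_epsilon = 0.1,
  hbond_energy = -1.0,
  hbond_dist_max = 3.5,
  hbond_angle_min = 120,
  entropy_per_chi = 0.6,
  solvation = c(C = 0.016, N = -0.006, O = -0.006, S = 0.021),
  solvation_charged = -0.024)

# Partial charges on side-chain atoms of formally charged residues plus a
# zwitterion-free backbone (no terminal charges in this model).
#' @keywords internal
PARTIAL_CHARGES <- list(
  D = c(OD1 = -0.5, OD2 = -0.5),
  E = c(OE1 = -0.5, OE2 = -0.5),
  K = c(NZ = 1.0),
  R = c(NH1 = 0.5, NH2 = 0.5))

#' Access the embedded constant tables
#'
#' Returns the package's embedded lookup tables: the 12 AAindex
#' physico-chemical property vectors, the BLOSUM62 substitution matrix, the
#' synthetic membrane-context (PHAT-like) and directional (SLIM-like)
#' substitution tables, reference maximum SASA values, side-chain volumes,
#' van der Waals radii, rotatable chi-angle counts, contact-category
#' membership and the native energy-model parameters.
#'
#' @return A named list of tables. Every table covers all 20 standard amino
#'   acids; `blosum62` and `phat` are symmetric, the `slim` pair is
#'   asymmetric with `slim_fwd[a,b] == slim_rev[b,a]`.
#' @examples
#' ct <- constant_tables()
#' ct$blosum62["L", "I"]
#' @export
constant_tables <- function() {
  list(aaindex = AAINDEX_TABLE,
       blosum62 = BLOSUM62_TABLE,
       phat = PHAT_TABLE,
       slim_fwd = SLIM_FWD_TABLE,
       slim_rev = SLIM_REV_TABLE,
       max_sasa = MAX_SASA,
       sidechain_volume = SIDECHAIN_VOLUME,
       vdw_radii = VDW_RADII,
       n_chi = N_CHI,
       contact_categories = CONTACT_CATEGORIES,
       energy_params = ENERGY_PARAMS)
}
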