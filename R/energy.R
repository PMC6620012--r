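# Native residue energy model.
#
# Five terms per residue, each describing the residue's interaction with its
# environment (atoms of all other residues):
#   electrostatic - Coulomb with distance-dependent dielectric eps = 4r:
#                   E = 332 q_i q_j / (4 r^2); partial charges on formally
#                   charged side-chain groups (Asp/Glu carboxylates, Lys
#                   ammonium, Arg guanidinium).
#   vdw           - Lennard-Jones 6-12, rmin = sum of vdW radii, common well
#                   depth; backbone-backbone pairs of adjacent residues are
#                   excluded (covalent peptide geometry).
#   hbond         - -1 energy unit per geometric hydrogen bond involving the
#                   residue.
#   solvation     - atomic solvation parameter x atomic SASA, charged atoms
#                   carrying their own coefficient.
#   entropic      - 0.6 units per rotatable side-chain chi angle (the
#                   configurational cost of ordering the side chain).
# total = sum of the five. This is the package's own documented model, not a
# reproduction of any commercial force field.

#' Per-atom partial charges
#' @keywords internal
atom_charges <- function(model) {
  a <- model$atoms
  q <- numeric(nrow(a))
  for (aa in names(PARTIAL_CHARGES)) {
    tab <- PARTIAL_CHARGES[[aa]]
    for (nm in names(tab)) {
      q[!is.na(a$aa) & a$aa == aa & a$name == nm] <- tab[[nm]]
    }
  }
  q
}

#' Pairwise electrostatic + van der Waals energy of one residue against the
#' rest of the structure
#' @keywords internal
residue_env_pair_energy <- function(model, resi, xyz = NULL, charges = NULL) {
  a <- model$atoms
  if (is.null(xyz)) xyz <- atom_xyz(model)
  if (is.null(charges)) charges <- atom_charges(model)
  p <- ENERGY_PARAMS
  ti <- which(a$resi == resi)
  oi <- which(a$resi != resi)
  if (length(ti) == 0 || length(oi) == 0) {
    return(c(electrostatic = 0, vdw = 0))
  }
  bb <- c("N", "CA", "C", "O")
  elec <- 0; vdw <- 0
  for (i in ti) {
    d2 <- rowSums(sweep(xyz[oi, , drop = FALSE], 2, xyz[i, ])^2)
    near <- d2 < 144  # 12 A cutoff
    if (!any(near)) next
    jj <- oi[near]
    r <- sqrt(d2[near])
    r <- pmax(r, 0.5)  # guard against engineered overlaps
    excl <- a$name[i] %in% bb & a$name[jj] %in% bb &
            abs(a$resi[jj] - resi) == 1
    qq <- charges[i] * charges[jj]
    elec <- elec + sum((p$coulomb_k * qq /
                        (p$dielectric_slope * r^2))[!excl & qq != 0])
    rmin <- a$radius[i] + a$radius[jj]
    sr6 <- (rmin / r)^6
    vdw <- vdw + sum((p$lj_epsilon * (sr6^2 - 2 * sr6))[!excl])
  }
  c(electrostatic = elec, vdw = vdw)
}

#' Total inter-residue pair energy of a model
#'
#' Sum of the electrostatic and van der Waals terms over all unordered
#' residue pairs. This is the objective minimized by Monte-Carlo repacking.
#'
#' @param model a [structure_model()].
#' @return single numeric energy value.
#' @export
system_energy <- function(model) {
  xyz <- atom_xyz(model)
  charges <- atom_charges(model)
  e <- vapply(model$residues$resi, function(ri) {
    sum(residue_env_pair_energy(model, ri, xyz, charges))
  }, numeric(1))
  sum(e) / 2
}

#' Six-term energy decomposition of one residue
#' @keywords internal
residue_energy_terms <- function(model, resi, xyz, charges, per_atom_sasa,
                                 hbonds) {
  a <- model$atoms
  pe <- residue_env_pair_energy(model, resi, xyz, charges)
  nhb <- sum(hbonds$donor_resi == resi | hbonds$acceptor_resi == resi)
  ti <- which(a$resi == resi)
  p <- ENERGY_PARAMS
  solv_coef <- p$solvation[a$elem[ti]]
  solv_coef[is.na(solv_coef)] <- p$solvation[["C"]]
  solv_coef[charges[ti] != 0] <- p$solvation_charged
  solvation <- sum(solv_coef * per_atom_sasa[ti])
  aa <- model$residues$aa[model$residues$resi == resi]
  entropic <- if (!is.na(aa) && aa %in% names(N_CHI)) {
    p$entropy_per_chi * N_CHI[[aa]]
  } else 0
  out <- c(electrostatic = unname(pe["electrostatic"]),
           vdw = unname(pe["vdw"]),
           hbond = p$hbond_energy * nhb,
           entropic = entropic,
           solvation = solvation)
  c(out, total = sum(out))
}

#' Energy profile of a mutation site
#'
#' The six energy terms (electrostatic, van der Waals, hydrogen-bond,
#' entropic, solvation, total) for the target residue, plus the same six
#' terms summed over the residues within `radius` of the target and divided
#' by their count (zero for an empty shell).
#'
#' @param model a [structure_model()].
#' @param chain,position chain id and author residue number of the target.
#' @param radius neighbourhood cutoff in Angstrom.
#' @param per_atom_sasa optional precomputed [atom_sasa()] vector.
#' @param hbonds optional precomputed [hydrogen_bonds()] result.
#' @return list with `target` and `neighborhood`, each a named numeric
#'   vector of the six terms.
#' @export
energy_profile <- function(model, chain, position, radius = 5,
                           per_atom_sasa = NULL, hbonds = NULL) {
  resi <- resolve_residue(model, chain, position)
  xyz <- atom_xyz(model)
  charges <- atom_charges(model)
  if (is.null(per_atom_sasa)) per_atom_sasa <- atom_sasa(model)
  if (is.null(hbonds)) hbonds <- hydrogen_bonds(model)
  target <- residue_energy_terms(model, resi, xyz, charges, per_atom_sasa,
                                 hbonds)
  dmin <- residue_min_dist(model, resi)
  shell <- model$residues$resi[dmin <= radius & model$residues$resi != resi]
  if (length(shell) == 0) {
    nb <- stats::setNames(numeric(6), names(target))
  } else {
    terms <- vapply(shell, function(ri) {
      residue_energy_terms(model, ri, xyz, charges, per_atom_sasa, hbonds)
    }, numeric(6))
    nb <- rowSums(terms) / length(shell)
  }
  list(target = target, neighborhood = nb)
}
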