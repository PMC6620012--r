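# Residue contact profiles: 5 A neighbourhoods, category counts, contact
# area, packing density and geometric hydrogen bonds.

# Donor heavy atoms and their covalent antecedents (for the angle test), and
# acceptor heavy atoms, per residue type; "N"/"O" are the backbone amide and
# carbonyl present in every residue.
#' @keywords internal
HBOND_DONORS <- list(
  backbone = c(N = "CA"),
  S = c(OG = "CB"), T = c(OG1 = "CB"), Y = c(OH = "CZ"), C = c(SG = "CB"),
  N = c(ND2 = "CG"), Q = c(NE2 = "CD"), K = c(NZ = "CE"),
  R = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"), W = c(NE1 = "CD1"),
  H = c(ND1 = "CG", NE2 = "CD2"))

#' @keywords internal
HBOND_ACCEPTORS <- list(
  backbone = "O",
  D = c("OD1", "OD2"), E = c("OE1", "OE2"), N = "OD1", Q = "OE1",
  S = "OG", T = "OG1", Y = "OH", H = c("ND1", "NE2"), M = "SD")

#' Geometric hydrogen bonds of a model
#'
#' A bond is called between a donor and an acceptor heavy atom when their
#' distance is at most `dist_max` (3.5 A) and the angle
#' antecedent-donor-acceptor is at least `angle_min` (120 degrees).
#' Backbone-backbone pairs of adjacent residues are excluded (peptide-bond
#' geometry, not hydrogen bonding).
#'
#' @param model a [structure_model()].
#' @return data.frame with columns donor_idx, acceptor_idx, donor_resi,
#'   acceptor_resi (atom indices into `model$atoms`).
#' @export
hydrogen_bonds <- function(model) {
  a <- model$atoms
  xyz <- atom_xyz(model)
  p <- ENERGY_PARAMS
  don <- list(); acc_idx <- integer(0)
  for (i in seq_len(nrow(a))) {
    aa <- a$aa[i]
    if (a$name[i] == "N") {
      don[[length(don) + 1]] <- c(i, NA)  # antecedent CA resolved below
    } else if (!is.na(aa) && aa %in% names(HBOND_DONORS) &&
               a$name[i] %in% names(HBOND_DONORS[[aa]])) {
      don[[length(don) + 1]] <- c(i, NA)
    }
    if (a$name[i] == "O" ||
        (!is.na(aa) && aa %in% names(HBOND_ACCEPTORS) &&
         a$name[i] %in% HBOND_ACCEPTORS[[aa]])) {
      acc_idx <- c(acc_idx, i)
    }
  }
  antecedent_of <- function(i) {
    aa <- a$aa[i]; nm <- a$name[i]
    ant_name <- if (nm == "N") "CA" else unname(HBOND_DONORS[[aa]][nm])
    j <- which(a$resi == a$resi[i] & a$name == ant_name)
    if (length(j) == 0) NA_integer_ else j[1]
  }
  out <- list()
  for (d in don) {
    i <- d[1]
    ant <- antecedent_of(i)
    if (is.na(ant)) next
    for (j in acc_idx) {
      if (a$resi[j] == a$resi[i]) next
      bb_pair <- a$name[i] == "N" && a$name[j] == "O"
      if (bb_pair && abs(a$resi[i] - a$resi[j]) < 2) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r > p$hbond_dist_max) next
      ang <- bond_angle(xyz[ant, ], xyz[i, ], xyz[j, ])
      if (ang >= p$hbond_angle_min) {
        out[[length(out) + 1]] <- data.frame(
          donor_idx = i, acceptor_idx = j,
          donor_resi = a$resi[i], acceptor_resi = a$resi[j])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor_idx = integer(0), acceptor_idx = integer(0),
                      donor_resi = integer(0), acceptor_resi = integer(0)))
  }
  do.call(rbind, out)
}

#' Minimum heavy-atom distance between the target residue and every residue
#' @keywords internal
residue_min_dist <- function(model, resi) {
  xyz <- atom_xyz(model)
  ti <- residue_atom_idx(model, resi)
  txyz <- xyz[ti, , drop = FALSE]
  vapply(model$residues$resi, function(rj) {
    oj <- residue_atom_idx(model, rj)
    m <- Inf
    for (k in oj) {
      dk <- sqrt(min(rowSums(sweep(txyz, 2, xyz[k, ])^2)))
      if (dk < m) m <- dk
    }
    m
  }, numeric(1))
}

#' Contact profile of a residue
#'
#' A residue is a contact of the target when its minimum heavy-atom distance
#' is at most `radius` (5 A). Category counts follow the membrane-protein
#' convention: polar {N,Q,T,S,Y,H}, charged {K,R,D,E}, aromatic {F,W,Y,H},
#' aliphatic {A,L,I,V,M}, special {C,P,G}; tyrosine and histidine increment
#' both of their categories. Contact area is the SASA the target loses to
#' its environment (isolated minus in-context SASA); packing density is the
#' molecular (van der Waals) surface area over the SASA, the denominator
#' floored at 0.1 A^2.
#'
#' @param model a [structure_model()].
#' @param chain,position chain id and author residue number of the target.
#' @param radius contact cutoff in Angstrom.
#' @param sasa_table optional precomputed [compute_sasa()] result.
#' @param hbonds optional precomputed [hydrogen_bonds()] result.
#' @return list with total_contact_area, side_chain_volume, n_hbonds,
#'   molecular_surface_area, packing_density, n_neighbors_5A and the five
#'   category counts.
#' @export
contact_profile <- function(model, chain, position, radius = 5,
                            sasa_table = NULL, hbonds = NULL) {
  resi <- resolve_residue(model, chain, position)
  res <- model$residues
  target_aa <- res$aa[res$resi == resi]
  if (is.null(sasa_table)) sasa_table <- compute_sasa(model)
  if (is.null(hbonds)) hbonds <- hydrogen_bonds(model)
  dmin <- residue_min_dist(model, resi)
  nb <- res$resi[dmin <= radius & res$resi != resi]
  nb_aa <- res$aa[match(nb, res$resi)]
  count_cat <- function(cat) {
    sum(!is.na(nb_aa) & nb_aa %in% CONTACT_CATEGORIES[[cat]])
  }
  sasa_ctx <- sasa_table$sasa[sasa_table$resi == resi]
  sasa_iso <- isolated_residue_sasa(model, resi)
  ti <- residue_atom_idx(model, resi)
  msa <- sum(atom_sasa(model, probe = 0, atom_idx = ti))
  list(total_contact_area = max(0, sasa_iso - sasa_ctx),
       side_chain_volume = unname(SIDECHAIN_VOLUME[target_aa]),
       n_hbonds = sum(hbonds$donor_resi == resi | hbonds$acceptor_resi == resi),
       molecular_surface_area = msa,
       packing_density = msa / max(sasa_ctx, 0.1),
       n_neighbors_5A = length(nb),
       n_polar = count_cat("polar"),
       n_charged = count_cat("charged"),
       n_aromatic = count_cat("aromatic"),
       n_aliphatic = count_cat("aliphatic"),
       n_special = count_cat("special"))
}
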