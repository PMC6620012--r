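# Solvent accessible surface area by the Shrake-Rupley method, plus relative
# SASA and the three-state exposure classification.

#' @keywords internal
sphere_points <- function(n) {
  # golden-spiral (Fibonacci) points on the unit sphere; deterministic
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent accessible surface area
#'
#' Shrake-Rupley: test points on each atom's solvent-expanded sphere are
#' classified accessible when outside every neighbouring expanded sphere.
#'
#' @param model a [structure_model()].
#' @param probe probe radius in Angstrom (1.4 = water; 0 gives the van der
#'   Waals surface used as the molecular-surface approximation).
#' @param n_points test points per atom (1920 by default; never below
#'   960).
#' @param atom_idx optional subset of atom indices to evaluate (occlusion is
#'   still computed against all atoms).
#' @return numeric vector of per-atom SASA in A^2 (length = atoms evaluated).
#' @export
atom_sasa <- function(model, probe = 1.4, n_points = 1920, atom_idx = NULL) {
  a <- model$atoms
  xyz <- atom_xyz(model)
  rad <- a$radius + probe
  if (is.null(atom_idx)) atom_idx <- seq_len(nrow(a))
  pts <- sphere_points(n_points)
  out <- numeric(length(atom_idx))
  for (k in seq_along(atom_idx)) {
    i <- atom_idx[k]
    ri <- rad[i]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ri + rad)^2 & seq_len(nrow(a)) != i)
    if (length(nb) == 0) {
      out[k] <- 4 * pi * ri^2
      next
    }
    sp <- pts * ri
    sp <- sweep(sp, 2, xyz[i, ], `+`)
    covered <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
             (sp[, 3] - xyz[j, 3])^2
      covered <- covered | dj2 < rad[j]^2
      if (all(covered)) break
    }
    out[k] <- 4 * pi * ri^2 * mean(!covered)
  }
  out
}

#' Per-residue SASA, relative SASA and exposure category
#'
#' Relative SASA divides the residue's SASA by its theoretical maximum
#' (Gly-X-Gly reference). Exposure follows the three-state convention:
#' buried (< 0.17), exposed (> 0.43), partially exposed otherwise; the
#' boundary values themselves fall in the partially-exposed class.
#'
#' @inheritParams atom_sasa
#' @return data.frame with resi, sasa, rel_sasa, exposure
#'   (buried/partial/exposed; NA for ineligible residues).
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 1920) {
  per_atom <- atom_sasa(model, probe = probe, n_points = n_points)
  res <- model$residues
  sasa <- vapply(res$resi, function(ri) {
    sum(per_atom[model$atoms$resi == ri])
  }, numeric(1))
  rel <- ifelse(res$aa %in% AA1, sasa / MAX_SASA[res$aa], NA_real_)
  exposure <- ifelse(is.na(rel), NA_character_,
              ifelse(rel < 0.17, "buried",
              ifelse(rel > 0.43, "exposed", "partial")))
  data.frame(resi = res$resi, sasa = sasa, rel_sasa = rel,
             exposure = exposure, stringsAsFactors = FALSE)
}

#' SASA of one residue extracted in isolation
#' @keywords internal
isolated_residue_sasa <- function(model, resi, probe = 1.4, n_points = 1920) {
  ai <- residue_atom_idx(model, resi)
  sub <- model$atoms[ai, ]
  sub$resi <- 1L
  iso <- structure_model(sub, provenance = model$provenance)
  sum(atom_sasa(iso, probe = probe, n_points = n_points))
}
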