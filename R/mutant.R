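# Mutant model construction: side-chain replacement at the target position
# and seeded Monte-Carlo repacking of the 5 A neighbourhood. The backbone is
# never moved.

#' Monte-Carlo repacking configuration
#'
#' @param radius shell radius in Angstrom: residues whose closest heavy atom
#'   lies within this distance of the target may have their side chains
#'   repacked.
#' @param mc_steps number of Monte-Carlo steps.
#' @param temperatures reduced-temperature schedule; steps are divided evenly
#'   over the stages (geometric cooling by default).
#' @param chi_perturbation maximum chi-angle perturbation per move, degrees.
#' @param seed integer seed; identical seeds give bit-identical results.
#' @return object of class `repack_config`.
#' @export
repack_config <- function(radius = 5, mc_steps = 500,
                          temperatures = c(2, 0.5, 0.125),
                          chi_perturbation = 30, seed = 1) {
  stopifnot(radius > 0, mc_steps >= 0, length(temperatures) >= 1,
            all(temperatures > 0), chi_perturbation > 0)
  structure(list(radius = radius, mc_steps = mc_steps,
                 temperatures = temperatures,
                 chi_perturbation = chi_perturbation, seed = seed),
            class = "repack_config")
}

#' Replace the side chain at one position
#'
#' Strips the target residue's side-chain atoms and rebuilds the substitute
#' side chain from the internal-coordinate template at its default chi
#' angles. Backbone atoms of every residue, and all atoms of every other
#' residue, are bit-identical to the input.
#'
#' @param wt a [structure_model()].
#' @param chain,position chain id and author residue number of the target.
#' @param mut_aa one-letter code of the substitute residue type.
#' @return a [structure_model()] with mutant provenance.
#' @export
mutate_side_chain <- function(wt, chain, position, mut_aa) {
  mut_aa <- aa_normalize(mut_aa)
  if (is.na(mut_aa)) stop("mut_aa is not a standard amino acid")
  resi <- resolve_residue(wt, chain, position)
  res_row <- which(wt$residues$resi == resi)
  if (!wt$residues$eligible[res_row]) {
    stop("position ", chain, "/", position,
         " is ineligible (incomplete backbone or non-standard residue)")
  }
  wt_aa <- wt$residues$aa[res_row]
  if (identical(wt_aa, mut_aa)) {
    stop("mut_aa equals the wild-type residue type (", wt_aa, ")")
  }
  a <- wt$atoms
  ti <- residue_atom_idx(wt, resi)
  bb_names <- c("N", "CA", "C", "O")
  bb_rows <- ti[a$name[ti] %in% bb_names]
  bb <- backbone_xyz(wt, resi)
  sc <- build_side_chain(mut_aa, bb)
  keep_bb <- a[bb_rows, ]
  keep_bb$aa <- mut_aa
  if (nrow(sc) > 0) {
    elem <- element_of(rownames(sc))
    sc_df <- data.frame(name = rownames(sc), elem = elem,
                        chain = keep_bb$chain[1], resno = keep_bb$resno[1],
                        resi = resi, x = sc[, 1], y = sc[, 2], z = sc[, 3],
                        radius = unname(VDW_RADII[elem]), aa = mut_aa,
                        stringsAsFactors = FALSE)
  } else {
    sc_df <- keep_bb[0, ]
  }
  before <- a[seq_len(nrow(a)) < min(ti), ]
  after <- a[seq_len(nrow(a)) > max(ti), ]
  atoms <- rbind(before, keep_bb, sc_df, after)
  rownames(atoms) <- NULL
  structure_model(atoms,
                  provenance = list(type = "mutant", chain = chain,
                                    position = position, wt_aa = wt_aa,
                                    mut_aa = mut_aa,
                                    parent = wt$provenance))
}

#' @keywords internal
set_residue_sidechain_xyz <- function(atoms, resi, sc) {
  for (nm in rownames(sc)) {
    row <- which(atoms$resi == resi & atoms$name == nm)
    atoms$x[row] <- sc[nm, 1]
    atoms$y[row] <- sc[nm, 2]
    atoms$z[row] <- sc[nm, 3]
  }
  atoms
}

#' Monte-Carlo repacking of the mutation neighbourhood
#'
#' Side chains of residues whose minimum heavy-atom distance to the target
#' residue is within `config$radius` (shell membership fixed once, from the
#' input mutant model) are repacked by random chi-angle moves: one randomly
#' chosen movable residue per step, one chi perturbed uniformly within
#' +/- `chi_perturbation` degrees, Metropolis acceptance under the stage
#' temperature. The objective is the inter-residue nonbonded energy
#' ([system_energy()]). The lowest-energy state visited (including the
#' input) is returned, so the final energy never exceeds the initial one.
#' Backbone atoms and residues outside the shell are never touched.
#'
#' @param model a mutant [structure_model()] from [mutate_side_chain()].
#' @param chain,position chain id and author residue number of the target.
#' @param config a [repack_config()].
#' @return list with `model` (best state), `trace` (data.frame of step,
#'   energy, accepted), `initial_energy`, `final_energy`.
#' @export
repack_neighborhood <- function(model, chain, position,
                                config = repack_config()) {
  stopifnot(inherits(config, "repack_config"))
  resi <- resolve_residue(model, chain, position)
  dmin <- residue_min_dist(model, resi)
  res <- model$residues
  shell <- res$resi[dmin <= config$radius]
  movable <- shell[vapply(shell, function(ri) {
    row <- which(res$resi == ri)
    res$eligible[row] && n_template_chis(res$aa[row]) > 0
  }, logical(1))]
  e0 <- system_energy(model)
  empty_trace <- data.frame(step = integer(0), energy = numeric(0),
                            accepted = logical(0))
  if (config$mc_steps == 0 || length(movable) == 0) {
    return(list(model = model, trace = empty_trace,
                initial_energy = e0, final_energy = e0))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  atoms <- model$atoms
  charges <- atom_charges(model)
  # current chi state per movable residue, measured from the input model
  chis <- lapply(movable, function(ri) {
    aa <- res$aa[res$resi == ri]
    measure_chis(model, ri, aa)
  })
  names(chis) <- as.character(movable)
  cur_model <- model
  cur_e <- e0
  best_atoms <- atoms
  best_e <- e0
  stages <- rep(config$temperatures,
                each = ceiling(config$mc_steps / length(config$temperatures)))
  trace <- data.frame(step = seq_len(config$mc_steps), energy = NA_real_,
                      accepted = FALSE)
  for (step in seq_len(config$mc_steps)) {
    temp <- stages[step]
    ri <- movable[sample.int(length(movable), 1)]
    key <- as.character(ri)
    aa <- res$aa[res$resi == ri]
    k <- sample.int(length(chis[[key]]), 1)
    delta_chi <- stats::runif(1, -config$chi_perturbation,
                              config$chi_perturbation)
    new_chis <- chis[[key]]
    new_chis[k] <- new_chis[k] + delta_chi
    bb <- backbone_xyz(cur_model, ri)
    sc <- build_side_chain(aa, bb, chis = new_chis)
    e_old <- sum(residue_env_pair_energy(cur_model, ri, charges = charges))
    cand_atoms <- set_residue_sidechain_xyz(cur_model$atoms, ri, sc)
    cand_model <- cur_model
    cand_model$atoms <- cand_atoms
    e_new <- sum(residue_env_pair_energy(cand_model, ri, charges = charges))
    delta <- e_new - e_old
    accept <- delta < 0 || stats::runif(1) < exp(-delta / temp)
    if (accept) {
      cur_model <- cand_model
      cur_e <- cur_e + delta
      chis[[key]] <- new_chis
      if (cur_e < best_e) {
        best_e <- cur_e
        best_atoms <- cand_atoms
      }
    }
    trace$energy[step] <- cur_e
    trace$accepted[step] <- accept
  }
  out <- model
  out$atoms <- best_atoms
  out$provenance$repacked <- list(seed = config$seed,
                                  mc_steps = config$mc_steps,
                                  radius = config$radius)
  list(model = out, trace = trace, initial_energy = e0,
       final_energy = best_e)
}

#' Measure the current chi angles of a residue from its coordinates
#' @keywords internal
measure_chis <- function(model, resi, aa) {
  nchi <- n_template_chis(aa)
  if (nchi == 0) return(numeric(0))
  tpl <- SIDECHAIN_TEMPLATES[[aa]]
  a <- model$atoms
  ti <- which(a$resi == resi)
  getp <- function(nm) {
    j <- ti[a$name[ti] == nm][1]
    c(a$x[j], a$y[j], a$z[j])
  }
  out <- numeric(nchi)
  for (k in seq_len(nchi)) {
    row <- tpl[tpl$chi == k & tpl$offset == 0, ][1, ]
    out[k] <- dihedral_angle(getp(row$a), getp(row$b), getp(row$c),
                             getp(row$name))
  }
  out
}

#' Build the repacked mutant for one mutation record
#'
#' Convenience wrapper: [mutate_side_chain()] followed by
#' [repack_neighborhood()].
#'
#' @param wt wild-type [structure_model()].
#' @param chain,position,mut_aa mutation definition.
#' @param config a [repack_config()].
#' @return the repacked mutant [structure_model()].
#' @export
build_mutant <- function(wt, chain, position, mut_aa,
                         config = repack_config()) {
  m <- mutate_side_chain(wt, chain, position, mut_aa)
  repack_neighborhood(m, chain, position, config)$model
}
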