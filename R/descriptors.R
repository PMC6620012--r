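# The 96-component mutation descriptor: 28 sequence-based, 44 structure-based
# and 24 energy-based features, computed from the wild-type model and the
# repacked mutant model.

#' @keywords internal
LAYOUT_VERSION <- "tmvarboost-96-v1"

#' Descriptor layout
#'
#' The fixed, versioned layout of the 96 features: 12 AAindex properties of
#' the wild-type residue, 12 of the mutant, 4 substitution scores (BLOSUM62,
#' membrane-context, directional forward/reverse); then 22 structural
#' features per model (6-state secondary-structure one-hot, SASA, relative
#' SASA, 3-state exposure one-hot, contact area, side-chain volume, H-bond
#' count, molecular surface area, packing density, neighbour count and the
#' five contact-category counts); then 12 energy features per model (six
#' target-residue terms and six neighbourhood-normalized terms).
#'
#' @return list with `version`, `names` (96 feature names) and `blocks`
#'   (named index vectors seq / struct / energy).
#' @export
descriptor_layout <- function() {
  props <- rownames(AAINDEX_TABLE)
  seq_names <- c(paste0("seq.wt.", props), paste0("seq.mut.", props),
                 "seq.sub.blosum62", "seq.sub.phat",
                 "seq.sub.slim_fwd", "seq.sub.slim_rev")
  per_model <- c("ss_H", "ss_G", "ss_I", "ss_E", "ss_B", "ss_coil",
                 "sasa", "rel_sasa",
                 "exp_buried", "exp_partial", "exp_exposed",
                 "total_contact_area", "side_chain_volume", "n_hbonds",
                 "molecular_surface_area", "packing_density",
                 "n_neighbors_5A", "n_polar", "n_charged", "n_aromatic",
                 "n_aliphatic", "n_special")
  struct_names <- c(paste0("struct.wt.", per_model),
                    paste0("struct.mut.", per_model))
  eterms <- c("electrostatic", "vdw", "hbond", "entropic", "solvation",
              "total")
  per_model_e <- c(paste0("tgt_", eterms), paste0("nbr_", eterms))
  energy_names <- c(paste0("energy.wt.", per_model_e),
                    paste0("energy.mut.", per_model_e))
  nm <- c(seq_names, struct_names, energy_names)
  list(version = LAYOUT_VERSION, names = nm,
       blocks = list(seq = seq_along(seq_names),
                     struct = length(seq_names) + seq_along(struct_names),
                     energy = length(seq_names) + length(struct_names) +
                              seq_along(energy_names)))
}

#' Sequence-based descriptor block (28 components)
#'
#' 12 physico-chemical properties of the wild-type residue, the same 12 of
#' the mutant residue, and the four substitution scores.
#'
#' @param wt_aa,mut_aa one-letter codes, distinct standard amino acids.
#' @return named numeric vector of length 28.
#' @export
sequence_block <- function(wt_aa, mut_aa) {
  wt_aa <- aa_normalize(wt_aa); mut_aa <- aa_normalize(mut_aa)
  if (is.na(wt_aa) || is.na(mut_aa)) {
    stop("sequence_block requires standard amino acids")
  }
  if (wt_aa == mut_aa) stop("wt_aa and mut_aa must differ")
  props <- rownames(AAINDEX_TABLE)
  v <- c(AAINDEX_TABLE[, wt_aa], AAINDEX_TABLE[, mut_aa],
         BLOSUM62_TABLE[wt_aa, mut_aa], PHAT_TABLE[wt_aa, mut_aa],
         SLIM_FWD_TABLE[wt_aa, mut_aa], SLIM_REV_TABLE[wt_aa, mut_aa])
  names(v) <- c(paste0("seq.wt.", props), paste0("seq.mut.", props),
                "seq.sub.blosum62", "seq.sub.phat",
                "seq.sub.slim_fwd", "seq.sub.slim_rev")
  v
}

#' Precompute the per-model quantities shared by the structural and energy
#' blocks (per-atom SASA, residue SASA table, hydrogen bonds, secondary
#' structure).
#' @keywords internal
model_context <- function(model) {
  per_atom <- atom_sasa(model)
  res <- model$residues
  sasa <- vapply(res$resi, function(ri) {
    sum(per_atom[model$atoms$resi == ri])
  }, numeric(1))
  rel <- ifelse(res$aa %in% AA1, sasa / MAX_SASA[res$aa], NA_real_)
  exposure <- ifelse(is.na(rel), NA_character_,
              ifelse(rel < 0.17, "buried",
              ifelse(rel > 0.43, "exposed", "partial")))
  list(per_atom_sasa = per_atom,
       sasa_table = data.frame(resi = res$resi, sasa = sasa, rel_sasa = rel,
                               exposure = exposure, stringsAsFactors = FALSE),
       hbonds = hydrogen_bonds(model),
       ss = assign_secondary_structure(model))
}

#' @keywords internal
structure_half <- function(model, chain, position, ctx) {
  resi <- resolve_residue(model, chain, position)
  row <- which(model$residues$resi == resi)
  ss1 <- ss_onehot(ctx$ss[row])
  st <- ctx$sasa_table[ctx$sasa_table$resi == resi, ]
  expo <- c(exp_buried = as.numeric(st$exposure == "buried"),
            exp_partial = as.numeric(st$exposure == "partial"),
            exp_exposed = as.numeric(st$exposure == "exposed"))
  cp <- contact_profile(model, chain, position,
                        sasa_table = ctx$sasa_table, hbonds = ctx$hbonds)
  c(ss1, sasa = st$sasa, rel_sasa = st$rel_sasa, expo,
    total_contact_area = cp$total_contact_area,
    side_chain_volume = cp$side_chain_volume,
    n_hbonds = cp$n_hbonds,
    molecular_surface_area = cp$molecular_surface_area,
    packing_density = cp$packing_density,
    n_neighbors_5A = cp$n_neighbors_5A,
    n_polar = cp$n_polar, n_charged = cp$n_charged,
    n_aromatic = cp$n_aromatic, n_aliphatic = cp$n_aliphatic,
    n_special = cp$n_special)
}

#' @keywords internal
check_shared_backbone <- function(wt, mut) {
  bb <- c("N", "CA", "C", "O")
  w <- wt$atoms[wt$atoms$name %in% bb, c("resi", "name", "x", "y", "z")]
  m <- mut$atoms[mut$atoms$name %in% bb, c("resi", "name", "x", "y", "z")]
  if (nrow(w) != nrow(m) ||
      !isTRUE(all.equal(w[order(w$resi, w$name), ],
                        m[order(m$resi, m$name), ],
                        check.attributes = FALSE, tolerance = 0))) {
    stop("wild-type and mutant models do not share a backbone")
  }
  invisible(TRUE)
}

#' Structure-based descriptor block (44 components)
#'
#' 22 structural features per model, wild-type half then mutant half.
#'
#' @param wt,mut wild-type and mutant [structure_model()]s sharing a
#'   backbone.
#' @param chain,position the mutation site.
#' @param wt_ctx,mut_ctx optional precomputed [model_context()]s.
#' @return named numeric vector of length 44.
#' @export
structure_block <- function(wt, mut, chain, position,
                            wt_ctx = NULL, mut_ctx = NULL) {
  check_shared_backbone(wt, mut)
  if (is.null(wt_ctx)) wt_ctx <- model_context(wt)
  if (is.null(mut_ctx)) mut_ctx <- model_context(mut)
  hw <- structure_half(wt, chain, position, wt_ctx)
  hm <- structure_half(mut, chain, position, mut_ctx)
  v <- c(hw, hm)
  names(v) <- c(paste0("struct.wt.", names(hw)),
                paste0("struct.mut.", names(hm)))
  v
}

#' Energy-based descriptor block (24 components)
#'
#' 12 energy features per model (six target-residue terms, six
#' neighbourhood-normalized terms), wild-type half then mutant half.
#'
#' @inheritParams structure_block
#' @return named numeric vector of length 24.
#' @export
energy_block <- function(wt, mut, chain, position,
                         wt_ctx = NULL, mut_ctx = NULL) {
  check_shared_backbone(wt, mut)
  if (is.null(wt_ctx)) wt_ctx <- model_context(wt)
  if (is.null(mut_ctx)) mut_ctx <- model_context(mut)
  half <- function(model, ctx) {
    ep <- energy_profile(model, chain, position,
                         per_atom_sasa = ctx$per_atom_sasa,
                         hbonds = ctx$hbonds)
    c(stats::setNames(ep$target, paste0("tgt_", names(ep$target))),
      stats::setNames(ep$neighborhood, paste0("nbr_", names(ep$neighborhood))))
  }
  hw <- half(wt, wt_ctx)
  hm <- half(mut, mut_ctx)
  v <- c(hw, hm)
  names(v) <- c(paste0("energy.wt.", names(hw)),
                paste0("energy.mut.", names(hm)))
  v
}

#' Full 96-component descriptor for one mutation
#'
#' Builds the repacked mutant model and concatenates the sequence (28),
#' structure (44) and energy (24) blocks. Deterministic for a fixed repack
#' seed.
#'
#' @param record one-row mutation record (see [read_mutation_table()]).
#' @param wt wild-type [structure_model()].
#' @param config a [repack_config()].
#' @param wt_ctx optional precomputed [model_context()] of `wt` (reused
#'   across records of the same protein).
#' @return named numeric vector of length 96 with attribute
#'   `layout_version`.
#' @export
full_descriptor <- function(record, wt, config = repack_config(),
                            wt_ctx = NULL) {
  stopifnot(nrow(record) == 1)
  resi <- resolve_residue(wt, record$chain, record$position)
  row <- which(wt$residues$resi == resi)
  if (!wt$residues$eligible[row]) {
    stop("record position ", record$position, " is ineligible in the model")
  }
  if (!identical(wt$residues$aa[row], record$wt_aa)) {
    stop("record wt_aa (", record$wt_aa, ") does not match the model (",
         wt$residues$aa[row], ") at position ", record$position)
  }
  mut <- build_mutant(wt, record$chain, record$position, record$mut_aa,
                      config)
  if (is.null(wt_ctx)) wt_ctx <- model_context(wt)
  mut_ctx <- model_context(mut)
  v <- c(sequence_block(record$wt_aa, record$mut_aa),
         structure_block(wt, mut, record$chain, record$position,
                         wt_ctx, mut_ctx),
         energy_block(wt, mut, record$chain, record$position,
                      wt_ctx, mut_ctx))
  layout <- descriptor_layout()
  stopifnot(identical(names(v), layout$names))
  attr(v, "layout_version") <- layout$version
  v
}

#' Write a descriptor matrix to TSV
#'
#' Identity columns first, then the 96 named feature columns. The first line
#' records the layout version; [read_descriptor_matrix()] refuses files whose
#' version or feature names do not match the current layout.
#'
#' @param vectors matrix (rows = mutations) or list of descriptor vectors.
#' @param records mutation records, one row per vector.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_descriptor_matrix <- function(vectors, records, path) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    vectors <- do.call(rbind, vectors)
  }
  layout <- descriptor_layout()
  stopifnot(ncol(vectors) == length(layout$names),
            nrow(vectors) == nrow(records))
  colnames(vectors) <- layout$names
  df <- cbind(records[, MUTATION_COLUMNS], as.data.frame(vectors))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#layout=", layout$version), con)
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor matrix written by [write_descriptor_matrix()]
#'
#' @param path TSV path.
#' @return list with `records` (identity columns) and `X` (numeric matrix of
#'   96 feature columns).
#' @export
read_descriptor_matrix <- function(path) {
  first <- readLines(path, n = 1)
  layout <- descriptor_layout()
  version <- sub("^#layout=", "", first)
  if (!startsWith(first, "#layout=") || version != layout$version) {
    stop("descriptor layout version mismatch: file has '", first,
         "', package expects '", layout$version, "'")
  }
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(layout$names %in% names(df))) {
    stop("descriptor file is missing feature column(s): ",
         paste(utils::head(setdiff(layout$names, names(df)), 5),
               collapse = ", "))
  }
  X <- as.matrix(df[, layout$names])
  records <- df[, intersect(MUTATION_COLUMNS, names(df))]
  records$label <- suppressWarnings(as.numeric(records$label))
  list(records = records, X = X)
}
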