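# All-atom structure container and PDB I/O.

#' Construct a structure model
#'
#' The all-atom container used throughout the package: an atom table plus a
#' derived residue table. Residues lacking any of the four backbone heavy
#' atoms (N, CA, C, O), or of non-standard type, are flagged ineligible and
#' are excluded from descriptor computation (their atoms still contribute to
#' the environment).
#'
#' @param atoms data.frame with columns name, elem, chain, resno (author
#'   residue number), resi (sequential residue index), x, y, z, radius.
#' @param provenance list describing the model origin (wild-type file or
#'   mutation applied).
#' @return object of class `structure_model` with elements `atoms`,
#'   `residues` and `provenance`.
#' @export
structure_model <- function(atoms, provenance = list(type = "wild_type")) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "elem", "chain", "resno", "resi",
                  "x", "y", "z", "radius") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  idx <- split(seq_len(nrow(atoms)), atoms$resi)
  resi_ids <- as.integer(names(idx))
  ord <- order(match(resi_ids, unique(atoms$resi)))
  first <- vapply(idx, `[`, integer(1), 1)
  residues <- data.frame(
    resi = resi_ids,
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    aa = if ("aa" %in% names(atoms)) atoms$aa[first] else NA_character_,
    stringsAsFactors = FALSE)
  residues <- residues[order(match(residues$resi, unique(atoms$resi))), ]
  bb_ok <- vapply(seq_len(nrow(residues)), function(i) {
    nm <- atoms$name[idx[[as.character(residues$resi[i])]]]
    all(c("N", "CA", "C", "O") %in% nm)
  }, logical(1))
  residues$eligible <- bb_ok & !is.na(residues$aa) & residues$aa %in% AA1
  rownames(residues) <- NULL
  structure(list(atoms = atoms, residues = residues,
                 provenance = provenance),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$residues), "residues,",
      nrow(x$atoms), "atoms;",
      sum(x$residues$eligible), "eligible;",
      "provenance:", x$provenance$type, "\n")
  invisible(x)
}

#' @keywords internal
atom_xyz <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' @keywords internal
residue_atom_idx <- function(model, resi) {
  which(model$atoms$resi == resi)
}

#' Find the sequential residue index for (chain, author number)
#' @keywords internal
resolve_residue <- function(model, chain, position) {
  hit <- which(model$residues$chain == chain & model$residues$resno == position)
  if (length(hit) != 1) {
    stop("residue ", chain, "/", position, " not found in model")
  }
  model$residues$resi[hit]
}

#' @keywords internal
backbone_xyz <- function(model, resi) {
  ai <- residue_atom_idx(model, resi)
  a <- model$atoms[ai, ]
  out <- list()
  for (nm in c("N", "CA", "C", "O")) {
    j <- which(a$name == nm)[1]
    out[[nm]] <- if (is.na(j)) NULL else c(a$x[j], a$y[j], a$z[j])
  }
  out
}

#' Read a protein chain from a PDB file
#'
#' Parses with bio3d, keeps standard protein ATOM records of the requested
#' chain, drops waters/heteroatoms, and for alternate locations keeps the
#' highest-occupancy copy. Only the first model of multi-model files is used.
#' Residues with incomplete backbones or non-standard types are retained but
#' flagged ineligible.
#'
#' @param path PDB file path.
#' @param chain single chain identifier.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, chain) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !is.na(at$chain) & at$chain == chain, ]
  if (nrow(at) == 0) stop("chain ", chain, " not present in ", path)
  at <- at[!at$resid %in% c("HOH", "WAT"), ]
  # alternate locations: within (resno, insert, name) keep highest occupancy
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ii) {
    ii[which.max(occ[ii])]
  }), use.names = FALSE)
  at <- at[sort(keep), ]
  at <- at[element_of(at$elety) != "H", ]
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  resi <- as.integer(factor(rkey, levels = unique(rkey)))
  aa <- aa_normalize(at$resid)
  elem <- element_of(at$elety)
  radius <- unname(VDW_RADII[elem])
  radius[is.na(radius)] <- 1.70
  atoms <- data.frame(name = at$elety, elem = elem, chain = at$chain,
                      resno = at$resno, resi = resi,
                      x = at$x, y = at$y, z = at$z,
                      radius = radius, aa = aa,
                      stringsAsFactors = FALSE)
  structure_model(atoms, provenance = list(type = "wild_type",
                                           source = basename(path),
                                           chain = chain))
}

#' Write a structure model to a PDB file
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  resid3 <- unname(AA3[a$aa])
  resid3[is.na(resid3)] <- "UNK"
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = resid3, chain = a$chain,
                   elety = a$name, o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}
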