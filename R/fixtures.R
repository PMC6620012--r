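# Synthetic fixtures: ideal-geometry helices, planted-label feature
# datasets and toy mutation sets. Everything is deterministic under a fixed
# seed so the whole package is testable without any external data.

# Ideal backbone geometry (A / degrees).
#' @keywords internal
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8, omega = 180)

#' Build an ideal polypeptide (helix by default)
#'
#' Constructs an all-atom model of a single chain with every residue at the
#' same (phi, psi), standard bond geometry, and side chains placed from the
#' internal-coordinate templates at their default chi angles. The defaults
#' (-57, -47) give an ideal alpha-helix, the canonical secondary structure of
#' transmembrane segments.
#'
#' @param sequence one-letter amino-acid string (length >= 1).
#' @param phi,psi backbone dihedrals in degrees.
#' @param chain chain identifier for the generated model.
#' @return a [structure_model()] with one residue per sequence letter.
#' @examples
#' h <- build_helix("AAAAAAAAAAAA")
#' h$residues$aa
#' @export
build_helix <- function(sequence, phi = -57, psi = -47, chain = "A") {
  aas <- strsplit(sequence, "")[[1]]
  if (length(aas) < 1) stop("sequence must have length >= 1")
  bad <- setdiff(aas, AA1)
  if (length(bad) > 0) stop("invalid residue letter(s): ",
                            paste(unique(bad), collapse = ", "))
  g <- BB_GEOM
  n_res <- length(aas)
  bb <- vector("list", n_res)  # per residue: list(N, CA, C, O)
  # residue 1: place N, CA, C in the xy-plane
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  C1 <- CA1 + g$ca_c * c(-cos(th), sin(th), 0)
  bb[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      prev <- bb[[i - 1]]
      Ni <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n, psi)
      CAi <- place_atom(prev$CA, prev$C, Ni, g$n_ca, g$ang_c_n_ca, g$omega)
      Ci <- place_atom(prev$C, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi)
      bb[[i]] <- list(N = Ni, CA = CAi, C = Ci)
    }
    # carbonyl O: trans to the next N, i.e. dihedral N-CA-C-O = psi + 180
    bb[[i]]$O <- place_atom(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C,
                            g$c_o, g$ang_ca_c_o, psi + 180)
  }
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    bbi <- bb[[i]]
    sc <- build_side_chain(aas[i], bbi)
    nm <- c("N", "CA", "C", "O", rownames(sc))
    xyz <- rbind(do.call(rbind, bbi[c("N", "CA", "C", "O")]), sc)
    elem <- element_of(nm)
    rows[[i]] <- data.frame(name = nm, elem = elem, chain = chain,
                            resno = i, resi = i,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            radius = unname(VDW_RADII[elem]),
                            aa = aas[i], stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  structure_model(atoms, provenance = list(type = "wild_type",
                                           source = "build_helix",
                                           phi = phi, psi = psi))
}

#' Generate a planted-rule classification dataset
#'
#' Standard-normal features; the label is the sign of a linear score over the
#' informative features, with the threshold set by quantile so the requested
#' fraction of +1 labels is achieved, then flipped at the label-noise rate.
#' Emulates the geometry of the mutation-descriptor problem (many weakly
#' structured columns, a few informative ones, class imbalance) without any
#' structural input.
#'
#' @param n number of samples.
#' @param d number of features.
#' @param informative integer indices (1-based) of the informative features.
#' @param effect_size coefficient magnitude on informative features.
#' @param noise_rate label-flip probability in [0, 0.5).
#' @param class_balance target fraction of +1 labels.
#' @param seed integer seed.
#' @return list with `X` (n x d matrix), `y` (+1/-1), `informative`.
#' @export
planted_dataset <- function(n, d, informative = 1:6, effect_size = 1,
                            noise_rate = 0, class_balance = 0.5,
                            seed = 1) {
  stopifnot(all(informative >= 1), all(informative <= d),
            noise_rate >= 0, noise_rate < 0.5,
            class_balance > 0, class_balance < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  X <- matrix(stats::rnorm(n * d), n, d)
  colnames(X) <- paste0("f", seq_len(d))
  beta <- rep(effect_size, length(informative))
  score <- X[, informative, drop = FALSE] %*% beta
  thr <- stats::quantile(score, probs = 1 - class_balance)
  y <- ifelse(score > thr, 1, -1)
  if (noise_rate > 0) {
    flip <- stats::runif(n) < noise_rate
    y[flip] <- -y[flip]
  }
  list(X = X, y = as.numeric(y), informative = informative)
}

#' Random mutation records on a fixture structure
#'
#' Draws distinct (position, substitute) pairs among the eligible residues of
#' a model; records carry region code "M" and no label.
#'
#' @param model a [structure_model()].
#' @param n_mut number of records to draw.
#' @param seed integer seed.
#' @return data.frame of mutation records (see [read_mutation_table()]).
#' @export
toy_mutation_set <- function(model, n_mut, seed = 1) {
  el <- model$residues[model$residues$eligible, ]
  pool <- do.call(rbind, lapply(seq_len(nrow(el)), function(i) {
    data.frame(position = el$resno[i], chain = el$chain[i],
               wt_aa = el$aa[i], mut_aa = setdiff(AA1, el$aa[i]),
               stringsAsFactors = FALSE)
  }))
  if (n_mut > nrow(pool)) {
    stop("n_mut exceeds the ", nrow(pool), " possible substitutions")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- sample(nrow(pool), n_mut)
  data.frame(protein_id = "FIXTURE", pdb_id = "XXXX",
             chain = pool$chain[pick], position = pool$position[pick],
             wt_aa = pool$wt_aa[pick], mut_aa = pool$mut_aa[pick],
             region = "M", label = NA_real_, stringsAsFactors = FALSE)
}

# Save/restore the global RNG state so fixture generators are seeded without
# disturbing the caller's stream.
#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
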