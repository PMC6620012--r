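# Shared fixtures, all generated in code. Structural fixtures are cached per
# session because helix construction is deterministic.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 15-residue membrane-like helix used by the descriptor and scan tests
fix_helix15 <- function() cached("helix15", build_helix("LLALAVLAILVALLA"))

# 12-residue polyalanine helix
fix_helix12 <- function() cached("helix12", build_helix("AAAAAAAAAAAA"))

fast_repack <- function(seed = 1) repack_config(mc_steps = 50, seed = seed)

# hand-built model: one target residue at the origin plus neighbour residues
# of chosen types at chosen center distances (backbone-only residues)
make_contact_toy <- function(neighbor_aas, dists = rep(3.5,
                             length(neighbor_aas))) {
  bb_local <- rbind(N = c(0, 1.4, 0), CA = c(0, 0, 0),
                    C = c(1.3, -0.6, 0), O = c(1.4, -1.8, 0))
  one_res <- function(resi, aa, center) {
    xyz <- sweep(bb_local, 2, center, `+`)
    data.frame(name = rownames(bb_local), elem = c("N", "C", "C", "O"),
               chain = "A", resno = resi, resi = resi,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               radius = c(1.55, 1.7, 1.7, 1.52), aa = aa,
               stringsAsFactors = FALSE)
  }
  rows <- list(one_res(1, "A", c(0, 0, 0)))
  for (i in seq_along(neighbor_aas)) {
    ang <- 2 * pi * i / (length(neighbor_aas) + 1)
    center <- dists[i] * c(cos(ang), sin(ang), 0.1 * i)
    rows[[i + 1]] <- one_res(i + 1, neighbor_aas[i], center)
  }
  structure_model(do.call(rbind, rows))
}

# independent brute-force neighbour count: double loop over residue pairs
brute_force_neighbors <- function(model, resi, radius = 5) {
  a <- model$atoms
  ti <- which(a$resi == resi)
  out <- integer(0)
  for (rj in setdiff(unique(a$resi), resi)) {
    oj <- which(a$resi == rj)
    found <- FALSE
    for (i in ti) for (j in oj) {
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
      if (d <= radius) found <- TRUE
    }
    if (found) out <- c(out, rj)
  }
  out
}

# grouped synthetic dataset for leave-one-protein-out tests
make_grouped_dataset <- function(n_proteins = 4, per_protein = 12, d = 8,
                                 seed = 11) {
  ds <- planted_dataset(n_proteins * per_protein, d, informative = 1:2,
                        seed = seed)
  list(X = ds$X, y = ds$y,
       protein = rep(paste0("PROT", seq_len(n_proteins)),
                     each = per_protein))
}

# standard side-chain heavy-atom counts (chemical composition)
SC_HEAVY <- c(A = 1, R = 7, N = 4, D = 4, C = 2, Q = 5, E = 5, G = 0,
              H = 6, I = 4, L = 4, K = 5, M = 4, F = 7, P = 3, S = 2,
              T = 3, W = 10, Y = 8, V = 3)
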