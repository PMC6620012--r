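# Kabsch-Sander style secondary-structure assignment from backbone geometry.
# Classes: H (alpha-helix), G (3/10-helix), I (pi-helix), E (beta-strand),
# B (beta-bridge), C (coil; the DSSP turn/bend states are merged into coil).

#' @keywords internal
SS_CLASSES <- c("H", "G", "I", "E", "B", "C")

#' Assign per-residue secondary structure
#'
#' Backbone amide hydrogens are placed 1 A from N along the preceding
#' peptide's C=O direction; a backbone hydrogen bond is called when the
#' Kabsch-Sander electrostatic energy is below -0.5 kcal/mol. Helices are
#' assigned from consecutive 3-/4-/5-turns, strands and bridges from the
#' parallel/antiparallel bridge patterns; everything else is coil.
#'
#' @param model a [structure_model()].
#' @return character vector of classes (one of H,G,I,E,B,C) per residue,
#'   in residue order.
#' @export
assign_secondary_structure <- function(model) {
  res <- model$residues
  n <- nrow(res)
  if (n < 2) return(rep("C", n))
  bb <- lapply(res$resi, function(ri) backbone_xyz(model, ri))
  ok <- vapply(bb, function(b) !any(vapply(b[c("N", "CA", "C", "O")],
                                           is.null, logical(1))), logical(1))
  # chain breaks: consecutive residues with peptide C-N distance > 2.5 A
  bonded <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    if (ok[i] && ok[i + 1]) {
      bonded[i] <- vnorm(bb[[i + 1]]$N - bb[[i]]$C) < 2.5
    }
  }
  # amide H of residue i from the preceding carbonyl
  hpos <- vector("list", n)
  for (i in 2:n) {
    if (ok[i] && ok[i - 1] && bonded[i - 1]) {
      co <- bb[[i - 1]]$C - bb[[i - 1]]$O
      hpos[[i]] <- bb[[i]]$N + vunit(co)
    }
  }
  # hb[i, j]: CO of residue i accepts the NH of residue j
  q1q2f <- 0.084 * 332
  hb <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    if (is.null(hpos[[j]]) || res$aa[j] %in% "P") next
    Nj <- bb[[j]]$N; Hj <- hpos[[j]]
    for (i in seq_len(n)) {
      if (abs(i - j) < 2 || !ok[i]) next
      Ci <- bb[[i]]$C; Oi <- bb[[i]]$O
      r_on <- vnorm(Oi - Nj)
      if (r_on > 5.2) next
      e <- q1q2f * (1 / r_on + 1 / vnorm(Ci - Hj) -
                    1 / vnorm(Oi - Hj) - 1 / vnorm(Ci - Nj))
      hb[i, j] <- e < -0.5
    }
  }
  turn <- function(k) {
    t <- rep(FALSE, n)
    for (i in seq_len(n - k)) t[i] <- hb[i, i + k]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  ss <- rep("C", n)
  mark <- function(ss, t, k, code) {
    for (i in seq_len(max(0, n - k - 1))) {
      if (t[i] && t[i + 1]) {
        span <- (i + 1):(i + k)
        free <- ss[span] == "C"
        ss[span][free] <- code
      }
    }
    ss
  }
  ss <- mark(ss, t4, 4, "H")
  # bridges
  para <- function(i, j) (i > 1 && j < n && hb[i - 1, j] && hb[j, i + 1]) ||
                         (j > 1 && i < n && hb[j - 1, i] && hb[i, j + 1])
  anti <- function(i, j) (hb[i, j] && hb[j, i]) ||
                         (i > 1 && j < n && i < n && j > 1 &&
                          hb[i - 1, j + 1] && hb[j - 1, i + 1])
  bridge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) >= 3 && (para(i, j) || anti(i, j))) bridge[i, j] <- TRUE
  }
  is_bridge <- apply(bridge, 1, any)
  for (i in which(is_bridge)) {
    if (ss[i] != "C") next
    partners <- which(bridge[i, ])
    ladder <- any(vapply(partners, function(j) {
      (i < n && any(bridge[i + 1, max(1, j - 1):min(n, j + 1)])) ||
      (i > 1 && any(bridge[i - 1, max(1, j - 1):min(n, j + 1)]))
    }, logical(1)))
    ss[i] <- if (ladder) "E" else "B"
  }
  ss <- mark(ss, t3, 3, "G")
  ss <- mark(ss, t5, 5, "I")
  ss
}

#' One-hot encoding of a secondary-structure class
#' @param class one of H, G, I, E, B, C.
#' @return named numeric vector of length 6 summing to 1.
#' @keywords internal
ss_onehot <- function(class) {
  v <- as.numeric(SS_CLASSES == class)
  names(v) <- c("ss_H", "ss_G", "ss_I", "ss_E", "ss_B", "ss_coil")
  v
}
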