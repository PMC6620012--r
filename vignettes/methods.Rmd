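---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmvarboost)
```

# The problem

Point mutations in the transmembrane segments of a protein sit in a lipid
environment where the usual sequence-conservation signals are weak and the
structural context — burial, packing, the energetic cost of a substitution —
carries most of the information about pathogenicity. `tmvarboost` models a
mutation as the pair (wild-type structure, repacked mutant structure) and
learns a binary classifier (+1 disease-associated, −1 benign) on a
96-component descriptor.

This vignette records the package's own design decisions: the mutant
builder, the descriptor layout, the native energy model, the learner and
the selection protocols, with the defaults and the reasoning behind them.

# Mutant model construction

`mutate_side_chain()` strips the target side chain and rebuilds the
substitute from an idealized internal-coordinate template (standard bond
lengths/angles, default χ angles; NeRF placement). The backbone — all four
heavy atoms N, CA, C, O at every position — is never touched, and the
contract is bit-exact, not approximate.

`repack_neighborhood()` then relaxes the local strain:

* **Shell.** Residues whose minimum heavy-atom distance to the target is
  within `radius` (default 5 Å). Membership is computed once, from the
  post-replacement mutant: the mutant side chain is the source of the
  strain, so the mutant geometry defines who may respond.
* **Moves.** One uniformly chosen movable residue per step, one χ angle
  perturbed uniformly within ±`chi_perturbation` (default 30°). Glycine,
  alanine and proline have no rotatable χ in the template and never move.
* **Objective.** The inter-residue nonbonded energy (`system_energy()`):
  Coulomb with ε = 4r plus Lennard-Jones 6-12. Hydrogen-bond, solvation
  and entropic terms are left out of the Monte-Carlo objective — they are
  descriptor-level summaries, and the pair energy is what diverges when a
  bulky side chain clashes.
* **Acceptance.** Metropolis at a 3-stage geometric temperature schedule
  (2, 0.5, 0.125 reduced units over `mc_steps` = 500 by default), with
  best-so-far retention: the returned model is the lowest-energy state
  visited, so the final energy never exceeds the initial one.
* **Determinism.** All randomness flows from `seed`; identical seeds give
  bit-identical coordinates.

The step count, schedule and move set are the package's own choices: they
satisfy the contracts that matter downstream (backbone immobility, 5 Å
locality, monotone best-so-far energy) at desk-scale cost. No attempt is
made to reproduce the conformations of any particular commercial sampler;
the descriptor consumes coarse summaries (SASA, contacts, energies) that
are robust to the exact repacked geometry.

# Descriptor layout (96 = 28 + 44 + 24)

The layout is versioned (`tmvarboost-96-v1`); files carry the version and
readers refuse mismatches.

**Sequence (28).** Twelve AAindex properties for wild-type and mutant
residues (24), then BLOSUM62, a membrane-context substitution score and a
directional (asymmetric) pair. The membrane-context and directional tables
are documented synthetic stand-ins constructed from BLOSUM62: a symmetric
hydrophobic-context adjustment (+1 when both residues are strongly
hydrophobic, −1 across the hydrophobic/polar divide), and a directionality
term that rewards substitution toward residue types more common in
membrane proteins. They preserve the real tables' contracts (integer
20×20; symmetric context table; `slim_fwd[a,b] == slim_rev[b,a]`) and are
clearly labelled synthetic in the constants documentation.

**Structure (22 per model × 2).** Secondary structure is assigned by a
Kabsch–Sander style criterion: amide hydrogens are placed from the
preceding carbonyl, and a backbone H-bond is called when the electrostatic
energy falls below −0.5 kcal/mol; helices come from consecutive 3-/4-/5-
turns, strands and bridges from the parallel/antiparallel patterns; the
DSSP turn and bend states are merged into coil. SASA is Shrake–Rupley with
probe 1.4 Å and 1920 deterministic golden-spiral points per atom (doubling
the density moves per-residue values by < 2 % on the test fixtures).
Relative SASA divides by theoretical Gly-X-Gly maxima; the three-state
exposure uses strict thresholds 0.17/0.43, with boundary values assigned
to "partially exposed" (the published inequalities are strict on both
sides, leaving the boundaries undefined; a deterministic rule is needed).
Contact area is the SASA the residue loses to its environment (isolated
minus in-context); molecular surface area is the exposed van der Waals
surface (probe 0); packing density divides it by SASA floored at 0.1 Å² so
fully buried residues stay finite. The published component enumeration
totals 40 when duplicated per model; molecular surface area and the 5 Å
neighbour count are carried per model to reach the printed 44 — the layout
is declared and versioned precisely because the original composition is
not recoverable.

**Energy (12 per model × 2).** Six terms for the target residue and the
same six summed over the 5 Å shell and divided by the shell size (zero for
an empty shell). The original enumeration gives 7 per model; the
neighbourhood aggregate is extended to all six terms to reach the printed
24, under the same versioned-layout reasoning.

## The native energy model

All terms describe a residue's interaction with its environment:

| term | form | parameters |
|---|---|---|
| electrostatic | 332·q₁q₂/(4r²) kcal/mol | charges −0.5 per carboxylate O, +1 Lys NZ, +0.5 per Arg NH |
| van der Waals | LJ 6-12, rmin = r₁+r₂ | well depth 0.1; adjacent-residue backbone pairs excluded |
| hydrogen bond | −1 × bond count | donor–acceptor ≤ 3.5 Å, antecedent angle ≥ 120° |
| solvation | ASP × atomic SASA | C +0.016, N/O −0.006, S +0.021, charged −0.024 kcal/mol/Å² |
| entropic | 0.6 × rotatable χ count | configurational ordering cost |

Distances below 0.5 Å are floored (engineered-clash fixtures would
otherwise overflow the 6-12 term). This is the package's own documented
model; it is not, and does not try to be, any commercial force field.

# The learner

A native second-order gradient-boosted tree ensemble
(`boost_fit()`, C++ core). Per boosting round, with labels y ∈ {−1, +1},
y₀₁ = (y+1)/2 and weights w: g = w(p − y₀₁), h = w·p(1−p). Split gain is

$$FG = \tfrac12\left[\frac{f_\alpha(G_L)^2}{H_L+\lambda} +
\frac{f_\alpha(G_R)^2}{H_R+\lambda} - \frac{f_\alpha(G)^2}{H+\lambda}\right]
- \gamma,$$

with the soft-threshold $f_\alpha(x) = x\mp\alpha$ outside $[-\alpha,
\alpha]$ and 0 inside; leaf weights are $-f_\alpha(G)/(H+\lambda)$.

Numerical choices:

* **Defaults** η = 0.3, λ = 1, α = 0, γ = 0 (the conventional defaults of
  gradient-boosting software; the source study reports none), base score
  0.5, ⌊√d⌋ features sampled per node, `min_samples_leaf` 1, depth
  unbounded.
* **Thresholds** are midpoints between consecutive distinct sorted values;
  gain ties break to the lower feature index, then the lower threshold, so
  fits are bit-reproducible.
* **Prefix property.** The feature-subsampling RNG stream is consumed tree
  by tree, so the model with n trees is an exact prefix of the model with
  N > n trees under the same seed. Staged evaluation of an estimator grid
  therefore costs one fit per fold.
* **Splits with non-positive gain are rejected**; growth also stops at
  purity or `min_samples_leaf`.
* `feature_gain()` averages the stored per-split gains per feature —
  an exact evaluation over the serialized statistics, tested against an
  independent walk of the tree dump.

# Protocols

* **Class weights**: N₋/(N₋+N₊) for disease, N₊/(N₋+N₊) for benign — the
  two values always sum to 1.
* **z-normalization** uses population statistics (denominator n) from the
  training part only; constant columns map to zero.
* **Repeated CV** (default 20 × 5-fold) draws fold assignments once per
  repetition (re-drawn, still seeded, if a training part is single-class)
  and reuses them across the whole estimator grid — a paired design. Class
  weights and normalization are recomputed inside each fold; the stricter
  no-leakage choice is taken wherever the original protocol is silent.
* **t-statistic selection**: paired t against the 50-estimator reference,
  sd with denominator m−1; all-zero differences give t = 0 and zero spread
  with non-zero mean a signed ±10⁶ sentinel. The CV comparison metric is
  MCC (configurable) — the imbalance-robust choice.
* **Train/test split** is uniform and unstratified (the published split
  counts are inconsistent with stratification).
* **Leave-one-protein-out** produces exactly one fold per protein; folds
  whose training part is single-class are skipped with a warning.
* **Metrics** with zero denominators are defined as 0.

# Synthetic fixtures, and what passing tests show

The test suite runs entirely on generated data:

* `build_helix()` — ideal-geometry all-atom helices (default φ = −57°,
  ψ = −47°, the canonical transmembrane conformation). These exercise every
  structural contract (backbone completeness, H-bond ladders, burial
  gradients, repacking locality) but are not crystal structures: no
  irregular loops, no β-barrels, no missing residues except those the
  tests remove deliberately, no lipids or waters.
* `planted_dataset()` — standard-normal features with labels from a linear
  rule over a chosen informative subset (equal coefficients), thresholded
  to the requested class balance, optionally noise-flipped. It emulates
  the geometry of the descriptor problem (many weakly informative columns,
  class imbalance) but not the correlation structure of real descriptors.
* `toy_mutation_set()` — seeded mutation records consistent with a fixture
  structure.

Passing tests on these fixtures demonstrate that the machinery is correct
and deterministic — not that the classifier's published real-data accuracy
is reproduced. That would require the original curated mutation set, PDB
structures, and the original (unspecified, commercial) energy software, and
is out of scope by design. One consequence is measured and documented
honestly in the acceptance run: on zero-noise planted data
(n = 500, d = 96, 6 informative features) the full protocol recovers all
six informative features, but its held-out MCC plateaus around 0.5–0.9
across seeds — an intrinsic ceiling of axis-aligned tree ensembles on an
equal-coefficient linear boundary at this sample size, which an
independent boosted-tree implementation reproduces almost exactly.

## Problem sizes used

The suite and the acceptance script use desk-scale sizes chosen as the
package's own configuration: repacking at 20–200 Monte-Carlo steps in
tests (500 by default in production use), the planted protocol at a
5 × 5-fold CV over the estimator grid {5, 10, …, 100} with top-10
test-set selection, a full 15 × 19 saturation scan, and
leave-one-protein-out at 10 synthetic proteins × 20 mutations.

# Known limitations

* Positions are PDB author numbers in structure space; no UniProt↔PDB
  mapping is provided.
* Reentrant-loop ("L") mutations are excluded by default
  (`filter_by_region(keep = "M")`) since the modelled convention for the
  source dataset is unstated; pass `keep = c("M", "L")` to include them.
* The membrane-context and directional substitution tables are synthetic
  stand-ins (see above), not the published matrices.
* The energy model is deliberately simple; its terms are features for a
  classifier, not thermodynamic predictions, and ΔΔG is out of scope.
* Multi-model NMR files use the first model only; mmCIF is not supported.
* Selenomethionine maps to M; any other non-standard residue makes its
  position ineligible rather than guessed at.
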