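---
title: "Methods: structural features and classification protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural features and classification protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitha)
```

# Scope and model

`pitha` predicts whether a humanized or full-human therapeutic antibody will
be clinically immunogenic (treatment-emergent anti-antibody response in ≥ 2%
of patients) from properties of its CDR surface. The working assumption,
supported by the handful of solved idiotype–anti-idiotype complexes, is that
anti-drug antibodies bind the CDR region, so the B-cell-epitope character of
that surface — and not sequence humanness or predicted T-cell epitopes —
carries the signal. Three features enter an RBF-kernel SVM:

* **CDR cavity volume** (Å³). Pockets are detected over the whole Fv; a
  pocket is assigned to the CDR region when at least two thirds of its
  lining atoms belong to CDR residues, and the volumes of all CDR pockets
  are summed. A large central cavity between VH and VL correlates with
  *low* immunogenicity.
* **CDR-H3 hydrophobic SASA** (Å²). Solvent-accessible surface area is
  computed over the whole Fv (the rest of the structure occludes), then
  summed over hydrophobic atoms of CDR-H3 residues. Hydrophobic atoms are
  C, S and N, excluding the non-protonated histidine side-chain nitrogen.
* **Glycine at the CDR-H2 β-turn** (Kabat VH 52–56), entered as a binary
  presence/absence flag. The glycine count is retained in the data model
  for descriptive statistics, but the classifier sees only the bit.

Kabat numbering is an *input* (an ANARCI-style CSV); the package never
assigns numbers to sequences. CDR definitions are the expanded heavy-chain
ranges H1 26–35, H2 49–65, H3 95–102 and the classical Kabat light-chain
ranges L1 24–34, L2 50–56, L3 89–97. Insertion-coded positions (35A, 52A,
100B, …) belong to the range of their base number, so H1 runs through 35B
and 52A sits inside the H2 turn; this follows the Kabat convention, and the
choice is isolated in `annotate_regions()`.

# Surface areas

`shrake_rupley()` uses the radii C 1.8, N 1.65, O 1.4, S 1.85, polar H
1.0 Å, a 1.4 Å probe, and a deterministic quasi-uniform Fibonacci point set,
960 points per atom by default. Per-atom area is the exposed-point fraction
times $4\pi (r + p)^2$. Non-polar hydrogens (bonded to carbon) are excluded
from the computation entirely; a hydrogen's bonding partner is the nearest
heavy atom within 1.3 Å. Crystal structures usually lack hydrogens; no
hydrogen placement is attempted. Heavy-atom-only input is valid and flagged
`no_hydrogens` in every result, and histidines then default to the
NE2-protonated tautomer for the hydrophobicity rule (NE2 hydrophobic, ND1
not). With explicit hydrogens, protonation is read from the structure.

Numerical behaviour, verified in the test suite against independent
oracles: the isolated sphere matches the closed form to < 0.5% at 960
points; the two-sphere case matches the analytic spherical-cap formula;
per-atom areas on random 30-atom clusters agree with a Monte-Carlo
rejection-sampling estimator (10⁵ samples/atom) within 2% of the
isolated-sphere area; refining 960 → 3840 points moves totals by < 1%.
Translation invariance is exact (the point lattice rides on the atoms);
rotation invariance holds only up to the discretization of the fixed point
set and is tested at 0.5% — an inherent property of any fixed-orientation
Shrake–Rupley implementation, not a bug.

# Cavity detection

The reference path consumes an fpocket-style report
(`parse_pocket_report()`), since the published cavity volumes were produced
by an external pocket detector whose exact version and parameters are not
reproducible. For a fully offline path, `detect_pockets()` implements a grid
flood-fill detector: a 1.0 Å grid over the padded bounding box; grid points
inside any probe-expanded atom sphere are solvent-excluded; exterior points
are found by 6-connected flood fill from the box boundary; cavity points are
the remaining interior points plus mouth points recovered by dilating the
cavity up to 2 cells into the exterior; connected components of ≥ 30 points
are pockets (volume = point count × 1 Å³, lining atoms within 4.5 Å). All
five constants are arguments. The detector is validated against a
Monte-Carlo interior-volume oracle on analytically constructed hollow-shell
fixtures (15% tolerance — grid discretization plus mouth recovery dominate
the error) and returns nothing on convex fixtures. It is an approximation
suitable for the 2/3-rule feature, not a replica of any particular pocket
program; per-antibody cavity volumes recomputed from deposited structures
are therefore reported with provenance, never asserted against the bundled
values.

The "two thirds" threshold is *inclusive* (a pocket with exactly 2/3 CDR
lining atoms counts as a CDR pocket) and lives in one predicate,
`is_cdr_pocket()`, so the opposite reading is a one-line change. Both
detector paths share the same rule and summation code.

# Humanness score

For PSSM position $i$ with query residue $r$,
$S_{\mathrm{human}} = \min(M_{ir} - B_{rr}, 0)$, with $M_{ir}$ the
PSI-BLAST self-substitution score and $B_{rr}$ the BLOSUM62 diagonal.
A residue is *rare* when $S_{\mathrm{human}} < -6$, read strictly (−6 is not
rare; the predicate `is_rare_residue()` isolates the choice). Sums and rare
counts are reported separately for CDR and framework positions and are
additive over the partition. The package consumes a user-supplied ASCII
PSSM and never launches searches: the profile depends on the search
database and its version, so database-dependent humanness statistics are
out of scope by design. Whether heavy and light chains are profiled
separately or concatenated is the caller's choice; positions are mapped to
regions explicitly.

# Classification protocol

Both variants use an RBF-kernel C-SVM (libsvm via `e1071`):

* **Scaling** to $[-1, 1]$ by per-feature training min/max, frozen into the
  model — the documented default of libsvm's `svm-scale`. ($[0, 1]$ was
  considered and rejected: it is not what the libsvm tooling does, and it
  degrades the crystal-variant leave-one-out accuracy on the 29-antibody
  set.)
* **Hyperparameters** from the grid $C = 2^{-5..15}$,
  $\gamma = 2^{-15..3}$ (integer exponents), chosen to maximize
  leave-one-out cross-validation accuracy on the training set; ties break
  toward smaller $C$, then smaller $\gamma$. Using LOO folds (rather than
  shuffled k-fold) makes selection fully deterministic on these tiny
  datasets: every fold is a singleton, so fold assignment cannot vary.
* **Reported LOO accuracy** (`loo_accuracy()`, default `nested = FALSE`) is
  the cross-validation accuracy of the selected grid point — the standard
  libsvm workflow (`grid` search, quote the best CV accuracy). Because the
  parameters are chosen on all $n$ samples, this estimate is optimistic.
  `nested = TRUE` re-runs scaling and grid selection inside every outer
  fold and predicts the truly held-out antibody; on 29-sample problems the
  nested estimate runs 10–20 points lower. The default reproduces the
  published protocol; the nested option quantifies the selection bias and
  is the honest generalization estimate for new feature sets.
* No class weights, no probability outputs, no feature selection beyond
  the two published variants.

The packaged deployment model is the modeled variant trained on the 29
crystal-structure antibodies — the scenario in which a candidate antibody
has no crystal structure and its features come from a homology model.

# Synthetic data and what the tests show

`synthetic_structure()` generates atom clouds with ground truth known by
construction: isolated atoms (closed-form SASA), seeded random clusters
(cross-checked against the Monte-Carlo SASA oracle), hollow shells with a
narrow mouth (cavity volume against the Monte-Carlo interior oracle;
defaults: 7.8 Å center-of-atom radius, 2 Å atom spacing, 18° mouth
half-angle), and a CDR-H3 loop buried in a carbon lattice (exact zero
exposed area). `make_feature_dataset()` draws two Gaussian clusters in
feature space with controllable separation (10σ: separable, LOO 100%; 0σ:
chance level). The Monte-Carlo oracles are implementationally independent
of the code they check — random sampling versus deterministic point sets,
rejection sampling versus flood fill.

These fixtures validate geometry and protocol, not biology: they contain no
real side chains, no packing heterogeneity, no crystallographic noise, and
the feature clusters are cleaner than real antibody data. Passing them
shows the *computational* pipeline is correct; the biological performance
claims rest entirely on the bundled 52-antibody tables, whose group means,
glycine census and classification accuracies the test suite and
`scripts/acceptance.R` recompute end to end. Problem sizes used there — 29-
and 23-antibody leave-one-out runs over the 399-point grid, 10⁵ Monte-Carlo
samples per atom, 2×10⁵ per volume estimate — were chosen so the whole
suite completes in a couple of minutes while keeping oracle noise well
below the tested tolerances.

# Known limitations

* The built-in cavity detector is not the detector used to produce the
  bundled cavity volumes; recomputed volumes can differ systematically, and
  the crystal-variant model should be fed volumes from the same detector
  family used at training time.
* No hydrogen placement: heavy-atom-only SASA is a documented deviation
  from protocols that add hydrogens before the calculation. The radii set
  assigns polar hydrogens 1.0 Å when present.
* Kabat numbering quality is inherited from the upstream numbering tool.
* With 29 training antibodies, the default LOO accuracy is a biased
  estimate (see above); ±1 antibody (≈ 3–4 points) is the meaningful
  resolution of any accuracy on these set sizes.
* Labels dichotomize a continuous, assay-dependent quantity (AAR rate at
  the 2% threshold); borderline antibodies carry label noise the model
  cannot resolve.
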