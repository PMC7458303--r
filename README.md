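# pitha

Structure-based prediction of clinical immunogenicity for humanized and
full-human therapeutic antibodies (PITHA).

## The problem

Most approved therapeutic antibodies elicit anti-drug antibodies (ADA) in
some patients; when the treatment-emergent anti-antibody response (AAR)
exceeds a few percent it can alter pharmacokinetics, abolish efficacy, or
end a program in phase III. Anti-idiotypic antibodies bind almost
exclusively to the complementarity-determining regions (CDRs) of the
idiotypic antibody, so B-cell-epitope-like properties of the CDR surface —
not global humanness or predicted T-cell epitopes — carry the
immunogenicity signal. `pitha` computes three such properties from an Fv
structure and combines them with a support vector machine:

1. **CDR cavity volume** `V` (Å³) — the central cavity between the VH and VL
   CDR loops. A pocket belongs to the CDR region when at least 2/3 of its
   lining atoms are in CDR residues; volumes of all such pockets are summed.
   Non-immunogenic antibodies have markedly larger cavities
   (means 798 vs 361 Å³ in the 29-antibody crystal set).
2. **CDR-H3 hydrophobic surface area** `A_H3` (Å²) — the summed
   solvent-accessible surface area (Shrake–Rupley, 1.4 Å probe; radii
   C 1.8, N 1.65, O 1.4, S 1.85, polar H 1.0 Å, non-polar H excluded) of
   hydrophobic atoms (C, S, N except non-protonated His side-chain N) in the
   CDR-H3 loop. Immunogenic antibodies have less hydrophobic CDR-H3 loops.
3. **Glycine at the CDR-H2 β-turn** (Kabat VH 52–56) — a binary
   presence/absence flag. 7 of the 52 antibodies have a glycine-free turn;
   6 of those 7 are immunogenic.

Two RBF-kernel SVM variants are trained, following libsvm practice
(features scaled to [−1, 1] by training min/max; `C = 2^−5…2^15`,
`γ = 2^−15…2^3` selected by maximizing leave-one-out cross-validation
accuracy): a *crystal* variant `(V, A_H3)` for antibodies with crystal
structures, and a *modeled* variant `(A_H3, Gly)` for homology models,
whose cavity volumes are too model-sensitive to be useful.

The package also implements the profile-based humanness score
`S_human(i) = min(M_ir − B_rr, 0)`, where `M_ir` is the PSI-BLAST PSSM
self-substitution score at position `i` for residue type `r` and `B_rr` the
BLOSUM62 diagonal; a residue is *rare* when `S_human < −6`. (Humanness does
not separate immunogenic from non-immunogenic antibodies — that negative
result is what motivates the structural features.)

## What's in the box

- `parse_pdb()`, `read_numbering()`, `annotate_regions()` — Fv structures
  (via bio3d) plus ANARCI-style Kabat numbering CSVs; expanded heavy-chain
  CDR definitions (H1 26–35, H2 49–65, H3 95–102), classical Kabat light
  chains.
- `shrake_rupley()`, `region_hydrophobic_area()` — deterministic SASA with
  the radii set above (960-point Fibonacci sphere by default).
- `detect_pockets()` (grid flood-fill detector, no external binary),
  `parse_pocket_report()` (fpocket-style reports), `cdr_cavity_volume()`.
- `read_pssm()`, `residue_humanness()`, `region_humanness()`.
- `train_svm()`, `loo_accuracy()`, `predict()`, JSON model serialization.
- `load_antibody_features()` — curated feature tables and clinical
  immunogenicity labels for all 52 antibodies (29 crystal / 23 modeled).
- `synthetic_structure()`, `monte_carlo_sasa()`,
  `monte_carlo_interior_volume()` — synthetic fixtures with independent
  Monte-Carlo oracles.
- A command-line entry point at `inst/cli/pitha`
  (`features`, `train`, `predict`, `reproduce`, `humanness`).

## Worked example

```r
library(pitha)

crystal <- load_antibody_features("crystal")   # 29 antibodies, labels included
model   <- train_svm(crystal, variant = "modeled")
model
#> RBF-SVM immunogenicity model
#>   features: h3_hydrophobic_area + gly_h2_turn_present
#>   C = 2^3, gamma = 2^2 (selected by LOO on 29 antibodies)
#>   training LOO accuracy: 79.3%

modeled <- load_antibody_features("modeled")   # 23 antibodies, modeled structures
pred <- predict(model, modeled)                # 1 = immunogenic, 0 = non-immunogenic
head(pred, 5)
#>  Golimumab Alirocumab  Dupilumab Olaratumab  Sarilumab
#>          0          1          0          0          1
prediction_accuracy(pred, modeled$label)
#> [1] 65.21739
```

The training printout says the H3-area + glycine model classifies 23/29
training antibodies correctly under leave-one-out; applied to the 23
antibodies whose structures had to be modeled, 15/23 (65.2%) of its
predictions match the clinical labels — structure quality, not the
classifier, is the limiting factor. From a structure instead of a feature
table:

```r
fv  <- parse_pdb("antibody.pdb", heavy_chain_id = "H", light_chain_id = "L")
num <- read_numbering("antibody_kabat.csv")
extract_features(fv, num)   # cavity_volume, h3_hydrophobic_area, gly counts
```

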