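# saxsemble

Fragment-recombination ensembles of multidomain proteins, validated by
small-angle X-ray scattering (SAXS).

## What it is for

Flexible multidomain proteins — the motivating system is the SHP2
phosphatase, whose constitutively active E76K mutant populates an open
state with no single representative structure — are better described by
a *heterogeneous solution ensemble* than by one conformer. `saxsemble`
is an R package for structural biologists and modellers who want to

* build such an ensemble by recombining conformer pools of two
  overlapping two-domain fragments: superpose each pair of pool
  representatives at the shared domain, count steric clashes between
  the non-shared domains, keep pairs with fewer than a threshold number
  of clashes (default 100), and stitch the survivors into full-length
  conformers;
* validate it against SAXS: forward-predict curves by the exact Debye
  sum or deterministic q-vector direction sampling (2000 directions per
  |q|), with Gaussian dummy-atom excluded-volume contrast
  (ρ\_s = 334 e/nm³) and a fixed hydration-layer offset
  ΔR\_g = 0.76 Å; extract R\_g by iterative Guinier fits; fit scale and
  background against a measured curve with reduced χ²;
* characterise it: essential-dynamics PCA (fit core vs analysis
  selection), GROMOS-style neighbor-counting clustering with cumulative
  population curves, interdomain rotation dihedrals, free-energy
  surfaces F = −kT ln(ρ/ρ\_max) with minimax transition paths,
  centre-of-mass distance series and 3D density maps.

A seeded synthetic generator builds three-domain bead-model fragment
pools with known ground truth (planted hinge modes, a planted von Mises
dihedral mixture at −100°/−30°, brute-force pair clash counts), so the
entire pipeline is testable offline. The core model is described in
`vignettes/fragment-ensembles.Rmd`.

## Worked example

```r
library(saxsemble)

cfg <- pipeline_config(synthetic = synthetic_spec(seed = 42),
                       out_dir = "run42", seed = 42)
rep <- run_pipeline(cfg)
```

```
[saxsemble] fragments: 150 AB + 150 BC members (0.7 s)
[saxsemble] clustering: 32 + 43 clusters; using 20 + 20 representatives (23.7 s)
[saxsemble] pair filter: 400 pairs, 347 pass, 280 zero-clash (26.9 s)
[saxsemble] assembled 347 full-length conformers (28.7 s)
[saxsemble] SAXS: ensemble Rg 2.716 nm; model Rg (hydrated) 1.57-3.27 nm (147.4 s)
[saxsemble] analytics done (150.3 s)
```

The 20 × 20 representative grid gives 400 candidate recombinations; 280
are clash-free, 347 have fewer than 100 clashes and are stitched into
full-length conformers, 53 are discarded. The assembled ensemble's
Guinier R\_g (hydration-corrected) is 2.72 nm, while individual models
span 1.6–3.3 nm — the ensemble average hides a wide range of compact
and elongated conformers, which is the central point of the
ensemble-based description. The shared-to-static domain landscape
(`rep$analytics`) has two basins separated by a 4.8 kJ/mol minimax
barrier, and the rotation-dihedral distribution peaks near the planted
−100° mode. `run42/` contains `report.json`, `clash_matrix.csv`,
per-conformer radii (`conformers.csv`), the ensemble curve
(`ensemble_saxs.dat`), PCA projections, the free-energy surface, the
density map, and the ensemble as a multi-model PDB.

Single structures work the same way at a lower level:

```r
gen <- generate_fragment_ensembles(synthetic_spec(seed = 1))
s <- gen$ab$members[[1]]
cv <- saxs_debye(s, saxs_config(q = seq(0, 2, length.out = 81),
                                scatterer = "uniform-bead"))
guinier_fit(cv, qmax_rg = 1.0)
#> Guinier fit: Rg = 1.4936 nm, I0 = 1.344e+04 (26 pts, q in [0.025, 0.65],
#>              qmax*Rg = 0.97, r^2 = 0.9999)
gyration_summary(s, weighting = "uniform")
#> Rg = 1.5113 nm; gyration eigenvalues (nm^2): 1.978, 0.1561, 0.1499
```

The Guinier estimate agrees with the direct gyration tensor to ~1 %,
the truncation bias expected at this window.

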