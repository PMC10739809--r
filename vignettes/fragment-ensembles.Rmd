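---
title: "Building and validating multidomain solution ensembles by fragment recombination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating multidomain solution ensembles by fragment recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsemble)
```

## The problem

Multidomain proteins with flexible linkers — SHP2 phosphatase is the
motivating case — often do not adopt a single structure in solution.
SHP2 consists of two SH2 domains (N-SH2, C-SH2) followed by the
catalytic PTP domain; in the autoinhibited state N-SH2 blocks the PTP
active site, while activating mutants such as E76K populate an *open*
state whose structure has resisted crystallographic description. A
small-angle X-ray scattering (SAXS) curve of such a protein reports an
ensemble average: the measured radius of gyration of the open mutant
(2.94 nm) exceeds that of the closed wild type (2.69 nm), but no single
conformer reproduces the whole curve.

`saxsemble` implements a fragment-recombination strategy for building a
heterogeneous conformer ensemble of a three-domain protein from two
overlapping two-domain fragment pools, and the analytics used to
characterise and validate it:

1. two fragment pools sharing a middle domain (tandem SH2 = N-SH2 +
   C-SH2, and the N-terminally truncated construct = C-SH2 + PTP) are
   each clustered, and the most-populated-cluster representatives are
   retained;
2. every pairwise combination of representatives is superposed at the
   shared domain and screened for steric clashes between the two
   *non*-shared domains; pairs with fewer than a threshold number of
   clashes (default 100) are stitched into full-length conformers;
3. the resulting ensemble is validated by forward-predicted SAXS
   (Guinier radius of gyration with a fixed hydration offset, ensemble
   curve, optional chi-squared against a measured curve) and
   characterised by essential-dynamics PCA, free-energy surfaces,
   interdomain rotation dihedrals, centre-of-mass distances and 3D
   density maps.

## The forward SAXS model

For scatterers with contrast amplitudes $g_a(q)$ at positions $r_a$ the
orientationally averaged intensity is computed two ways:

* **Debye formula** (exact spherical average):
  $I(q) = \sum_{ab} g_a(q)\, g_b(q)\, \mathrm{sinc}(q\,r_{ab})$.
  This is the oracle; it is exact but quadratic in the atom count.
* **q-vector sampling**: $I(q)$ as the mean of
  $|\sum_a g_a(q) e^{i q \hat u \cdot r_a}|^2$ over unit directions
  $\hat u$. The default 2000 directions per $|q|$ come from a
  *deterministic* spherical Fibonacci lattice rather than random
  sampling, so results are reproducible and the error decays smoothly
  with the direction count. The test suite verifies agreement with the
  Debye oracle to well below 1 % over the working range
  $q \le 3\,\mathrm{nm^{-1}}$.

In atomic mode, amplitudes are 4-Gaussian-plus-constant element form
factors; the excluded solvent is modelled as a Gaussian dummy atom per
element,
$g_a(q) = f_a(q) - \rho_s V_a \exp(-q^2 V_a^{2/3}/4\pi)$,
the Fourier transform of a Gaussian density of integrated volume $V_a$
(the displaced-solvent volume), which gives the exact limit
$g_a(0) = Z_a - \rho_s V_a$ and reproduces the low-$q$ behaviour of a
uniform sphere of equal volume. The default solvent density is the
experimental value $\rho_s = 334\ e/\mathrm{nm^3}$. Uniform-bead mode
($g \equiv 1$) serves coarse-grained models.

Explicit hydration layers are out of scope; instead a fixed offset
$\Delta R_g = 0.076$ nm (0.76 Å) is added to bare-model radii of
gyration, the magnitude by which an ordered water shell raises the
apparent $R_g$ of a protein of this size. This keeps implicit-solvent
model values comparable with experimental (hydrated) ones.

### Guinier analysis

`guinier_fit()` iterates a linear fit of $\ln I$ vs $q^2$, truncating
the window to $q R_g \le$ a configurable bound (default 1.3, the common
convention) until stable. On an ideal Guinier curve the recovery is
exact; on curved profiles (e.g. a solid sphere) the truncation bias is
$O((q_{max} R_g)^2)$ — roughly 1.8 % at a bound of 1.3 and under 1 % at
0.8 — so comparisons against the gyration tensor in the tests use the
stricter window. The window actually used is reported in the fit
object.

## Assembly semantics

* **Clash definition.** A clash is a cross-pair of atoms, one from each
  tested domain, at distance below a cutoff after superposition at the
  shared domain. For all-atom structures the default is 0.20 nm between
  heavy atoms (genuine steric overlap, not mere contact); for
  residue-level bead models the natural criterion is one bead diameter,
  0.38 nm, which the synthetic defaults use. Counting uses a cell-list
  grid and is verified identical to the brute force.
* **Threshold semantics.** A pair survives iff its clash count is
  *strictly below* the threshold (default 100): "fewer than 100 pass,
  at least 100 are discarded". A moderate clash allowance is deliberate
  — residual surface-side-chain overlap is fixable downstream, while a
  zero-tolerance filter would discard most of the conformational
  diversity.
* **Junction.** Stitching replaces spatial-restraint homology
  modelling: residues below the junction come from the first fragment,
  the rest from the second. The junction sits in the middle of the
  shared domain, where both fragments have just been superposed, so the
  seam inherits continuity from the fit (the seam bond length and fit
  RMSD are reported per conformer). Carving a parent structure into
  fragments and reassembling reproduces the parent to machine
  precision.

## Ensemble analytics

* **PCA** (essential dynamics): members are superposed over a rigid
  *fit* core onto an iteratively refined mean (two passes), and the
  covariance of a separate *analysis* selection is diagonalised; this
  separates interdomain motion from tumbling. The model stores its
  fitting reference, so projecting the training set reproduces the
  eigenvalues exactly.
* **Clustering** uses the neighbor-counting (GROMOS-style) algorithm:
  deterministic, with ties broken by the lowest member index. The RMSD
  cutoff is configurable (0.3 nm is typical for all-atom C-alpha
  clustering; the bead-model pipeline default is 0.10 nm, about a
  quarter of the bead spacing, chosen so the default pools resolve into
  more than 20 clusters).
* **Free-energy surfaces** are Boltzmann inversions of 2D histograms,
  $F = -k_BT \ln(\rho/\rho_{max})$, with $k_BT = 2.478$ kJ/mol (298 K).
  Empty bins stay masked (no pseudo-counts), matching the blank
  unexplored regions of published landscapes. Bin-to-bin differences
  reproduce count ratios exactly, by construction.
* **Transition paths** are *minimax* paths on the 8-connected graph of
  occupied bins: the path minimising the highest free energy crossed,
  with the barrier measured from the starting basin. A landscape shows
  a pathway but rarely defines one; minimax is the natural discrete
  notion of "lowest saddle" and is deterministic.
* **Rotation dihedral**: the interdomain rotation is monitored by a
  dihedral over four C-alpha atoms, two near the centre of each domain
  and roughly perpendicular to the interdomain axis (for SHP2:
  Glu139–Ser134–Pro454–Cys459; about 20° in the autoinhibited
  structure). Histogram peaks are local maxima after a 3-bin circular
  moving average — single-bin sampling noise would otherwise split a
  broad mode into spurious peaks; the raw counts are kept alongside.
* **Density maps and COM distances** place every member in the
  static-domain frame and histogram the mobile-domain centre of mass;
  isosurface levels are reported as fractions of the maximum (defaults
  0.1 and 0.001).

## What the synthetic generator emulates

`synthetic_spec()` / `generate_fragment_ensembles()` build two fragment
pools of a three-domain toy protein with *known ground truth*, standing
in for the molecular-dynamics conformer pools of the real study, which
cannot be regenerated at desk scale:

* domains are rigid clouds of pseudo-C-alpha beads on a 0.38 nm
  lattice (A ≈ N-SH2, 60 beads; B ≈ C-SH2, 50; C ≈ PTP, 110 —
  roughly proportional to the real domain sizes at one bead per
  residue);
* fragment AB varies by a hinge rotation of A about an axis through
  the A–B linker anchor. A configurable fraction (default 0.3, mirroring
  the observed ~31 % discard rate) is drawn in a *closed* pose
  (170° ± 8°) that folds A onto C's position upon recombination,
  producing clash counts that straddle the threshold; open poses
  (55° ± 15°) are clash-free;
* fragment BC varies by a screw motion of C along the interdomain
  axis: a spin (the planted rotation dihedral, drawn from a von Mises
  mixture at −100°/−30° with weights 0.6/0.4) plus an axial
  displacement. Four marker beads (one off-axis and one on-axis per
  domain) make the measured dihedral *exactly* equal to the planted
  spin — axial translation does not change marker azimuths;
* the mixture concentration (κ = 10, circular spread ≈ 18°) keeps the
  two rotation basins connected across a saddle of a few kJ/mol, the
  low-barrier regime reported for the real interdomain roto-translation
  (< 5 kJ/mol);
* every member receives a random global rigid motion that downstream
  superpositions must remove; ground truth records per-member hinge
  angles, dihedrals, domain COMs, radii of gyration, and brute-force
  pair clash counts.

What the toys deliberately do **not** emulate: side-chain chemistry and
packing, linker energetics, solvent, and the atomic-detail SAXS
contrast of a real protein (bead mode uses unit amplitudes). Passing
the recovery tests therefore demonstrates the correctness of the
*algorithms* — superposition, clash counting, stitching, forward
scattering, PCA, clustering, landscape analysis — not the physical
accuracy of any force field. Conversely, nothing in the pipeline is
bead-specific: all-atom PDB ensembles run through the same surface
with atomic form factors.

## Default study conditions and problem sizes

The default pipeline generates 150 members per fragment pool, clusters
each pool (cutoff 0.10 nm), takes 20 representatives per pool (the
20 × 20 = 400-pair screen), assembles the passing pairs (~330
conformers), and computes per-conformer and ensemble SAXS on a
0–3 nm⁻¹ grid of 151 points. These sizes keep a full run around a
minute on one core while leaving every stage statistically meaningful
(20 clusters resolvable, free-energy bins occupied). The
planted-recovery analyses use larger single-purpose pools where
precision demands it (2000 members for dihedral peak location, 1500 for
eigenvalue ratios).

## Numerical choices

* Optimal rotations via the SVD (Kabsch) construction with a
  determinant guard; collinear fit sets are rejected rather than
  silently resolved.
* Dihedrals use the atan2 formulation, IUPAC sign, range (−180°, 180°]
  with exactly opposed arrangements reported as +180°.
* Altloc records: highest occupancy wins, ties go to code "A".
  Residue numbers are author numbering, never renumbered; negative
  numbers (N-terminal expression tags) are supported.
* Internal units are nm (q in nm⁻¹) throughout; PDB I/O converts
  Å ↔ nm at the boundary, and fixed-width overflow (residues > 9999,
  coordinates beyond ±9999.999 Å) is an error, never a truncation.
* The GROMOS clustering and the minimax path are fully deterministic;
  all stochastic stages flow from one integer seed, and rerunning a
  pipeline with the same configuration reproduces the report
  byte-for-byte.

## Working with the real accession data

The package runs offline on synthetic data; the checks against the
published system use public records that must be fetched once by hand
(they are not redistributed): SASBDB curves SASDEP4 / SASDEN4
(experimental SAXS of the open mutant and wild type; `read_saxs_curve()`
reads them with `q_unit = "angstrom"`), PDB 4DGP (autoinhibited
structure; the rotation dihedral over residues 139, 134, 454, 459 of
chain A evaluates to ≈ 20°), and the deposited model ensembles. Placing
the files under `inst/extdata/accessions/` and reinstalling activates
the corresponding acceptance tests.

## Known limitations

* The stitched conformers are geometric seeds, not relaxed structures:
  no side-chain repacking, no restraint-based remodelling, no MD
  refinement.
* The implicit-solvent SAXS model with the fixed hydration offset
  cannot capture system-specific hydration effects; discrepancies of a
  few tenths of an Å in $R_g$ are inside its systematic error.
* Ensemble SAXS weights conformers by the assembly output (uniform over
  passing pairs by default); no reweighting against the experimental
  curve is performed, by design — the ensemble is validated against the
  data, not fitted to it.
* The minimax barrier is resolved only to the histogram bin; sparse
  ensembles can leave basins legitimately disconnected, which is
  reported rather than interpolated away.
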