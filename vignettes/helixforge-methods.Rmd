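---
title: "helixforge: methods and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{helixforge: methods and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixforge)
```

# Scope

helixforge is a toolkit for the structural analysis of helical protein
filaments — actin-like two-start helices in particular — built from cryo-EM
maps and atomic models. It covers four analysis families:

1. **Helical symmetry**: estimating rise and twist from a filament model by
   screw-axis decomposition, and the cross-over arithmetic that follows.
2. **Density sharpening**: real-space high-boost filtering with a
   score-driven choice of the sharpening factor, scored either by a
   side-chain χ1 map-model statistic or by masked map-model correlation,
   with Fourier B-factor sharpening as the classic baseline.
3. **Cation-site geometry**: coordinating-atom searches, angle RMSD against
   ideal coordination polyhedra (gRMSD), bond-valence vector sums, and
   difference-density peak picking for density that the protein model cannot
   explain.
4. **Structure comparison**: least-squares superposition, per-residue
   deviation maps (global and locally aligned), peptide-flip detection, salt
   bridges, and inter-subunit distance bookkeeping in straight and bent
   filaments.

Everything is exercised against seeded synthetic fixtures generated in code,
so the full test suite runs offline.

# Containers and conventions

An `AtomicModel` is an ordered atom table (chain, residue number, residue
name, atom name, element, xyz in Å, B-factor in Å², occupancy, HETATM flag);
the (chain, resno, atom) triple is unique. Coordinates are Å, right-handed,
PDB convention. A `DensityMap` is a 3D grid plus per-axis voxel size and a
world-space origin; the world coordinate of (1-based) index $(i,j,k)$ is
exactly $\mathrm{origin} + (i-1,j-1,k-1)\cdot\mathrm{voxel}$. Grids are
always stored x-fastest; axis-permuted MRC files are canonicalized on read.

Two origin dialects occur in deposited MRC maps: the `origin` float record
and integer `nstart` offsets. `read_map()` uses the origin record when any
component is nonzero and `nstart * voxel` otherwise; both behaviors can be
forced with `origin_mode`.

# Helical symmetry

`build_filament()` places subunit $k$ at a rotation of $k\cdot$twist about
the axis and a translation of $k\cdot$rise along it. `estimate_symmetry()`
inverts this: each consecutive chain pair is superposed on shared Cα atoms
(Kabsch, proper rotation only) and the optimal transform is decomposed into
screw parameters — the rotation angle from the rotation matrix, the axis
from its antisymmetric part, and the rise as the translation component along
the axis. The axis direction is chosen so the rise is positive; the twist is
then the signed right-handed angle about that axis, which makes a left-handed
1-start actin helix come out near −167°. At numerically exact 180° rotations
the sign is meaningless; we report +180 by convention and the cross-over
computation refuses such input rather than guessing a sign. Rotations near
0° have no defined axis and raise an error.

The cross-over distance of a two-start helix is
$L = \mathrm{rise} \cdot 180 / (180 - |\mathrm{twist}|)$, the axial length
over which the two long-pitch strands cross. It is linear in rise and
strictly increasing in $|\mathrm{twist}|$ toward 180°. For the actin-like
parameter pairs (27.5 Å, −167.2°) and (27.5 Å, −166.6°) this gives 386.72 Å
vs 369.40 Å, a 4.69 % relative increase — the number the acceptance script
reports as target `t1`.

`compare_twist()` applies a Welch (unequal-variance) two-sample t-test to
per-interface twist samples. The choice of Welch is an assumption — the
upstream refinement statistics behind published twist p-values are not
available to a model-based estimator — and is documented as such.

# High-boost sharpening and the χ1 scorer

The sharpening filter computes a 3×3×3 boxcar mean of the map (edges by
nearest replication, avoiding rim artifacts) and subtracts a weighted copy:
$\mathrm{out} = \mathrm{map} - w \cdot \mathrm{lowpass}(\mathrm{map})$.
This is the verbatim "subtract a weighted low-pass copy" reading; the
alternative $\mathrm{map} + w(\mathrm{map} - \mathrm{lowpass})$ differs only
by scale and offset. A uniform kernel is the simplest consistent choice for
a "fixed 3×3×3 kernel". Factor 0 is the identity; factors near 1 remove most
low-frequency content, and larger factors can invert smooth regions — the
optimizer's trace makes that visible rather than hiding it.

`optimize_sharpening()` evaluates a scorer on the sharpened map over an
ascending factor grid and returns the argmax (ties to the smaller factor).
One fidelity gap is deliberate: published score-optimized sharpening
protocols re-refine the model for each trial factor; helixforge rescores the
fixed model, trading a heavyweight refinement dependency for reproducibility.

The χ1 scorer follows the EMRinger idea. For every residue with a γ heavy
atom (all standard residues except Gly/Ala/Pro), candidate γ positions are
generated by sweeping the idealized Cβ–γ bond (1.52 Å, 113.8° angle) about
the χ1 axis in 5° steps (72 angles) and the map is interpolated trilinearly
at each. The peak angle is rotameric when within ±30° (inclusive) of 60°,
180° or 300°, so the null rotameric fraction is $p_0 = 39/72$. At each of 20
thresholds evenly spaced from 0 to the map maximum, residues whose peak
value clears the threshold contribute to
$z = (n_{rot} - n p_0)/\sqrt{n p_0 (1-p_0)}$, and the score is the maximum
$z$ over thresholds retaining at least 10 residues. If every one of $n$
residues is rotameric, $z = \sqrt{n(1-p_0)/p_0}$ — 4.11 for $n = 20$ — which
the suite reproduces as a closed-form anchor. The score is invariant under
uniform positive scaling of map values because peak angles depend only on
ranks along the ring and the threshold grid rescales with the maximum.
Exact parity with any particular EMRinger implementation is not claimed;
the variant is fixed and documented here.

`bfactor_sharpen()` scales Fourier amplitudes by $\exp(-B s^2/4)$ up to a
resolution cutoff and zeroes beyond it; the suite checks the per-component
amplitude contract directly against an independent FFT and the analytic
width/peak change of a Gaussian blob.

# Model-derived maps

`model_to_map()` uses the simple Gaussian-atom model: each atom contributes
an isotropic Gaussian with variance $(B + B_{\mathrm{offset}})/(8\pi^2)$ and
integral equal to atomic number × occupancy, truncated at 4.5σ (spherical
cutoff, identical in the gridded and analytic evaluation paths so that
difference maps of a model against its own synthetic map vanish
identically). Electron scattering factors are out of scope; amplitude ∝ Z is
sufficient for difference-peak detection and scoring. No parity with
refinement-package model maps is claimed.

# Cation-site evaluation

`find_coordinating_atoms()` returns O/N donors (waters included, hydrogens
and the metal excluded) strictly inside the cutoff; 2.6 Å is the default,
the usual Mg²⁺ coordination distance. `geometry_grmsd()` scores the observed
ligand–metal–ligand angles against the ideal angles of octahedral, trigonal
bipyramidal, square pyramidal or tetrahedral polyhedra under the best of all
exhaustive ligand-to-vertex assignments (≤ 6! = 720); it is invariant to
rigid motion, uniform scaling and ligand relabeling, and the suite pins it
to an independently coded brute-force oracle at 1e-9. `bond_valence_vecsum()`
computes $|\sum_i s_i \hat u_i| / \sum_i s_i$ with
$s_i = \exp((r_0 - r_i)/0.37)$ and shipped $r_0$ constants (Mg–O 1.693 Å,
K–O 2.132 Å, Mg–N 1.85 Å, and a few more): 0 for a centrosymmetric
equal-distance shell, 1 for a single ligand. By this bond-valence
vector-sum convention **smaller is more symmetric**; some published glosses
describe a normalized variant in the opposite sense, so the convention is
stated explicitly wherever the number is reported.

`find_unmodeled_peaks()` builds a difference map against the least-squares
amplitude-scaled model map, then reports strict 26-neighborhood local maxima
above `sigma_threshold` difference-map standard deviations and farther than
an exclusion radius from any model atom. `classify_cation_candidate()` turns
a site report into an ordered Mg²⁺/K⁺/water plausibility list using distance
windows (Mg–O 1.9–2.6 Å, K–O 2.6–3.2 Å), coordination-number preferences
(Mg 5–6, K 6–8), a gRMSD regularity bonus and an under-coordination rule for
water — with the fired rules attached, and never a certainty claim.

# Structure comparison

Superposition is Kabsch with the reflection guard (det +1). Per-residue
deviation maps come in two modes: *global* (one fit on all shared Cα, then
per-residue distances) and *local* (each residue measured after fitting its
±10-residue window), the pair of views that distinguishes genuine local
rearrangement from domain- or hinge-scale motion. A peptide flip is flagged
when, after window superposition, the carbonyl C→O vectors of a residue
differ by more than 90° while both flanking Cα deviations stay below 3 Å —
plane rotation with a preserved trace. Both thresholds are exposed as
arguments. Salt bridges pair Asp/Glu side-chain oxygens with Lys/Arg/His
side-chain nitrogens below 5 Å (minimum-distance atom pair per residue
pair). For bent filaments, `bending_distance_change()` evaluates a contact
across user-labeled inner/outer interfaces of a straight and a bent
filament; inner/outer labeling is deliberately user-supplied because
curvature-side classification is not uniquely defined for a generic bent
model (an automatic classifier is a documented extension point).

# Synthetic fixtures: what they emulate, and what they do not

The generators are pure functions of their parameters and seed. The toy
monomer uses idealized backbone internal coordinates (trans peptides, varied
φ/ψ in alternating helix-like and extended blocks, consecutive Cα–Cα ≈ 3.80
Å) with optional Lys/Glu/Leu side chains at a requested χ1 — enough for χ1
scoring, salt-bridge and flip fixtures, but not a rotamer library and not
chemically refined. Filaments wrap `build_filament()` with the monomer
displaced ~15 Å off-axis (an actin-like helix radius) and optional Gaussian
coordinate jitter. Metal sites place ideal polyhedron vertices at a chosen
distance with Gaussian perturbation. Bending is rigid-subunit arc transport
onto a circle: it reproduces the outer-stretch/inner-compression geometry to
thin-arc accuracy but carries no intra-subunit strain — it validates the
distance bookkeeping, not bending physics.

Consequently a green suite establishes the correctness of the algorithms and
their contracts on controlled inputs. It does not establish agreement with
any deposited experimental reconstruction: real maps have non-Gaussian
noise, local resolution variation, solvent flattening and mask artifacts
that the fixtures deliberately omit.

# Stochastic test worlds (fixed before measurement)

* χ1 null: 200-residue toy chain scored in i.i.d. N(0,1) voxel noise
  (1.2 Å voxels), 20 seeds; the mean score must stay below 1.
* Sharpening-helps fixture: model map blurred with B = 150 Å² (a typical
  overall cryo-EM B-factor scale) plus Gaussian noise at 10 % of the map
  maximum; optimization must never return a worse-scoring factor than 0.
* Peak recovery: blobs of nominal amplitude 6× the noise sd (measured
  heights ~5–6σ of the difference map, i.e. the ≥ 4σ class of real ion
  peaks) planted in noise with sd 5 % of the model-map maximum; recovery is
  required in 20/20 seeds within one voxel in the Chebyshev sense (the
  26-neighborhood of the planted voxel).
* Symmetry recovery: 0.1 Å coordinate jitter, 10 seeds, recovery of
  (27.5 Å, −167.2°) within 0.05 Å / 0.05° on the seed-averaged estimate.

These parameters were chosen once, on the grounds stated, and are not tuned
against test outcomes.

# Numerical choices and degenerate inputs

* Trilinear interpolation returns `NA` outside the grid box; callers decide
  (the χ1 scorer treats it as −∞, i.e. never a peak).
* Kabsch superposition needs ≥ 3 pairs and errors on collinear/degenerate
  selections (zero determinant); the rotation determinant is always +1.
* `estimate_symmetry()` requires ≥ 3 shared Cα per chain pair; ties at 180°
  and undefined axes error as described above.
* PDB output is refused (or falls back to mmCIF on request) when residue
  numbers exceed 9999 or chain ids exceed one character.
* A difference map that is numerically zero (model map scored against
  itself) yields no peaks rather than dividing by a zero sigma.
* Sharpening-factor ties resolve to the smaller factor, preferring the less
  aggressive filter.

# Known limitations

* No per-factor model re-refinement inside sharpening optimization (see
  above); scores on real maps will differ from refine-then-score protocols.
* The Gaussian-atom model ignores element-specific scattering curves and
  anisotropic B-factors.
* mmCIF support is the `atom_site` loop only — no assemblies, no symmetry
  expansion.
* Symmetry estimation operates on atomic models, not on density maps; map
  space helical refinement is out of scope.
* CLI subcommands cover the documented operations with TSV/JSON outputs; a
  configuration-file layer beyond flags is not implemented.
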