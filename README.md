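# helixforge

Structural analysis of helical protein filaments from cryo-EM data, in R.

Actin-like filaments are two-start helices whose mechanics are read off, in
large part, from structural quantities: the helical rise and twist relating
consecutive subunits (and the cross-over distance of the long-pitch strands
that follows from them), the quality of the density around side chains
(which sharpening tries to maximize without amplifying noise), the geometry
of candidate cation sites at inter-subunit interfaces, and distance changes
across those interfaces when filaments bend. helixforge implements these
analyses for structural biologists who have an atomic model (PDB/mmCIF)
and/or a density map (MRC2014) and want reproducible, scriptable numbers:

* **Helical symmetry** — `estimate_symmetry()` superposes consecutive
  subunits on shared Cα atoms and decomposes the optimal rigid transform
  into screw parameters (rise along the axis, signed twist about it);
  `build_filament()` is its exact inverse. `crossover_distance()` computes
  `rise * 180 / (180 - |twist|)`, and `compare_twist()` runs a Welch t-test
  on per-interface twist samples.
* **Density sharpening** — `high_boost(map, w)` subtracts `w` times a 3×3×3
  boxcar low-pass copy from the map (3D high-boost filtering: high
  frequencies enhanced, low frequencies retained);
  `optimize_sharpening()` picks the factor maximizing either an
  EMRinger-style χ1 rotamer score (`chi1_map_score()`) or masked map-model
  correlation (`masked_correlation()`); `bfactor_sharpen()` is the Fourier
  B-factor baseline.
* **Cation sites** — `find_coordinating_atoms()` (default cutoff 2.6 Å, the
  Mg²⁺ coordination distance), `geometry_grmsd()` (angle RMSD against ideal
  coordination polyhedra, minimized over exhaustive vertex assignments),
  `bond_valence_vecsum()` (|Σ sᵢûᵢ|/Σ sᵢ with sᵢ = exp((r₀−rᵢ)/0.37); 0 =
  perfectly symmetric), `find_unmodeled_peaks()` (difference-density peaks
  the model cannot explain), `classify_cation_candidate()` (rule-based
  Mg²⁺/K⁺/water ranking).
* **Structure comparison** — `superpose()`, `per_residue_deviation()`
  (global and locally aligned Cα deviation maps),
  `detect_peptide_flips()` (carbonyl rotation > 90° with the Cα trace
  preserved), `detect_salt_bridges()` (acidic O vs basic N under 5 Å),
  `interface_distance()` and `bending_distance_change()` for straight vs
  bent filaments.
* **Synthetic fixtures** — seeded generators (`make_toy_monomer()`,
  `make_helical_filament()`, `make_metal_site()`, `make_bent_filament()`)
  produce every input class the toolkit needs, so all tests run offline.

## Worked example

```r
library(helixforge)

# Cross-over arithmetic at actin-like helical parameters
sym_y <- helical_symmetry(27.5, -167.2)   # yeast-like twist
sym_v <- helical_symmetry(27.5, -166.6)   # vertebrate-like twist
crossover_distance(sym_y)                 # 386.72 A
crossover_distance(sym_v)                 # 369.40 A
100 * (crossover_distance(sym_y) / crossover_distance(sym_v) - 1)  # 4.69 %

# Estimate symmetry back from a noisy synthetic filament
fil <- make_helical_filament(sym_y, n_subunits = 6, n_residues = 30,
                             noise_sd = 0.1, seed = 42)
estimate_symmetry(fil)
#> <SymmetryEstimate> 5 interfaces; mean rise 27.4996 A, mean twist -167.2079 deg

# Score a model against its own synthetic map: every chi1 peak rotameric
m <- make_toy_monomer(20, with_sidechains = TRUE, seed = 5, chi1 = 180)
map <- model_to_map(m, voxel_size = 0.8, b_offset = 15)
sc <- chi1_map_score(map, m)
sc$score                                  # 4.11 = sqrt(20 * (1 - p0) / p0)
sum(sc$per_residue$rotameric)             # 20 of 20

# Evaluate a slightly perturbed 5-coordinate metal site
site <- make_metal_site("trigonal_bipyramidal", mean_distance = 2.15,
                        perturbation_sigma = 0.1, seed = 7)
rep <- metal_site_report(site, "MG", c(0, 0, 0), cutoff = 2.6)
rep
#> <MetalSiteReport> MG, CN 5, vecsum 0.152, best geometry trigonal_bipyramidal
classify_cation_candidate(rep)$ranking
#> "Mg2+" "K+"   "water"
```

The printed numbers mean: the 0.6° twist difference between the two helical
parameter sets stretches the cross-over distance by 4.69 % (≈ 17 Å per
cross-over); the symmetry estimator recovers the generating parameters to
well under 0.01 Å / 0.01° even with 0.1 Å coordinate noise; a map that
perfectly supports all 20 side chains reaches the all-rotameric ceiling of
the χ1 score for n = 20; and a mildly perturbed trigonal-bipyramidal site
with ~2.1 Å O-ligands, gRMSD 6.2° and vecsum 0.15 is ranked as a plausible
Mg²⁺ rather than K⁺ or water.

A command-line entry point mirrors the API:

```sh
Rscript -e 'quit(status = helixforge::helixforge_main())' \
  crossover --rise 27.5 --twist -167.2
# 386.72 A
```

## Documentation

The methods vignette (`vignettes/helixforge-methods.Rmd`) describes the
models and conventions: the screw decomposition and twist sign convention,
the high-boost filter and the exact χ1-score variant implemented, the
Gaussian-atom map model, the bond-valence convention (smaller vecsum = more
symmetric), the synthetic-data worlds used by the stochastic tests, and
known limitations.
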