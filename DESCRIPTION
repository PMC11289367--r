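Package: helixforge
Title: Helical Filament Density Sharpening and Structural Geometry Toolkit
Version: 0.1.0
Authors@R: person("Helixforge", "Developers", role = c("aut", "cre"),
    email = "helixforge@example.org")
Description: Tools for structural analysis of helical protein filaments from
    cryo-EM data: score-optimized real-space high-boost density sharpening with
    a side-chain chi1 map-model scorer and a masked map correlation scorer;
    helical symmetry (rise/twist) estimation by screw-axis decomposition and
    cross-over distance arithmetic; candidate cation-site evaluation via
    coordination-geometry angle RMSD and bond-valence vector sums together with
    unmodeled difference-density peak picking; structure comparison
    (superposition, per-residue deviation maps, peptide-flip detection, salt
    bridges, inter-subunit distances in straight and bent filaments); readers
    and writers for PDB, mmCIF (atom_site) and MRC2014 density maps; and seeded
    synthetic fixture generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
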