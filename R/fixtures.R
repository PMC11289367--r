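# Seeded synthetic-fixture generators. Every generator is a pure function of
# its parameters and seed (same inputs -> bit-identical output), so the whole
# test suite runs without downloading deposited maps or models.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Idealized backbone internal coordinates (trans peptide).
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.5, omega = 180)

#' Generate a toy protein monomer
#'
#' Builds a chemically plausible single-chain backbone from idealized bond
#' lengths and angles with varied phi/psi (alternating helix-like and
#' extended-like stretches plus seeded jitter), carbonyl oxygens and C-beta
#' atoms. With `with_sidechains = TRUE` residues cycle through Lys/Glu/Leu and
#' receive side chains whose chi1 dihedral is placed at `chi1` (remaining
#' dihedrals trans), which makes the monomer usable for chi1 map-model scoring
#' and salt-bridge fixtures. Without side chains all residues are alanine.
#'
#' @param n_residues number of residues (>= 3).
#' @param with_sidechains add Lys/Glu/Leu side chains.
#' @param seed RNG seed (determinism contract).
#' @param chi1 requested chi1 dihedral for side chains, degrees.
#' @param chain chain identifier.
#' @return an [atomic_model()].
#' @export
make_toy_monomer <- function(n_residues, with_sidechains = FALSE, seed = 1,
                             chi1 = 180, chain = "A") {
  if (n_residues < 3) hf_error("n_residues must be >= 3")
  with_seed(seed, {
    # alternating secondary-structure-like blocks of 8 residues
    blk <- ((seq_len(n_residues) - 1) %/% 8) %% 2
    phi <- ifelse(blk == 0, -60, -120) + runif(n_residues, -10, 10)
    psi <- ifelse(blk == 0, -45, 130) + runif(n_residues, -10, 10)
    N <- matrix(0, n_residues, 3); CA <- N; C <- N; O <- N
    N[1, ] <- c(0, 0, 0)
    CA[1, ] <- c(.bb$n_ca, 0, 0)
    C[1, ] <- CA[1, ] + .bb$ca_c *
      c(cos(deg2rad(180 - .bb$ang_n_ca_c)), sin(deg2rad(180 - .bb$ang_n_ca_c)), 0)
    for (i in 2:n_residues) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           .bb$c_n, .bb$ang_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            .bb$n_ca, .bb$ang_c_n_ca, .bb$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           .bb$ca_c, .bb$ang_n_ca_c, phi[i])
    }
    for (i in seq_len(n_residues)) {
      # carbonyl O in the peptide plane, opposite the next N
      ref_dihedral <- if (i < n_residues) psi[i] + 180 else 0
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                           .bb$c_o, .bb$ang_ca_c_o, ref_dihedral)
    }
    seqnames <- if (with_sidechains)
      rep(c("LYS", "GLU", "LEU"), length.out = n_residues)
    else rep("ALA", n_residues)
    rows <- list()
    add <- function(i, at, el, p) {
      rows[[length(rows) + 1]] <<- data.frame(
        chain = chain, resno = i, resname = seqnames[i], atom = at,
        element = el, x = p[1], y = p[2], z = p[3], b = 15, occ = 1,
        het = FALSE, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_residues)) {
      add(i, "N", "N", N[i, ]); add(i, "CA", "C", CA[i, ])
      add(i, "C", "C", C[i, ]); add(i, "O", "O", O[i, ])
      cb <- place_atom(C[i, ], N[i, ], CA[i, ], 1.526, 110.5, -122.5)
      add(i, "CB", "C", cb)
      if (with_sidechains) {
        cg <- place_atom(N[i, ], CA[i, ], cb, 1.52, 113.8, chi1)
        if (seqnames[i] == "LYS") {
          add(i, "CG", "C", cg)
          cd <- place_atom(CA[i, ], cb, cg, 1.52, 111, 180)
          ce <- place_atom(cb, cg, cd, 1.52, 111, 180)
          nz <- place_atom(cg, cd, ce, 1.49, 111, 180)
          add(i, "CD", "C", cd); add(i, "CE", "C", ce); add(i, "NZ", "N", nz)
        } else if (seqnames[i] == "GLU") {
          add(i, "CG", "C", cg)
          cd <- place_atom(CA[i, ], cb, cg, 1.52, 112, 180)
          oe1 <- place_atom(cb, cg, cd, 1.25, 118, 0)
          oe2 <- place_atom(cb, cg, cd, 1.25, 118, 180)
          add(i, "CD", "C", cd); add(i, "OE1", "O", oe1); add(i, "OE2", "O", oe2)
        } else {  # LEU
          add(i, "CG", "C", cg)
          cd1 <- place_atom(CA[i, ], cb, cg, 1.52, 110.5, 180)
          cd2 <- place_atom(CA[i, ], cb, cg, 1.52, 110.5, 60)
          add(i, "CD1", "C", cd1); add(i, "CD2", "C", cd2)
        }
      }
    }
    as_atomic_model(do.call(rbind, rows))
  })
}

#' Generate a helical filament fixture
#'
#' Wraps [build_filament()] around a generated toy monomer (displaced off the
#' axis so the helix has a sensible radius) and optionally adds per-atom
#' Gaussian coordinate jitter, for symmetry-recovery simulations with known
#' ground truth. Defaults target the actin-like regime (rise 27.5 Angstrom,
#' twist -167.2 degrees).
#'
#' @param sym a [helical_symmetry()].
#' @param n_subunits number of subunits.
#' @param n_residues residues per toy monomer.
#' @param radius approximate distance of the monomer centroid from the helix
#'   axis, Angstrom.
#' @param noise_sd per-coordinate Gaussian jitter, Angstrom (0 = noiseless).
#' @param with_sidechains passed to [make_toy_monomer()].
#' @param seed RNG seed.
#' @return an [atomic_model()] filament.
#' @export
make_helical_filament <- function(sym = helical_symmetry(27.5, -167.2),
                                  n_subunits = 6, n_residues = 25,
                                  radius = 15, noise_sd = 0,
                                  with_sidechains = FALSE, seed = 1) {
  mono <- make_toy_monomer(n_residues, with_sidechains, seed = seed)
  ctr <- colMeans(model_coords(mono))
  mono <- transform_model(mono, diag(3), c(radius, 0, 0) - ctr)
  fil <- build_filament(mono, sym, n_subunits)
  if (noise_sd > 0) {
    fil <- with_seed(seed + 7919L, {
      xyz <- model_coords(fil)
      set_model_coords(fil, xyz + matrix(rnorm(length(xyz), 0, noise_sd),
                                         ncol = 3))
    })
  }
  fil
}

#' Generate an idealized (optionally perturbed) metal site
#'
#' Places a metal HETATM at `center` and oxygen ligands (modeled as waters) at
#' the ideal vertices of the requested geometry scaled to `mean_distance`,
#' then perturbs each ligand position by isotropic Gaussian noise.
#'
#' @param geometry one of the geometries of [geometry_grmsd()].
#' @param mean_distance metal-ligand distance, Angstrom.
#' @param perturbation_sigma Gaussian positional noise per ligand coordinate,
#'   Angstrom.
#' @param metal_element metal element symbol.
#' @param center site position.
#' @param seed RNG seed.
#' @return an [atomic_model()] with the metal and its water ligands.
#' @export
make_metal_site <- function(geometry = "octahedral", mean_distance = 2.1,
                            perturbation_sigma = 0, metal_element = "MG",
                            center = c(0, 0, 0), seed = 1) {
  v <- ideal_geometry_vertices(geometry)
  with_seed(seed, {
    pos <- sweep(v * mean_distance, 2, center, "+")
    if (perturbation_sigma > 0)
      pos <- pos + matrix(rnorm(length(pos), 0, perturbation_sigma), ncol = 3)
    df <- data.frame(
      chain = "M",
      resno = c(1L, seq_len(nrow(v)) + 1L),
      resname = c(toupper(metal_element), rep("HOH", nrow(v))),
      atom = c(toupper(metal_element), rep("O", nrow(v))),
      element = c(toupper(metal_element), rep("O", nrow(v))),
      x = c(center[1], pos[, 1]), y = c(center[2], pos[, 2]),
      z = c(center[3], pos[, 3]),
      b = 20, occ = 1, het = TRUE, stringsAsFactors = FALSE)
    as_atomic_model(df)
  })
}

#' Bend a straight filament onto a circular arc
#'
#' Maps the helix axis (z) onto a circular arc of radius `arc_radius` in the
#' xz plane (arc center on +x), transporting each subunit rigidly: a subunit
#' whose centroid sits at axial position z0 is rotated by z0/arc_radius about
#' y and re-seated on the arc. Material on the -x side (outside the bending
#' curve) is stretched, the +x side compressed, by the thin-arc factor
#' (1 -/+ r/arc_radius). Rigid-subunit transport tests the distance
#' bookkeeping, not bending physics.
#'
#' @param filament a straight filament built along z.
#' @param arc_radius bending radius, Angstrom; `Inf` returns the filament
#'   unchanged.
#' @param bend_plane plane containing the arc: "xz" (arc center on +x) or
#'   "yz" (arc center on +y).
#' @return the bent [atomic_model()].
#' @export
make_bent_filament <- function(filament, arc_radius, bend_plane = c("xz", "yz")) {
  bend_plane <- match.arg(bend_plane)
  if (is.infinite(arc_radius)) return(filament)
  if (bend_plane == "yz") {
    # rotate the problem into the xz frame, bend, rotate back
    Rz <- rotation_about_axis(c(0, 0, 1), -90)
    fil <- transform_model(filament, Rz, c(0, 0, 0))
    bent <- make_bent_filament(fil, arc_radius, "xz")
    return(transform_model(bent, t(Rz), c(0, 0, 0)))
  }
  zr <- range(filament$z)
  if (arc_radius <= (zr[2] - zr[1]) / pi)
    hf_error("arc_radius too small: filament would self-intersect")
  out <- filament
  for (ch in unique(filament$chain)) {
    idx <- which(filament$chain == ch)
    z0 <- mean(filament$z[idx])
    phi <- z0 / arc_radius
    Ry <- rotation_about_axis(c(0, 1, 0), rad2deg(phi))
    seat <- c(arc_radius * (1 - cos(phi)), 0, arc_radius * sin(phi))
    local <- sweep(model_coords(model_subset(filament, idx)), 2, c(0, 0, z0))
    moved <- sweep(local %*% t(Ry), 2, seat, "+")
    out$x[idx] <- moved[, 1]; out$y[idx] <- moved[, 2]; out$z[idx] <- moved[, 3]
  }
  out
}
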