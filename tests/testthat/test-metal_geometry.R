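# Cation-site evaluation: donor search, gRMSD vs a brute-force oracle,
# bond-valence vector sums, difference peaks, plausibility ranking.

test_that("find_coordinating_atoms applies the strict distance cutoff", {
  site <- make_metal_site("octahedral", mean_distance = 2.1)
  lig <- find_coordinating_atoms(site, c(0, 0, 0), cutoff = 2.6)
  expect_equal(nrow(lig), 6)
  expect_true(all(lig$distance < 2.6))
  expect_true(all(lig$element == "O"))
  expect_equal(nrow(find_coordinating_atoms(site, c(0, 0, 0), cutoff = 2.0)), 0)
  # strict inequality at the boundary: 2.59 in, 2.61 out
  edge <- atomic_model("M", 1:2, "HOH", c("O", "O"), "O",
                       x = c(2.59, -2.61), y = 0, z = 0, het = TRUE)
  got <- find_coordinating_atoms(edge, c(0, 0, 0), cutoff = 2.6)
  expect_equal(nrow(got), 1)
  expect_equal(got$x, 2.59)
  expect_error(find_coordinating_atoms(edge, c(0, 0, 0), cutoff = 0), "cutoff")
})

test_that("geometry_grmsd is zero on ideal sites and rejects mismatches", {
  for (g in c("octahedral", "trigonal_bipyramidal", "square_pyramidal",
              "tetrahedral")) {
    v <- helixforge:::ideal_geometry_vertices(g) * 2.1
    expect_equal(geometry_grmsd(c(0, 0, 0), v, g), 0, tolerance = 1e-9)
  }
  tbp <- helixforge:::ideal_geometry_vertices("trigonal_bipyramidal") * 2
  expect_error(geometry_grmsd(c(0, 0, 0), tbp, "octahedral"), "6 ligands")
  # a perfect trigonal bipyramid is distinguishable from square pyramidal
  expect_gt(geometry_grmsd(c(0, 0, 0), tbp, "square_pyramidal"), 5)
})

test_that("geometry_grmsd equals the exhaustive brute-force oracle", {
  set.seed(42)
  for (trial in 1:50) {
    geom <- sample(c("octahedral", "trigonal_bipyramidal"), 1)
    site <- make_metal_site(geom, mean_distance = 2.1,
                            perturbation_sigma = 0.25, seed = trial)
    lig <- as.matrix(site[site$resname == "HOH", c("x", "y", "z")])
    lig <- lig[sample(nrow(lig)), ]  # relabeling must not matter
    expect_equal(geometry_grmsd(c(0, 0, 0), lig, geom),
                 oracle_grmsd(c(0, 0, 0), lig, geom), tolerance = 1e-9)
  }
})

test_that("geometry_grmsd is invariant under rigid motion and scaling", {
  site <- make_metal_site("octahedral", 2.1, perturbation_sigma = 0.2,
                          seed = 9)
  lig <- as.matrix(site[site$resname == "HOH", c("x", "y", "z")])
  v0 <- geometry_grmsd(c(0, 0, 0), lig, "octahedral")
  rt <- rigid37()
  moved <- sweep(lig %*% t(rt$R), 2, rt$t, "+")
  ctr <- drop(rt$R %*% c(0, 0, 0)) + rt$t
  expect_equal(geometry_grmsd(ctr, moved, "octahedral"), v0, tolerance = 1e-9)
  expect_equal(geometry_grmsd(c(0, 0, 0), lig * 3.7, "octahedral"), v0,
               tolerance = 1e-9)
})

test_that("bond_valence_vecsum matches hand arithmetic and stays in [0,1]", {
  site <- make_metal_site("octahedral", 2.1)
  lig <- find_coordinating_atoms(site, c(0, 0, 0), 2.6)
  expect_equal(bond_valence_vecsum("MG", c(0, 0, 0), lig), 0, tolerance = 1e-12)
  expect_equal(bond_valence_vecsum("MG", c(0, 0, 0), lig[1, , drop = FALSE]), 1)
  # 5-ligand trigonal bipyramid, one axial bond stretched 0.3 A: direct
  # evaluation of s_i = exp((r0 - r_i)/0.37) weighted unit vectors
  v <- helixforge:::ideal_geometry_vertices("trigonal_bipyramidal")
  pos <- v * 2.1
  pos[1, ] <- v[1, ] * 2.4
  df <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], element = "O")
  s <- exp((1.693 - c(2.4, rep(2.1, 4))) / 0.37)
  hand <- sqrt(sum(colSums(s * (pos / c(2.4, rep(2.1, 4))))^2)) / sum(s)
  expect_equal(bond_valence_vecsum("MG", c(0, 0, 0), df), hand,
               tolerance = 1e-12)
  # always within [0, 1] on random perturbed sites
  for (s_ in 1:20) {
    st <- make_metal_site("tetrahedral", 2.0, perturbation_sigma = 0.4,
                          seed = s_)
    lg <- find_coordinating_atoms(st, c(0, 0, 0), 4)
    vs <- bond_valence_vecsum("MG", c(0, 0, 0), lg)
    expect_gte(vs, 0); expect_lte(vs, 1)
  }
  expect_error(bond_valence_vecsum("MG", c(0, 0, 0), lig[0, , drop = FALSE]),
               "ligand")
  fe <- data.frame(x = 2, y = 0, z = 0, element = "P")
  expect_error(bond_valence_vecsum("MG", c(0, 0, 0), fe), "r0")
})

test_that("metal site fixtures grow monotonically in gRMSD with noise", {
  mean_g <- sapply(c(0, 0.1, 0.25), function(sig) {
    mean(sapply(1:25, function(s) {
      st <- make_metal_site("octahedral", 2.1, perturbation_sigma = sig,
                            seed = s)
      lig <- as.matrix(st[st$resname == "HOH", c("x", "y", "z")])
      geometry_grmsd(c(0, 0, 0), lig, "octahedral")
    }))
  })
  expect_true(all(diff(mean_g) > 0))
  expect_equal(mean_g[1], 0, tolerance = 1e-9)
})

test_that("find_unmodeled_peaks recovers planted blobs and nothing else", {
  m <- make_toy_monomer(15, seed = 4)
  mm <- model_to_map(m, voxel_size = 1, padding = 6, b_offset = 20)
  # exact model map: empty difference, no peaks
  expect_equal(nrow(find_unmodeled_peaks(mm, m)), 0)
  d <- dim(mm$grid)
  ax <- lapply(1:3, function(k) mm$origin[k] + (seq_len(d[k]) - 1))
  spot <- c(ax[[1]][4], ax[[2]][4], ax[[3]][4])  # empty corner voxel center
  sn <- 0.05 * max(mm$grid)
  blob <- 6 * sn * outer(outer(exp(-(ax[[1]] - spot[1])^2 / (2 * 1.1^2)),
                               exp(-(ax[[2]] - spot[2])^2 / (2 * 1.1^2))),
                         exp(-(ax[[3]] - spot[3])^2 / (2 * 1.1^2)))
  hits <- 0; heights <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    noisy <- density_map(mm$grid + blob + array(rnorm(prod(d), 0, sn), d),
                         1, mm$origin)
    pk <- find_unmodeled_peaks(noisy, m)
    expect_gt(nrow(pk), 0)
    cheb <- apply(abs(cbind(pk$x - spot[1], pk$y - spot[2], pk$z - spot[3])),
                  1, max)
    if (any(cheb <= 1.0)) hits <- hits + 1
    heights[s] <- max(pk$height[cheb <= 1.0], -Inf)
  }
  expect_equal(hits, 20)
  expect_gte(mean(heights), 4)
  # threshold contract: raising sigma_threshold above the blob height (~6
  # sigma here) makes the same blob invisible
  set.seed(1)
  noisy1 <- density_map(mm$grid + blob + array(rnorm(prod(d), 0, sn), d),
                        1, mm$origin)
  pw <- find_unmodeled_peaks(noisy1, m, sigma_threshold = 10)
  expect_equal(nrow(pw), 0)
  expect_error(find_unmodeled_peaks(mm, m, mask_radius = 0.0001), "mask")
})

test_that("classify_cation_candidate fires the documented rules", {
  # 6 oxygens at 2.1 A, regular: Mg first
  s1 <- make_metal_site("octahedral", 2.1, perturbation_sigma = 0.05, seed = 2)
  r1 <- metal_site_report(s1, "MG", c(0, 0, 0), cutoff = 2.6)
  c1 <- classify_cation_candidate(r1)
  expect_equal(c1$ranking[1], "Mg2+")
  expect_equal(r1$coordination_number, 6)
  expect_equal(r1$best_geometry, "octahedral")
  # 7 oxygens at ~2.8 A: K first (use a 6-vertex shell plus an extra water)
  s2 <- make_metal_site("octahedral", 2.8)
  extra <- data.frame(chain = "M", resno = 99L, resname = "HOH", atom = "O",
                      element = "O", x = 2.8 / sqrt(3), y = 2.8 / sqrt(3),
                      z = 2.8 / sqrt(3), b = 20, occ = 1, het = TRUE)
  s2 <- helixforge:::as_atomic_model(rbind(as.data.frame(s2), extra))
  r2 <- metal_site_report(s2, "K", c(0, 0, 0), cutoff = 3.2)
  expect_equal(r2$coordination_number, 7)
  c2 <- classify_cation_candidate(r2)
  expect_equal(c2$ranking[1], "K+")
  # 2 ligands at 2.8 A: water first
  s3 <- atomic_model("M", 1:2, "HOH", c("O", "O"), "O",
                     x = c(2.8, -2.8), y = 0, z = 0, het = TRUE)
  r3 <- metal_site_report(s3, "MG", c(0, 0, 0), cutoff = 3.2)
  c3 <- classify_cation_candidate(r3)
  expect_equal(c3$ranking[1], "water")
  # empty ligand list: indeterminate
  r0 <- metal_site_report(s3, "MG", c(50, 50, 50), cutoff = 2.6)
  expect_equal(classify_cation_candidate(r0)$ranking, "indeterminate")
})
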