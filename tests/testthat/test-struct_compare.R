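# Superposition, deviation maps, peptide flips, salt bridges, interface and
# bent-filament distances.

test_that("superpose recovers rigid motions and the analytic triangle", {
  m <- make_toy_monomer(15, seed = 7)
  s0 <- superpose(m, m)
  expect_equal(s0$rmsd, 0, tolerance = 1e-9)
  expect_equal(s0$R, diag(3), tolerance = 1e-9)
  rt <- rigid37()
  moved <- transform_model(m, rt$R, rt$t)
  s1 <- superpose(moved, m)
  expect_equal(s1$rmsd, 0, tolerance = 1e-9)
  expect_equal(s1$R, t(rt$R), tolerance = 1e-9)  # inverts the motion
  expect_equal(det(s1$R), 1, tolerance = 1e-9)
  # planar triangle pair with a closed-form optimum: congruent triangles
  # related by an in-plane rotation superpose exactly
  P <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  th <- pi / 5
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fit <- helixforge:::kabsch(P, P %*% t(Rz))
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  # degenerate input: < 3 pairs
  expect_error(helixforge:::kabsch(P[1:2, ], P[1:2, ]), "3")
})

test_that("superpose never exceeds the unfitted RMSD", {
  set.seed(13)
  for (i in 1:10) {
    m <- make_toy_monomer(12, seed = i)
    b <- m
    xyz <- model_coords(b) + matrix(rnorm(3 * nrow(b), 0, 1.5), ncol = 3)
    b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
    ca_b <- model_coords(helixforge:::ca_subset(b))
    ca_m <- model_coords(helixforge:::ca_subset(m))
    raw_rmsd <- sqrt(mean(rowSums((ca_b - ca_m)^2)))
    expect_lte(superpose(b, m)$rmsd, raw_rmsd + 1e-12)
  }
})

test_that("per_residue_deviation separates hinge motion by alignment mode", {
  a <- make_toy_monomer(30, seed = 8)
  # identical models: all deviations zero
  r0 <- per_residue_deviation(a, a)
  expect_equal(max(r0$per_residue$deviation), 0, tolerance = 1e-9)
  expect_equal(r0$global_rmsd,
               sqrt(mean(r0$per_residue$deviation^2)), tolerance = 1e-9)
  # single displaced residue shows up at its own position
  b <- a
  i <- which(b$resno == 12 & b$atom == "CA")
  b$x[i] <- b$x[i] + 2.2
  rb <- per_residue_deviation(a, b)
  worst <- rb$per_residue[which.max(rb$per_residue$deviation), ]
  expect_equal(worst$resno, 12)
  expect_equal(worst$deviation, 2.2, tolerance = 0.3)
  # hinge-bent fixture: global large in the far domain, local near zero
  h <- a
  piv <- unlist(a[a$resno == 15 & a$atom == "CA", c("x", "y", "z")])
  Rh <- helixforge:::rotation_about_axis(c(0, 1, 0), 60)
  sel <- h$resno > 15
  xyz <- model_coords(h)
  xyz[sel, ] <- sweep(sweep(xyz[sel, ], 2, piv) %*% t(Rh), 2, piv, "+")
  h$x <- xyz[, 1]; h$y <- xyz[, 2]; h$z <- xyz[, 3]
  rg <- per_residue_deviation(a, h, "global")
  rl <- per_residue_deviation(a, h, "local", window = 10)
  expect_gt(max(rg$per_residue$deviation), 2)
  expect_lt(max(rl$per_residue$deviation), max(rg$per_residue$deviation))
  far <- abs(rl$per_residue$resno - 15) > 11
  expect_lt(max(rl$per_residue$deviation[far]), 1e-6)
  # invariant: local never exceeds global far from the hinge
  expect_true(all(rl$per_residue$deviation[far] <=
                    rg$per_residue$deviation[far] + 1e-9))
  expect_equal(rg$global_rmsd,
               sqrt(mean(rg$per_residue$deviation^2)), tolerance = 1e-9)
})

test_that("detect_peptide_flips flags rotated planes and gates rigid motion", {
  a <- make_toy_monomer(30, seed = 8)
  expect_equal(nrow(detect_peptide_flips(a, a)), 0)
  # rotate one peptide plane (C, O of residue 15) 180 deg about the CA-CA axis
  b <- a
  ca1 <- unlist(a[a$resno == 15 & a$atom == "CA", c("x", "y", "z")])
  ca2 <- unlist(a[a$resno == 16 & a$atom == "CA", c("x", "y", "z")])
  Rf <- helixforge:::rotation_about_axis(ca2 - ca1, 180)
  for (j in which(b$resno == 15 & b$atom %in% c("C", "O"))) {
    p <- unlist(b[j, c("x", "y", "z")])
    q <- drop(Rf %*% (p - ca1)) + ca1
    b$x[j] <- q[1]; b$y[j] <- q[2]; b$z[j] <- q[3]
  }
  fl <- detect_peptide_flips(a, b)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$resno, 15)
  expect_gt(fl$angle, 150)
  # whole-model rigid rotation: no flips (deviations vanish after fitting)
  rt <- rigid37()
  expect_equal(nrow(detect_peptide_flips(a, transform_model(a, rt$R, rt$t))),
               0)
  # missing backbone atoms are skipped with a warning
  miss <- helixforge:::model_subset(b, !(b$resno == 20 & b$atom == "O"))
  expect_warning(fl2 <- detect_peptide_flips(a, miss), "skipped")
  expect_equal(fl2$resno, 15)
})

test_that("detect_salt_bridges applies cutoff and chain filters", {
  m <- make_toy_monomer(12, with_sidechains = TRUE, seed = 14)
  sb <- detect_salt_bridges(m, cutoff = 5)
  # reported pairs are Glu/Asp oxygens against Lys/Arg/His nitrogens
  if (nrow(sb) > 0) {
    expect_true(all(sb$resname_a %in% c("GLU", "ASP")))
    expect_true(all(sb$resname_b %in% c("LYS", "ARG", "HIS")))
    expect_true(all(sb$distance < 5))
  }
  # constructed pair at 3.4 A is found; at 5.5 A it is not
  pair <- atomic_model(
    chain = c("A", "A", "B", "B"),
    resno = c(1L, 1L, 2L, 2L),
    resname = c("GLU", "GLU", "LYS", "LYS"),
    atom = c("OE1", "OE2", "NZ", "CE"),
    element = c("O", "O", "N", "C"),
    x = c(0, 0.5, 3.4, 4.5), y = 0, z = 0)
  got <- detect_salt_bridges(pair)
  expect_equal(nrow(got), 1)
  expect_equal(got$atom_a, "OE2")  # minimum-distance equivalent reported
  expect_equal(got$distance, 2.9)
  far <- pair; far$x[3:4] <- c(6.0, 7.0)
  expect_equal(nrow(detect_salt_bridges(far)), 0)
  # intra-chain exclusion
  intra <- pair; intra$chain <- "A"; intra <- helixforge:::as_atomic_model(intra)
  expect_equal(nrow(detect_salt_bridges(intra, inter_chain_only = TRUE)), 0)
  expect_equal(nrow(detect_salt_bridges(intra, inter_chain_only = FALSE)), 1)
  # stability under rigid motion
  rt <- rigid37()
  moved <- transform_model(pair, rt$R, rt$t)
  expect_equal(detect_salt_bridges(moved)$distance, got$distance,
               tolerance = 1e-9)
})

test_that("interface_distance resolves equivalents and missing atoms", {
  m <- atomic_model(
    chain = c("A", "A", "B"),
    resno = c(167L, 167L, 61L),
    resname = c("GLU", "GLU", "LYS"),
    atom = c("OE1", "OE2", "NZ"),
    element = c("O", "O", "N"),
    x = c(4.9, 3.1, 0), y = 0, z = 0)
  spec <- contact_spec("A", 167, c("OE1", "OE2"), "B", 61, "NZ")
  expect_equal(interface_distance(m, spec), 3.1)
  sp1 <- contact_spec("A", 167, "OE1", "B", 61, "NZ", mode = "specific")
  expect_equal(interface_distance(m, sp1), 4.9)
  two <- atomic_model("A", 1:2, "HOH", c("O1", "O2"), "O",
                      x = c(0, 2.1), y = 0, z = 0, het = TRUE)
  expect_equal(interface_distance(two, contact_spec("A", 1, "O1", "A", 2, "O2")),
               2.1)
  bad <- contact_spec("A", 167, "OE3", "B", 61, "NZ")
  expect_error(interface_distance(m, bad), "OE3")
  expect_error(contact_spec("A", 1, c("O1", "O2"), "B", 2, "NZ",
                            mode = "specific"), "single")
})

test_that("bending_distance_change tracks outer stretch and inner compression", {
  # twist-free filament with marker atoms on both sides of the axis
  mono <- atomic_model(
    chain = "A", resno = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
    resname = "GLY", atom = rep(c("N", "CA", "C"), 3), element = rep("C", 9),
    x = rep(c(-5, 0, 5), 3), y = 0, z = rep(c(0, 0.5, 1), each = 3))
  fil <- build_filament(mono, helical_symmetry(10, 1e-7), 5)
  bent <- make_bent_filament(fil, 400)
  ifc <- data.frame(chain_a = c("A", "B", "C"), chain_b = c("B", "C", "D"),
                    label = "i")
  outer_spec <- contact_spec("A", 2, "N", "B", 2, "N")    # x = -5 side
  inner_spec <- contact_spec("A", 2, "C", "B", 2, "C")    # x = +5 side
  ro <- bending_distance_change(fil, bent, outer_spec,
                                transform(ifc, label = "outer"))
  ri <- bending_distance_change(fil, bent, inner_spec,
                                transform(ifc, label = "inner"))
  expect_true(all(ro$delta > 0))
  expect_true(all(ri$delta < 0))
  expect_equal(ro$label, rep("outer", 3))
  # thin-arc chord prediction: separation ~ 2 (Rc +/- 5) sin(rise/(2 Rc))
  pred_out <- 2 * (400 + 5) * sin(10 / 800)
  expect_equal(ro$bent, rep(pred_out, 3), tolerance = 5e-4)
  # identical filaments: zero deltas; swapped labels swap groups
  r0 <- bending_distance_change(fil, fil, outer_spec, ifc)
  expect_equal(r0$delta, rep(0, 3))
  expect_identical(
    bending_distance_change(fil, bent, outer_spec,
                            transform(ifc, label = "swapped"))$delta,
    ro$delta)
  # infinite radius bend is the identity
  expect_identical(make_bent_filament(fil, Inf), fil)
  expect_error(make_bent_filament(fil, 5), "self-intersect")
})
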