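test_that("atomic radii follow the antibody radii set and hydrogen rules", {
  expect_equal(atom_radius("C"), 1.8)
  expect_equal(atom_radius("N"), 1.65)
  expect_equal(atom_radius("O"), 1.4)
  expect_equal(atom_radius("S"), 1.85)
  expect_true(is.na(atom_radius("H", bonded_to = "C")))   # non-polar: excluded
  expect_equal(atom_radius("H", bonded_to = "N"), 1.0)
  expect_equal(atom_radius("H", bonded_to = "O"), 1.0)
  expect_error(atom_radius("FE"), "unsupported element: FE")
  expect_error(atom_radius("H"), "no covalent partner")
})

test_that("hydrophobic atoms are C, S and N except non-protonated His side-chain N", {
  atoms <- data.frame(
    name = c("N", "CA", "O", "SD", "ND1", "NE2"),
    element = c("N", "C", "O", "S", "N", "N"),
    chain = "H", resno = c(1, 1, 1, 2, 3, 3), insert = "",
    resname = c("ALA", "ALA", "ALA", "MET", "HIS", "HIS"),
    x = c(0, 1, 2, 3, 4, 6.2), y = 0, z = 0)
  hp <- is_hydrophobic_atom(atoms)
  expect_true(hp[1])    # backbone N
  expect_true(hp[2])    # carbon
  expect_false(hp[3])   # carbonyl O
  expect_true(hp[4])    # sulfur
  # no hydrogens in structure: NE2-protonated tautomer assumed
  expect_false(hp[5])   # His ND1 non-protonated
  expect_true(hp[6])    # His NE2 protonated

  # explicit hydrogen on ND1 flips the classification
  atoms_h <- rbind(atoms,
                   data.frame(name = "HD1", element = "H", chain = "H",
                              resno = 3, insert = "", resname = "HIS",
                              x = 3.6, y = 0.9, z = 0))
  hp_h <- is_hydrophobic_atom(atoms_h)
  expect_true(hp_h[5])   # ND1 now protonated
  expect_false(hp_h[6])  # NE2 has no H within bonding distance
  expect_false(hp_h[7])  # hydrogen itself never hydrophobic
})

test_that("isolated and well-separated spheres match the closed form to < 0.5%", {
  one <- shrake_rupley(carbon_atoms(cbind(0, 0, 0)))
  exact <- 4 * pi * (1.8 + 1.4)^2
  expect_lt(abs(one$total_area - exact) / exact, 0.005)

  two <- shrake_rupley(carbon_atoms(cbind(c(0, 10), 0, 0)))
  expect_equal(two$atoms$area, rep(exact, 2), tolerance = 0.005)
})

test_that("two overlapping spheres match the analytic cap formula", {
  R <- 1.8 + 1.4
  d <- 3.0
  exact <- two_sphere_exposed_area(R, R, d)
  sr <- shrake_rupley(carbon_atoms(cbind(c(0, d), 0, 0)), n_sphere_points = 3840)
  expect_equal(sr$atoms$area, rep(exact, 2), tolerance = 0.005)

  mc <- monte_carlo_sasa(carbon_atoms(cbind(c(0, d), 0, 0)),
                         n_samples = 1e5, seed = 7)
  expect_true(all(abs(mc$area - exact) <= 3 * mc$std_error + 1e-9))
})

test_that("Shrake-Rupley agrees with the Monte-Carlo oracle on a random cluster", {
  set.seed(11)
  xyz <- matrix(rnorm(90, sd = 4), ncol = 3)
  atoms <- carbon_atoms(xyz)
  sr <- shrake_rupley(atoms)
  mc <- monte_carlo_sasa(atoms, n_samples = 1e5, seed = 3)
  ref_area <- 4 * pi * (1.8 + 1.4)^2
  # per-atom agreement within 2% of the isolated-sphere area
  expect_true(all(abs(sr$atoms$area - mc$area) <= 0.02 * ref_area))
  expect_lt(abs(sr$total_area - sum(mc$area)) / sum(mc$area), 0.02)
})

test_that("point-set refinement changes areas by < 1%", {
  set.seed(5)
  atoms <- carbon_atoms(matrix(rnorm(60, sd = 3.5), ncol = 3))
  a960 <- shrake_rupley(atoms, n_sphere_points = 960)$total_area
  a3840 <- shrake_rupley(atoms, n_sphere_points = 3840)$total_area
  expect_lt(abs(a960 - a3840) / a3840, 0.01)
})

test_that("adding an occluder never increases any other atom's area", {
  set.seed(9)
  xyz <- matrix(rnorm(45, sd = 3), ncol = 3)
  base <- shrake_rupley(carbon_atoms(xyz))
  grown <- shrake_rupley(carbon_atoms(rbind(xyz, c(0.5, 0.5, 0.5))))
  expect_true(all(grown$atoms$area[seq_len(nrow(xyz))] <= base$atoms$area + 1e-9))
})

test_that("hydrophobic fraction is invariant under rigid motion", {
  atoms <- data.frame(
    name = c("N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C"),
    chain = "H", resno = 1, insert = "", resname = "ALA",
    x = c(0, 1.5, 2.2, 1.6, 2.1), y = c(0, 0, 1.3, 2.4, -1.3), z = 0)
  ref <- shrake_rupley(atoms)

  # translation: exact (the point lattice translates with the atoms)
  shifted <- atoms
  shifted$x <- atoms$x + 12.3; shifted$y <- atoms$y - 4.5; shifted$z <- atoms$z + 7
  got_t <- shrake_rupley(shifted)
  expect_equal(got_t$hydrophobic_fraction, ref$hydrophobic_fraction,
               tolerance = 1e-9)
  expect_equal(got_t$atoms$area, ref$atoms$area, tolerance = 1e-9)

  # rotation: invariant up to the discretization of the fixed point set
  theta <- 0.83
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% rot
  rotated <- atoms
  rotated$x <- xyz[, 1]; rotated$y <- xyz[, 2]; rotated$z <- xyz[, 3]
  got_r <- shrake_rupley(rotated)
  expect_equal(got_r$hydrophobic_fraction, ref$hydrophobic_fraction,
               tolerance = 5e-3)
  expect_equal(got_r$total_area, ref$total_area, tolerance = 5e-3)
})

test_that("non-polar hydrogens are excluded while polar ones contribute", {
  heavy <- data.frame(name = c("CA", "N"), element = c("C", "N"),
                      chain = "H", resno = 1, insert = "", resname = "GLY",
                      x = c(0, 10), y = 0, z = 0)
  with_h <- rbind(heavy,
                  data.frame(name = c("HA", "H"), element = "H",
                             chain = "H", resno = 1, insert = "",
                             resname = "GLY",
                             x = c(1.0, 11.0), y = 0, z = 0))
  res <- shrake_rupley(with_h)
  # the C-bonded hydrogen is dropped: only 3 atoms computed
  expect_equal(nrow(res$atoms), 3)
  expect_true("H" %in% res$atoms$element)
  expect_false(res$no_hydrogens)
})

test_that("region areas partition the total and CDR-H3 burial gives zero", {
  synth <- synthetic_structure("buried_loop")
  mapped <- atom_regions(synth$fv, synth$annotation)
  res <- shrake_rupley(mapped)
  a <- res$atoms
  by_region <- tapply(a$area, a$region, sum)
  expect_equal(sum(by_region), res$total_area, tolerance = 1e-9)

  h3 <- region_hydrophobic_area(synth$fv, synth$annotation, region = "CDR-H3")
  expect_equal(h3$hydrophobic_area, 0)
  expect_true(h3$no_hydrogens)

  expect_error(region_hydrophobic_area(synth$fv, synth$annotation,
                                       region = "CDR-L2"),
               "no residues")
})

test_that("an isolated glycine dipeptide matches the Monte-Carlo oracle", {
  synth <- synthetic_structure("buried_loop")
  loop_atoms <- synth$fv$atoms[synth$fv$atoms$serial %in% synth$loop_serials, ]
  sr <- shrake_rupley(loop_atoms)
  mc <- monte_carlo_sasa(loop_atoms, n_samples = 1e5, seed = 21)
  expect_lt(abs(sr$total_area - sum(mc$area)) / sum(mc$area), 0.02)
})

test_that("degenerate inputs error", {
  expect_error(shrake_rupley(carbon_atoms(cbind(0, 0, 0)),
                             n_sphere_points = 10), ">= 60")
  only_npH <- data.frame(name = c("CA", "HA"), element = c("C", "H"),
                         chain = "H", resno = 1, insert = "", resname = "GLY",
                         x = c(0, 1), y = 0, z = 0)
  expect_error(shrake_rupley(only_npH[2, ]), "no included atoms|partner")
})
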