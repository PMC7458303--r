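fpocket_report <- function(volumes, drop_volume = FALSE) {
  blocks <- vapply(seq_along(volumes), function(i) {
    vol_line <- if (drop_volume && i == 1) "" else
      sprintf("\tVolume : \t%.1f", volumes[i])
    paste(sprintf("Pocket %d :", i),
          "\tScore : \t0.2",
          vol_line,
          "\tNumber of Alpha Spheres : \t12",
          sep = "\n")
  }, character(1))
  paste(blocks, collapse = "\n\n")
}

test_that("pocket report parser captures volumes and lining atoms", {
  rep2 <- fpocket_report(c(150.0, 300.0))
  pk <- parse_pocket_report(rep2, pocket_atoms = list(`1` = 1:12, `2` = 20:25))
  expect_length(pk, 2)
  expect_equal(vapply(pk, `[[`, numeric(1), "volume"), c(150, 300))
  expect_equal(pk[[2]]$lining_serials, 20:25)

  # PDB-format atom listing also works
  pdb_atoms <- paste(pdb_atom_line(7, "CA", "GLY", "H", 1, 0, 0, 0),
                     pdb_atom_line(9, "CB", "ALA", "H", 2, 1, 1, 1),
                     sep = "\n")
  pk2 <- parse_pocket_report(fpocket_report(55), pocket_atoms = list(`1` = pdb_atoms))
  expect_equal(pk2[[1]]$lining_serials, c(7L, 9L))
})

test_that("pocket report parser handles degenerate and malformed input", {
  expect_length(parse_pocket_report("no pockets here\n"), 0)
  expect_error(parse_pocket_report(fpocket_report(100, drop_volume = TRUE)),
               "volume.*pocket 1|pocket 1")
  expect_error(parse_pocket_report("Pocket 3 :\n\tVolume : \tnotanumber\n"),
               "pocket 3")
})

test_that("the two-thirds CDR rule is inclusive at the boundary", {
  mapped <- data.frame(serial = 1:12,
                       region = c(rep("CDR-H1", 8), rep("FR", 4)))
  p_8of12 <- list(pocket_id = 1, volume = 100, lining_serials = 1:12)
  expect_equal(cdr_fraction(p_8of12, mapped), 8 / 12)
  expect_true(is_cdr_pocket(p_8of12, mapped))   # 0.6667 >= 2/3, inclusive

  p_7of12 <- list(pocket_id = 2, volume = 100, lining_serials = c(1:7, 9:12, 12))
  mapped2 <- data.frame(serial = 1:12,
                        region = c(rep("CDR-H1", 7), rep("FR", 5)))
  expect_equal(cdr_fraction(p_7of12, mapped2), 7 / 12)
  expect_false(is_cdr_pocket(p_7of12, mapped2))

  p_fr <- list(pocket_id = 3, volume = 100, lining_serials = 8:12)
  expect_equal(cdr_fraction(p_fr, mapped2), 0)
  expect_false(is_cdr_pocket(p_fr, mapped2))
})

test_that("cdr_fraction errors on unmappable lining atoms", {
  mapped <- data.frame(serial = 1:5, region = c(rep("CDR-H1", 3), NA, "FR"))
  p_missing <- list(pocket_id = 1, volume = 10, lining_serials = c(1, 99))
  expect_error(cdr_fraction(p_missing, mapped), "99")
  p_unnumbered <- list(pocket_id = 2, volume = 10, lining_serials = c(1, 4))
  expect_error(cdr_fraction(p_unnumbered, mapped), "4")
  p_empty <- list(pocket_id = 3, volume = 10, lining_serials = integer(0))
  expect_error(cdr_fraction(p_empty, mapped), "no lining atoms")
})

test_that("CDR cavity volume sums only pockets passing the rule", {
  mapped <- data.frame(serial = 1:30,
                       region = c(rep("CDR-H3", 20), rep("FR", 10)))
  pockets <- structure(list(
    list(pocket_id = 1, volume = 150, lining_serials = c(1:8, 21:22)),   # 0.8
    list(pocket_id = 2, volume = 300, lining_serials = c(1:5, 21:25)),   # 0.5
    list(pocket_id = 3, volume = 200, lining_serials = 9:16)             # 1.0
  ), class = "pocket_set")
  res <- cdr_cavity_volume(pockets, mapped)
  expect_equal(res$total_volume, 350)
  expect_equal(res$cdr_pockets, c(1, 3))
  expect_equal(unname(res$per_pocket_cdr_fraction), c(0.8, 0.5, 1.0))

  empty <- structure(list(), class = "pocket_set")
  expect_equal(cdr_cavity_volume(empty, mapped)$total_volume, 0)
})

test_that("a convex compact cluster has no pockets", {
  # close-packed blob: 50 carbons on a jittered grid
  set.seed(4)
  g <- as.matrix(expand.grid(x = seq(0, 12, 3), y = seq(0, 9, 3),
                             z = seq(0, 6, 3)))[1:50, ]
  g <- g + matrix(runif(150, -0.3, 0.3), ncol = 3)
  pk <- detect_pockets(carbon_atoms(g))
  expect_length(pk, 0)
})

test_that("hollow shell pocket volume matches the Monte-Carlo interior oracle", {
  synth <- synthetic_structure("hollow_shell", shell_radius = 7.8,
                               mouth_half_angle = 18)
  shell_atoms <- synth$fv$atoms[synth$fv$atoms$chain == "H", ]
  pk <- detect_pockets(shell_atoms)
  expect_length(pk, 1)

  mc <- monte_carlo_interior_volume(shell_atoms, center = c(0, 0, 0),
                                    enclosing_radius = synth$shell_radius,
                                    n_samples = 2e5, seed = 13)
  expect_lt(abs(pk[[1]]$volume - mc$volume) / mc$volume, 0.15)
  expect_gt(length(pk[[1]]$lining_serials), 0)
})

test_that("detector volumes are invariant under translation", {
  synth <- synthetic_structure("hollow_shell")
  shell_atoms <- synth$fv$atoms[synth$fv$atoms$chain == "H", ]
  pk <- detect_pockets(shell_atoms)
  moved <- shell_atoms
  moved$x <- moved$x + 100
  pk_moved <- detect_pockets(moved)
  expect_length(pk_moved, length(pk))
  expect_equal(pk_moved[[1]]$volume, pk[[1]]$volume)
})

test_that("filling a cavity shrinks the detected volume", {
  synth <- synthetic_structure("hollow_shell")
  shell_atoms <- synth$fv$atoms[synth$fv$atoms$chain == "H", ]
  pk <- detect_pockets(shell_atoms)
  blockers <- carbon_atoms(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0),
                                 c(0, 0, 2), c(-2, 0, 0)))
  blockers$serial <- max(shell_atoms$serial) + seq_len(nrow(blockers))
  filled <- rbind(shell_atoms[, c("serial", "element", "x", "y", "z")],
                  blockers)
  pk_filled <- detect_pockets(filled)
  vol_filled <- if (length(pk_filled)) sum(vapply(pk_filled, `[[`,
                                                  numeric(1), "volume")) else 0
  expect_lt(vol_filled, pk[[1]]$volume)
})

test_that("structures below the atom threshold are rejected", {
  expect_error(detect_pockets(carbon_atoms(matrix(rnorm(30), ncol = 3))),
               "too small")
})
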