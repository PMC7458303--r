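test_that("parse_pdb returns the two chains with waters and heteroatoms dropped", {
  fv <- parse_pdb(minimal_fv_pdb(), "H", "L")
  expect_s3_class(fv, "fv_structure")
  expect_equal(nrow(fv$atoms), 9)
  expect_equal(nrow(fv_residues(fv)), 2)
  expect_setequal(unique(fv$atoms$chain), c("H", "L"))

  with_water <- minimal_fv_pdb(
    pdb_atom_line(10, "O", "HOH", "H", 99, 5, 5, 5, record = "HETATM"))
  fv2 <- parse_pdb(with_water, "H", "L")
  expect_equal(fv2$atoms, fv$atoms)
})

test_that("parse_pdb keeps only blank or 'A' alternate locations", {
  with_alt <- minimal_fv_pdb(c(
    pdb_atom_line(10, "CB", "ALA", "L", 2, 25, 0, 0, altloc = "A"),
    pdb_atom_line(11, "CB", "ALA", "L", 2, 26, 0, 0, altloc = "B")))
  fv <- parse_pdb(with_alt, "H", "L")
  expect_equal(nrow(fv$atoms), 10)
  expect_false(any(fv$atoms$altloc == "B"))
  expect_true(any(fv$atoms$altloc == "A"))
})

test_that("parse_pdb errors name the missing chain and the bad line", {
  expect_error(parse_pdb(minimal_fv_pdb(), "H", "Z"), "chain Z not found")
  broken <- paste(c(pdb_atom_line(1, "CA", "GLY", "H", 1, 0, 0, 0),
                    "ATOM      2  CA  GLY H   2      badcoords"),
                  collapse = "\n")
  expect_error(parse_pdb(broken, "H", "L"), "line 2")
})

test_that("read_numbering parses entries in order and validates input", {
  csv <- paste("chain,seq_index,kabat_number,insertion,residue",
               "H,1,26,,G", "H,2,27,,F", "H,3,52,A,S", sep = "\n")
  num <- read_numbering(csv)
  expect_equal(nrow(num), 3)
  expect_equal(num$insertion, c("", "", "A"))
  expect_equal(num$kabat_number, c(26L, 27L, 52L))

  expect_error(read_numbering("chain,seq_index,kabat_number,insertion,residue"),
               "no entries")
  dup <- paste("chain,seq_index,kabat_number,insertion,residue",
               "H,1,26,,G", "H,1,27,,F", sep = "\n")
  expect_error(read_numbering(dup), "duplicate")
  bad <- paste("chain,seq_index,kabat_number,insertion,residue",
               "H,1,26A,,G", sep = "\n")
  expect_error(read_numbering(bad), "non-integer kabat_number")
})

test_that("expanded heavy-chain CDR definitions include positions 26-30 and 49", {
  ann <- annotate_regions(full_numbering())
  h <- ann[ann$chain_role == "H", ]
  expect_equal(h$region[h$kabat_number == 30], "CDR-H1")
  expect_equal(h$region[h$kabat_number == 26], "CDR-H1")
  expect_equal(h$region[h$kabat_number == 49], "CDR-H2")
  expect_equal(h$region[h$kabat_number == 25], "FR")
  expect_equal(h$region[h$kabat_number == 66], "FR")
  expect_equal(h$region[h$kabat_number == 95], "CDR-H3")
  expect_equal(h$region[h$kabat_number == 102], "CDR-H3")
})

test_that("light-chain CDRs use classical Kabat ranges", {
  ann <- annotate_regions(full_numbering())
  l <- ann[ann$chain_role == "L", ]
  expect_equal(l$region[l$kabat_number == 24], "CDR-L1")
  expect_equal(l$region[l$kabat_number == 34], "CDR-L1")
  expect_equal(l$region[l$kabat_number == 35], "FR")
  expect_equal(l$region[l$kabat_number == 50], "CDR-L2")
  expect_equal(l$region[l$kabat_number == 89], "CDR-L3")
  expect_equal(l$region[l$kabat_number == 98], "FR")
})

test_that("every numbered residue gets exactly one label and h2_turn is inside CDR-H2", {
  num <- rbind(full_numbering(),
               make_numbering("H", c(35L, 52L, 100L), insertion = "A"))
  class(num) <- c("kabat_numbering", "data.frame")
  num$seq_index <- stats::ave(num$kabat_number, num$chain, FUN = seq_along)
  ann <- annotate_regions(num)
  expect_false(anyNA(ann$region))
  expect_true(all(ann$region %in% c("CDR-H1", "CDR-H2", "CDR-H3",
                                    "CDR-L1", "CDR-L2", "CDR-L3", "FR")))
  expect_true(all(ann$region[ann$h2_turn] == "CDR-H2"))
  # insertion-coded positions fall in their base number's range
  ins <- ann[ann$insertion == "A", ]
  expect_equal(ins$region[ins$kabat_number == 35], "CDR-H1")
  expect_equal(ins$region[ins$kabat_number == 100], "CDR-H3")
  expect_true(ins$h2_turn[ins$kabat_number == 52])
  # determinism
  expect_identical(ann, annotate_regions(num))
})

test_that("glycine count at the CDR-H2 turn counts positions 52-56", {
  res <- rep("A", 102)
  res[52:56] <- c("G", "G", "S", "I", "S")
  ann <- annotate_regions(full_numbering(h_residues = NULL))
  ann$residue[ann$chain_role == "H"] <- res
  expect_equal(h2_turn_gly_count(ann), 2)
  expect_equal(gly_present(h2_turn_gly_count(ann)), 1L)

  ann$residue[ann$chain_role == "H"][52:56] <- c("N", "P", "S", "L", "K")
  expect_equal(h2_turn_gly_count(ann), 0)
  expect_equal(gly_present(0), 0L)
})

test_that("CDR-H3 length counts numbered residues 95-102 with insertions", {
  ann <- annotate_regions(full_numbering())
  expect_equal(cdr_h3_length(ann), 8)

  num <- rbind(full_numbering(),
               make_numbering("H", c(100L, 100L, 100L),
                              insertion = c("A", "B", "C")))
  class(num) <- c("kabat_numbering", "data.frame")
  num$seq_index <- stats::ave(num$kabat_number, num$chain, FUN = seq_along)
  expect_equal(cdr_h3_length(annotate_regions(num)), 11)

  short <- rbind(make_numbering("H", 1:94), make_numbering("L", 1:10))
  class(short) <- c("kabat_numbering", "data.frame")
  expect_equal(cdr_h3_length(annotate_regions(short)), 0)
})
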