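# Shared in-code fixtures: a minimal two-residue Fv PDB and its numbering.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM", element = substr(name, 1, 1),
                          altloc = " ", icode = " ") {
  sprintf("%-6s%5d  %-3s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resno, icode,
          x, y, z, 1, 0, element)
}

minimal_fv_pdb <- function(extra_lines = character(0)) {
  lines <- c(
    pdb_atom_line(1, "N",  "GLY", "H", 1, 0.0, 0.0, 0.0),
    pdb_atom_line(2, "CA", "GLY", "H", 1, 1.5, 0.0, 0.0),
    pdb_atom_line(3, "C",  "GLY", "H", 1, 2.2, 1.3, 0.0),
    pdb_atom_line(4, "O",  "GLY", "H", 1, 1.6, 2.4, 0.0),
    pdb_atom_line(5, "N",  "ALA", "L", 1, 20.0, 0.0, 0.0),
    pdb_atom_line(6, "CA", "ALA", "L", 1, 21.5, 0.0, 0.0),
    pdb_atom_line(7, "C",  "ALA", "L", 1, 22.2, 1.3, 0.0),
    pdb_atom_line(8, "O",  "ALA", "L", 1, 21.6, 2.4, 0.0),
    pdb_atom_line(9, "CB", "ALA", "L", 1, 22.1, -1.3, 0.0),
    extra_lines,
    "END"
  )
  paste(lines, collapse = "\n")
}

minimal_numbering_csv <- function() {
  paste("chain,seq_index,kabat_number,insertion,residue",
        "H,1,26,,G",
        "L,1,24,,A",
        sep = "\n")
}

# Numbering table built directly (no CSV round trip) for annotation tests.
make_numbering <- function(chain, kabat, insertion = "", residue = "G") {
  n <- length(kabat)
  out <- data.frame(chain = rep_len(chain, n),
                    seq_index = stats::ave(kabat, rep_len(chain, n),
                                           FUN = seq_along),
                    kabat_number = as.integer(kabat),
                    insertion = rep_len(insertion, n),
                    residue = rep_len(residue, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("kabat_numbering", "data.frame")
  out
}

# Both-chain numbering covering a realistic span of Kabat positions.
full_numbering <- function(h_residues = NULL) {
  h <- make_numbering("H", 1:102)
  if (!is.null(h_residues)) h$residue <- rep_len(h_residues, nrow(h))
  l <- make_numbering("L", 1:100, residue = "A")
  out <- rbind(h, l)
  class(out) <- c("kabat_numbering", "data.frame")
  out
}

# Analytic exposed area of one of two equal spheres (radius R, centers d
# apart): total area minus the buried spherical cap.
two_sphere_exposed_area <- function(R1, R2, d) {
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1)
}

carbon_atoms <- function(xyz) {
  data.frame(serial = seq_len(nrow(xyz)), element = "C",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}
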