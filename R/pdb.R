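#' Parse an antibody Fv structure from PDB text
#'
#' Reads ATOM records for a heavy/light chain pair, drops waters, heteroatom
#' records and alternate locations other than blank or 'A', and returns the
#' atom table of the two-chain variable fragment. Elements missing from the
#' element column are inferred from the atom-name field.
#'
#' @param pdb_text Character scalar (full PDB file content) or character
#'   vector of lines. A path to an existing file is also accepted.
#' @param heavy_chain_id,light_chain_id Chain identifiers of the heavy and
#'   light variable domains.
#' @param source_id Free-text identifier stored with the structure (e.g. a
#'   PDB code); defaults to `""`.
#'
#' @return An object of class `fv_structure`: a list with `atoms` (data.frame
#'   with columns `serial`, `name`, `element`, `chain`, `resname`, `resno`,
#'   `insert`, `x`, `y`, `z`, `occupancy`, `altloc`), `heavy_chain_id`,
#'   `light_chain_id`, `source_id`, and `has_hydrogens`.
#' @export
parse_pdb <- function(pdb_text, heavy_chain_id = "H", light_chain_id = "L",
                      source_id = "") {
  lines <- pdb_lines(pdb_text)
  validate_atom_lines(lines)

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom

  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD", "H2O")), , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]

  for (ch in c(heavy_chain_id, light_chain_id)) {
    if (!any(at$chain == ch, na.rm = TRUE)) {
      stop("chain ", ch, " not found in PDB input", call. = FALSE)
    }
  }
  at <- at[at$chain %in% c(heavy_chain_id, light_chain_id), , drop = FALSE]

  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    element[missing_el] <- infer_element(at$elety[missing_el])
  }

  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = toupper(element),
    chain = at$chain,
    resname = at$resid,
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )

  structure(
    list(atoms = atoms,
         heavy_chain_id = heavy_chain_id,
         light_chain_id = light_chain_id,
         source_id = source_id,
         has_hydrogens = any(atoms$element == "H")),
    class = "fv_structure"
  )
}

#' @export
print.fv_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "insert")]))
  cat("Fv structure", if (nzchar(x$source_id)) paste0("[", x$source_id, "]"),
      "-", nrow(x$atoms), "atoms,", nres, "residues",
      sprintf("(H=%s, L=%s, %s)\n", x$heavy_chain_id, x$light_chain_id,
              if (x$has_hydrogens) "with hydrogens" else "heavy atoms only"))
  invisible(x)
}

pdb_lines <- function(pdb_text) {
  if (length(pdb_text) == 1 && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    return(readLines(pdb_text, warn = FALSE))
  }
  if (length(pdb_text) == 1) {
    return(strsplit(pdb_text, "\n", fixed = TRUE)[[1]])
  }
  pdb_text
}

validate_atom_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (nchar(ln) < 54 || anyNA(coords)) {
      stop("unparseable ATOM record at line ", i, call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Element from the PDB atom-name field: letters only, leading digits dropped
# (e.g. "1HB" is a hydrogen); names starting with H after digit-stripping are
# hydrogens, otherwise the first letter is the element for standard protein
# atoms (C, N, O, S).
infer_element <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[^A-Za-z]", "", nm)
    if (!nzchar(nm)) stop("atom name with no element information", call. = FALSE)
    first <- toupper(substr(nm, 1, 1))
    if (first %in% c("C", "N", "O", "S", "H")) first else toupper(nm)
  }, character(1), USE.NAMES = FALSE)
}

#' Residue table of an Fv structure
#'
#' One row per residue, in file order within each chain, with the ordinal
#' `seq_index` used to join structures to numbering tables.
#'
#' @param fv An `fv_structure`.
#' @return data.frame with `chain`, `seq_index`, `resno`, `insert`, `resname`.
#' @export
fv_residues <- function(fv) {
  stopifnot(inherits(fv, "fv_structure"))
  a <- fv$atoms
  out <- do.call(rbind, lapply(split(a, a$chain), function(ch) {
    key <- paste(ch$resno, ch$insert)
    first <- !duplicated(key)
    data.frame(chain = ch$chain[first],
               seq_index = seq_len(sum(first)),
               resno = ch$resno[first],
               insert = ch$insert[first],
               resname = ch$resname[first],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
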