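#' Parse an fpocket-style pocket report
#'
#' Reads the per-pocket information text produced by pocket-detection
#' programs in the fpocket dialect (`Pocket <id> :` blocks with a
#' `Volume : <value>` line) together with per-pocket atom listings, and
#' returns the pocket list used by the CDR cavity rule.
#'
#' @param report_text Info text (scalar, lines, or a file path) listing one
#'   block per pocket with at least a volume line.
#' @param pocket_atoms List mapping pocket id (name or position) to its
#'   lining atoms: either an integer vector of atom serial numbers or
#'   PDB-format text of the pocket's atoms (serials are extracted).
#' @return A `pocket_set`: list of pockets, each with `pocket_id`, `volume`
#'   (cubic Angstrom), and `lining_serials`.
#' @export
parse_pocket_report <- function(report_text, pocket_atoms = NULL) {
  if (length(report_text) == 1 && !grepl("\n", report_text) &&
      file.exists(report_text)) {
    lines <- readLines(report_text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(report_text, "\n", fixed = TRUE))
  }
  starts <- grep("^\\s*Pocket\\s+[0-9]+", lines)
  if (!length(starts)) return(new_pocket_set(list()))

  ids <- as.integer(sub("^\\s*Pocket\\s+([0-9]+).*", "\\1", lines[starts]))
  ends <- c(starts[-1] - 1, length(lines))
  pockets <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    vline <- grep("^\\s*(Real volume|Volume)\\s*[:=]", block, value = TRUE)
    if (!length(vline)) {
      stop("no volume reported for pocket ", ids[k], call. = FALSE)
    }
    vol <- suppressWarnings(as.numeric(sub(".*[:=]\\s*", "", vline[1])))
    if (is.na(vol)) {
      stop("malformed volume field for pocket ", ids[k], call. = FALSE)
    }
    serials <- integer(0)
    if (!is.null(pocket_atoms)) {
      key <- if (!is.null(names(pocket_atoms))) as.character(ids[k]) else k
      pa <- pocket_atoms[[key]]
      if (!is.null(pa)) {
        serials <- if (is.numeric(pa)) as.integer(pa) else pdb_atom_serials(pa)
      }
    }
    pockets[[k]] <- list(pocket_id = ids[k], volume = vol,
                         lining_serials = serials)
  }
  new_pocket_set(pockets)
}

pdb_atom_serials <- function(pdb_text) {
  lines <- unlist(strsplit(pdb_text, "\n", fixed = TRUE))
  at <- lines[substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")]
  as.integer(substr(at, 7, 11))
}

new_pocket_set <- function(pockets) {
  structure(pockets, class = "pocket_set")
}

#' @export
print.pocket_set <- function(x, ...) {
  cat("Pocket set:", length(x), "pocket(s)\n")
  for (p in x) {
    cat(sprintf("  pocket %d: volume %.1f A^3, %d lining atoms\n",
                p$pocket_id, p$volume, length(p$lining_serials)))
  }
  invisible(x)
}

#' Grid flood-fill cavity detector
#'
#' Offline cavity detector requiring no external program. A cubic grid is
#' laid over the structure; grid points inside any probe-expanded atom sphere
#' are solvent-excluded, exterior points are found by flood fill from the box
#' boundary through non-excluded points, and cavity points are the remaining
#' interior points plus mouth points recovered by a limited dilation into the
#' exterior. Connected components above a minimum size are reported as
#' pockets; volume is the point count times the grid cell volume.
#'
#' @param atoms Atom data.frame (needs `x`, `y`, `z`, `element`, `serial`).
#' @param probe_radius Probe used to expand atom spheres (default 1.4 A).
#' @param grid_spacing Grid resolution in Angstrom (default 1.0).
#' @param min_points Minimum connected-component size to report (default 30).
#' @param lining_cutoff Atoms within this distance (A) of any pocket point
#'   are its lining atoms (default 4.5).
#' @param mouth_depth Dilation depth (cells) recovering pocket mouths
#'   (default 2).
#' @param radii Radii table from [default_radii()].
#' @return A `pocket_set` (see [parse_pocket_report()]); each pocket also
#'   carries a `centroid`.
#' @export
detect_pockets <- function(atoms, probe_radius = NULL, grid_spacing = 1.0,
                           min_points = 30, lining_cutoff = 4.5,
                           mouth_depth = 2, radii = default_radii()) {
  atoms <- complete_atom_columns(atoms)
  if (nrow(atoms) < 20) stop("structure too small for pocket detection",
                             call. = FALSE)
  if (!is.null(probe_radius)) radii$probe_radius <- probe_radius

  partner <- assign_h_partners(atoms)
  r <- vapply(seq_len(nrow(atoms)), function(i) {
    atom_radius(atoms$element[i], partner[i], radii)
  }, numeric(1))
  keep <- !is.na(r)
  atoms <- atoms[keep, , drop = FALSE]
  R <- r[keep] + radii$probe_radius

  h <- grid_spacing
  pad <- max(R) + 2 * h
  x0 <- c(min(atoms$x), min(atoms$y), min(atoms$z)) - pad
  x1 <- c(max(atoms$x), max(atoms$y), max(atoms$z)) + pad
  dims <- pmax(ceiling((x1 - x0) / h) + 1L, 3L)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]

  # 0 free, 1 excluded, 2 exterior, 3 cavity
  state <- array(0L, dim = dims)
  gx <- x0[1] + (seq_len(nx) - 1) * h
  gy <- x0[2] + (seq_len(ny) - 1) * h
  gz <- x0[3] + (seq_len(nz) - 1) * h

  for (i in seq_len(nrow(atoms))) {
    ra <- R[i]
    ix <- which(abs(gx - atoms$x[i]) <= ra)
    iy <- which(abs(gy - atoms$y[i]) <= ra)
    iz <- which(abs(gz - atoms$z[i]) <= ra)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - atoms$x[i])^2
    dy2 <- (gy[iy] - atoms$y[i])^2
    dz2 <- (gz[iz] - atoms$z[i])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= ra^2
    sub <- state[ix, iy, iz, drop = FALSE]
    sub[inside] <- 1L
    state[ix, iy, iz] <- sub
  }

  # flood fill exterior from all boundary cells (6-connectivity)
  lin <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * as.integer(nx * ny)
  boundary <- c(
    lin(rep(c(1L, nx), each = ny * nz),
        rep(rep(seq_len(ny), times = nz), 2),
        rep(rep(seq_len(nz), each = ny), 2)),
    lin(rep(rep(seq_len(nx), times = nz), 2),
        rep(c(1L, ny), each = nx * nz),
        rep(rep(seq_len(nz), each = nx), 2)),
    lin(rep(rep(seq_len(nx), times = ny), 2),
        rep(rep(seq_len(ny), each = nx), 2),
        rep(c(1L, nz), each = nx * ny))
  )
  frontier <- unique(boundary[state[boundary] == 0L])
  state[frontier] <- 2L
  nxy <- as.integer(nx * ny)
  ncell <- as.integer(nx * ny * nz)
  neighbors6 <- function(cells) {
    i <- ((cells - 1L) %% nx) + 1L
    j <- (((cells - 1L) %/% nx) %% ny) + 1L
    k <- ((cells - 1L) %/% nxy) + 1L
    out <- c(cells[i > 1L] - 1L, cells[i < nx] + 1L,
             cells[j > 1L] - nx, cells[j < ny] + nx,
             cells[k > 1L] - nxy, cells[k < nz] + nxy)
    unique(out)
  }
  while (length(frontier)) {
    nb <- neighbors6(frontier)
    nb <- nb[state[nb] == 0L]
    state[nb] <- 2L
    frontier <- nb
  }

  cavity <- which(state == 0L)
  state[cavity] <- 3L
  # recover mouth points: dilate cavity into exterior, limited depth
  front <- cavity
  for (d in seq_len(mouth_depth)) {
    if (!length(front)) break
    nb <- neighbors6(front)
    nb <- nb[state[nb] == 2L]
    state[nb] <- 3L
    front <- nb
  }
  cavity <- which(state == 3L)
  if (!length(cavity)) return(new_pocket_set(list()))

  # connected components over cavity cells
  incav <- logical(ncell); incav[cavity] <- TRUE
  visited <- logical(ncell)
  comps <- list()
  for (seed in cavity) {
    if (visited[seed]) next
    members <- seed
    visited[seed] <- TRUE
    front <- seed
    while (length(front)) {
      nb <- neighbors6(front)
      nb <- nb[incav[nb] & !visited[nb]]
      visited[nb] <- TRUE
      members <- c(members, nb)
      front <- nb
    }
    if (length(members) >= min_points) comps[[length(comps) + 1L]] <- members
  }
  if (!length(comps)) return(new_pocket_set(list()))

  cell_vol <- h^3
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pockets <- lapply(seq_along(comps), function(k) {
    cells <- comps[[k]]
    i <- ((cells - 1L) %% nx) + 1L
    j <- (((cells - 1L) %/% nx) %% ny) + 1L
    kk <- ((cells - 1L) %/% nxy) + 1L
    pts <- cbind(gx[i], gy[j], gz[kk])
    near <- vapply(seq_len(nrow(xyz)), function(a) {
      min((pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
            (pts[, 3] - xyz[a, 3])^2) <= lining_cutoff^2
    }, logical(1))
    list(pocket_id = k,
         volume = length(cells) * cell_vol,
         lining_serials = atoms$serial[near],
         centroid = colMeans(pts))
  })
  new_pocket_set(pockets)
}

#' Fraction of a pocket's lining atoms in CDR residues
#'
#' A pocket is assigned to the CDR region when at least two thirds of its
#' surrounding (lining) atoms belong to CDR residues; the threshold is
#' inclusive.
#'
#' @param pocket One element of a `pocket_set`.
#' @param mapped_atoms Atom table with region labels from [atom_regions()]
#'   (needs `serial` and `region` columns).
#' @return Fraction in `[0, 1]`.
#' @export
cdr_fraction <- function(pocket, mapped_atoms) {
  if (!length(pocket$lining_serials)) {
    stop("pocket ", pocket$pocket_id, " has no lining atoms", call. = FALSE)
  }
  hit <- match(pocket$lining_serials, mapped_atoms$serial)
  if (anyNA(hit)) {
    stop("lining atom serial(s) absent from structure: ",
         paste(pocket$lining_serials[is.na(hit)], collapse = ", "),
         call. = FALSE)
  }
  reg <- mapped_atoms$region[hit]
  if (anyNA(reg)) {
    stop("lining atom(s) not mappable to a numbered residue: serial(s) ",
         paste(pocket$lining_serials[is.na(reg)], collapse = ", "),
         call. = FALSE)
  }
  mean(reg != "FR")
}

#' @rdname cdr_fraction
#' @param threshold Inclusive CDR-assignment threshold (default 2/3).
#' @export
is_cdr_pocket <- function(pocket, mapped_atoms, threshold = 2 / 3) {
  cdr_fraction(pocket, mapped_atoms) >= threshold
}

#' Total cavity volume at the CDR region
#'
#' Applies the two-thirds lining-atom rule to every pocket and sums the
#' volumes of those assigned to the CDR region. This is the cavity-volume
#' feature of the immunogenicity classifier: non-immunogenic antibodies tend
#' to have a large central cavity between the heavy- and light-chain CDRs.
#'
#' @param pockets A `pocket_set` (from [detect_pockets()] or
#'   [parse_pocket_report()]).
#' @param mapped_atoms Atom table with region labels from [atom_regions()].
#' @param threshold Inclusive CDR-assignment threshold (default 2/3).
#' @return List with `total_volume` (cubic Angstrom), `cdr_pockets`
#'   (pocket ids), and `per_pocket_cdr_fraction`.
#' @export
cdr_cavity_volume <- function(pockets, mapped_atoms, threshold = 2 / 3) {
  fr <- vapply(pockets, cdr_fraction, numeric(1), mapped_atoms = mapped_atoms)
  sel <- fr >= threshold
  list(
    total_volume = sum(vapply(pockets[sel], `[[`, numeric(1), "volume")),
    cdr_pockets = vapply(pockets[sel], `[[`, numeric(1), "pocket_id"),
    per_pocket_cdr_fraction = stats::setNames(
      fr, vapply(pockets, `[[`, numeric(1), "pocket_id"))
  )
}
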