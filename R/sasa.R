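#' Atomic radii used for surface calculations
#'
#' Radii (in Angstrom) for the elements occurring in protein structures:
#' carbon 1.8, nitrogen 1.65, oxygen 1.4, sulfur 1.85, polar hydrogen 1.0.
#' Non-polar hydrogens (bonded to carbon) are excluded from surface
#' computation altogether. The solvent probe is 1.4 A.
#'
#' @param overrides Named numeric vector of per-element radius overrides.
#' @return Named list with `radii` (named numeric vector) and `probe_radius`.
#' @export
default_radii <- function(overrides = NULL) {
  radii <- c(C = 1.8, N = 1.65, O = 1.4, S = 1.85, H = 1.0)
  if (!is.null(overrides)) {
    stopifnot(all(overrides > 0))
    radii[names(overrides)] <- overrides
  }
  list(radii = radii, probe_radius = 1.4)
}

#' Radius of a single atom, given its covalent partner
#'
#' Hydrogens take their role from the bonded heavy atom: bonded to carbon
#' they are non-polar and excluded (returns `NA`); bonded to N, O or S they
#' are polar with radius 1.0 A.
#'
#' @param element Element symbol of the atom.
#' @param bonded_to Element symbol of the covalent partner (only used for
#'   hydrogens); `NA` allowed for heavy atoms.
#' @param radii A radii table from [default_radii()].
#' @return Radius in Angstrom, or `NA_real_` for excluded (non-polar H) atoms.
#' @export
atom_radius <- function(element, bonded_to = NA_character_,
                        radii = default_radii()) {
  element <- toupper(element)
  if (element == "H") {
    if (is.na(bonded_to)) {
      stop("hydrogen with no covalent partner assigned", call. = FALSE)
    }
    if (toupper(bonded_to) == "C") return(NA_real_)
    if (toupper(bonded_to) %in% c("N", "O", "S")) return(radii$radii[["H"]])
    stop("hydrogen bonded to unsupported element ", bonded_to, call. = FALSE)
  }
  if (!element %in% names(radii$radii)) {
    stop("unsupported element: ", element, call. = FALSE)
  }
  radii$radii[[element]]
}

# Nearest heavy atom within `cutoff` of each hydrogen; NA when none.
assign_h_partners <- function(atoms, cutoff = 1.3) {
  partner <- rep(NA_character_, nrow(atoms))
  hs <- which(atoms$element == "H")
  if (!length(hs)) return(partner)
  heavy <- which(atoms$element != "H")
  hx <- as.matrix(atoms[heavy, c("x", "y", "z")])
  for (i in hs) {
    d2 <- (hx[, 1] - atoms$x[i])^2 + (hx[, 2] - atoms$y[i])^2 +
      (hx[, 3] - atoms$z[i])^2
    j <- which.min(d2)
    if (length(j) && d2[j] <= cutoff^2) partner[i] <- atoms$element[heavy[j]]
  }
  partner
}

#' Classify atoms as hydrophobic
#'
#' Carbon, sulfur and nitrogen atoms count as hydrophobic, except the
#' non-protonated nitrogen of the histidine side chain (ND1/NE2 without an
#' attached hydrogen). Oxygen and hydrogen are not hydrophobic. When the
#' structure carries no hydrogens at all, histidines default to the
#' NE2-protonated tautomer: NE2 is treated as protonated (hydrophobic) and
#' ND1 as non-protonated.
#'
#' @param atoms Atom data.frame (columns `name`, `element`, `resname`,
#'   `chain`, `resno`, `insert`, coordinates).
#' @return Logical vector, one entry per atom.
#' @export
is_hydrophobic_atom <- function(atoms) {
  el <- toupper(atoms$element)
  hydro <- el %in% c("C", "S", "N")

  his_n <- which(atoms$resname == "HIS" & atoms$name %in% c("ND1", "NE2"))
  if (length(his_n)) {
    has_h <- any(el == "H")
    for (i in his_n) {
      if (has_h) {
        hs <- which(el == "H" & atoms$chain == atoms$chain[i] &
                      atoms$resno == atoms$resno[i] &
                      atoms$insert == atoms$insert[i])
        protonated <- length(hs) > 0 && any(
          (atoms$x[hs] - atoms$x[i])^2 + (atoms$y[hs] - atoms$y[i])^2 +
            (atoms$z[hs] - atoms$z[i])^2 <= 1.3^2)
      } else {
        protonated <- atoms$name[i] == "NE2"
      }
      if (!protonated) hydro[i] <- FALSE
    }
  }
  hydro
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Deterministic SASA by test points on each atom's probe-expanded sphere
#' (quasi-uniform Fibonacci point set). Per-atom area is the exposed-point
#' fraction times the expanded-sphere area \eqn{4\pi (r + p)^2}.
#'
#' @param atoms Atom data.frame with columns `x`, `y`, `z`, `element`, and
#'   optionally `name`, `resname` (used for hydrophobicity and hydrogen
#'   handling). Non-polar hydrogens are excluded before computation.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_sphere_points Test points per atom (default 960, minimum 60).
#' @param radii Radii table from [default_radii()].
#' @return A `sasa_result`: list with `atoms` (input rows retained in the
#'   computation, with `radius`, `area`, `hydrophobic` columns), `total_area`,
#'   `hydrophobic_area`, `hydrophobic_fraction` (percent), `n_sphere_points`,
#'   `probe_radius`, and `no_hydrogens` flag.
#' @export
shrake_rupley <- function(atoms, probe_radius = NULL, n_sphere_points = 960,
                          radii = default_radii()) {
  if (!is.null(probe_radius)) radii$probe_radius <- probe_radius
  if (n_sphere_points < 60) stop("n_sphere_points must be >= 60", call. = FALSE)
  atoms <- complete_atom_columns(atoms)

  partner <- assign_h_partners(atoms)
  r <- vapply(seq_len(nrow(atoms)), function(i) {
    atom_radius(atoms$element[i], partner[i], radii)
  }, numeric(1))
  keep <- !is.na(r)
  if (!any(keep)) stop("no included atoms for surface computation", call. = FALSE)
  atoms <- atoms[keep, , drop = FALSE]
  r <- r[keep]

  R <- r + radii$probe_radius
  n <- nrow(atoms)
  pts <- sphere_points(n_sphere_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])

  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R + R[i])^2 & d2 > 0)
    if (!length(nb)) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    px <- p[, 1] + xyz[i, 1]; py <- p[, 2] + xyz[i, 2]; pz <- p[, 3] + xyz[i, 3]
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      still <- which(exposed)
      if (!length(still)) break
      dj2 <- (px[still] - xyz[j, 1])^2 + (py[still] - xyz[j, 2])^2 +
        (pz[still] - xyz[j, 3])^2
      exposed[still[dj2 < R[j]^2]] <- FALSE
    }
    area[i] <- mean(exposed) * 4 * pi * R[i]^2
  }

  atoms$radius <- r
  atoms$area <- area
  atoms$hydrophobic <- is_hydrophobic_atom(atoms)

  structure(
    list(atoms = atoms,
         total_area = sum(area),
         hydrophobic_area = sum(area[atoms$hydrophobic]),
         hydrophobic_fraction = 100 * sum(area[atoms$hydrophobic]) / sum(area),
         n_sphere_points = n_sphere_points,
         probe_radius = radii$probe_radius,
         no_hydrogens = !any(atoms$element == "H")),
    class = "sasa_result"
  )
}

complete_atom_columns <- function(atoms) {
  atoms <- as.data.frame(atoms)
  for (col in c("name", "resname", "chain", "insert")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- ""
  }
  if (is.null(atoms$resno)) atoms$resno <- seq_len(nrow(atoms))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)), all(nzchar(atoms$element)))
  atoms
}

#' Hydrophobic surface area of a CDR region
#'
#' Computes SASA over the whole Fv (the full structure occludes), then sums
#' the areas of hydrophobic atoms belonging to residues of the requested
#' region. This is the CDR-H3 hydrophobicity feature when
#' `region = "CDR-H3"`.
#'
#' @param fv An `fv_structure`.
#' @param annotation A `region_annotation` matching the structure.
#' @param region Region label (one of the CDR labels or `"FR"`), or a vector
#'   of labels treated as a union.
#' @param ... Passed to [shrake_rupley()].
#' @return List with `hydrophobic_area`, `total_area` (both over the region,
#'   in squared Angstrom), `hydrophobic_fraction` (percent), and
#'   `no_hydrogens`.
#' @export
region_hydrophobic_area <- function(fv, annotation, region = "CDR-H3", ...) {
  mapped <- atom_regions(fv, annotation)
  if (!any(mapped$region %in% region, na.rm = TRUE)) {
    stop("region ", paste(region, collapse = "/"),
         " has no residues in this structure", call. = FALSE)
  }
  res <- shrake_rupley(mapped, ...)
  a <- res$atoms
  sel <- !is.na(a$region) & a$region %in% region
  list(hydrophobic_area = sum(a$area[sel & a$hydrophobic]),
       total_area = sum(a$area[sel]),
       hydrophobic_fraction = if (sum(a$area[sel]) > 0) {
         100 * sum(a$area[sel & a$hydrophobic]) / sum(a$area[sel])
       } else 0,
       no_hydrogens = res$no_hydrogens)
}
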