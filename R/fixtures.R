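#' Synthetic structures with known ground truth
#'
#' Builds small atom clouds whose surface areas and cavity volumes are known
#' analytically or checkable with the Monte-Carlo oracles, packaged as proper
#' Fv structures with a matching Kabat numbering so the whole feature pipeline
#' can run offline.
#'
#' Kinds:
#' * `isolated_atoms` — `n` carbon atoms spaced far apart (`spacing`, default
#'   50 A): each atom's SASA is the closed-form sphere area.
#' * `random_cluster` — `n` carbons with Gaussian coordinates (`sigma`).
#' * `hollow_shell` — carbons quasi-uniformly covering a sphere of radius
#'   `shell_radius` (atom centers), about `shell_spacing` apart, with atoms
#'   inside a polar cone of half-angle `mouth_half_angle` (degrees) removed
#'   to open a mouth; the interior is a cavity of known geometry.
#' * `buried_loop` — three glycine residues (N, CA, C, O backbone) labeled
#'   CDR-H3, surrounded by a tight carbon shell so the loop is fully buried.
#'
#' @param kind Structure kind (above).
#' @param n Number of atoms (`isolated_atoms`, `random_cluster`).
#' @param seed Integer seed for the stochastic kinds.
#' @param sigma Coordinate standard deviation for `random_cluster` (A).
#' @param spacing Atom spacing for `isolated_atoms` (A).
#' @param shell_radius,shell_spacing,mouth_half_angle Shell geometry.
#' @return List with `fv` (an `fv_structure`), `numbering`, `annotation`, and
#'   kind-specific extras (`shell_radius`, `loop_serials`, ...).
#' @export
synthetic_structure <- function(kind = c("isolated_atoms", "random_cluster",
                                         "hollow_shell", "buried_loop"),
                                n = 30, seed = 1, sigma = 4, spacing = 50,
                                shell_radius = 7.8, shell_spacing = 2.0,
                                mouth_half_angle = 18) {
  kind <- match.arg(kind)
  extras <- list()
  if (kind == "isolated_atoms") {
    xyz <- cbind(x = (seq_len(n) - 1) * spacing, y = 0, z = 0)
    heavy <- atom_rows(xyz, element = "C", chain = "H")
  } else if (kind == "random_cluster") {
    set.seed(seed)
    xyz <- matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
    heavy <- atom_rows(xyz, element = "C", chain = "H")
  } else if (kind == "hollow_shell") {
    n_shell <- max(60, round(4 * pi * shell_radius^2 / shell_spacing^2))
    pts <- sphere_points(n_shell) * shell_radius
    keep <- acos(pmin(1, pts[, 3] / shell_radius)) > mouth_half_angle * pi / 180
    xyz <- pts[keep, , drop = FALSE]
    colnames(xyz) <- c("x", "y", "z")
    heavy <- atom_rows(xyz, element = "C", chain = "H")
    extras <- list(shell_radius = shell_radius)
  } else { # buried_loop
    loop <- gly_backbone(n_res = 3, origin = c(0, 0, 0))
    # bury the loop in a carbon lattice: every probe test point on a loop
    # atom then falls inside some lattice atom's expanded sphere
    lx <- range(loop$x); ly <- range(loop$y); lz <- range(loop$z)
    g <- expand.grid(x = seq(lx[1] - 6, lx[2] + 6, by = 1.8),
                     y = seq(ly[1] - 6, ly[2] + 6, by = 1.8),
                     z = seq(lz[1] - 6, lz[2] + 6, by = 1.8))
    keep_g <- vapply(seq_len(nrow(g)), function(i) {
      min((loop$x - g$x[i])^2 + (loop$y - g$y[i])^2 +
            (loop$z - g$z[i])^2) > 2.4^2
    }, logical(1))
    shell <- atom_rows(as.matrix(g[keep_g, ]), element = "C", chain = "H",
                       resno_start = 20)
    heavy <- rbind(loop, shell)
    heavy$serial <- seq_len(nrow(heavy))
    extras <- list(loop_serials = seq_len(nrow(loop)))
  }

  light <- atom_rows(cbind(x = 200, y = 200, z = 200), element = "C",
                     chain = "L", resno_start = 1)
  light$serial <- max(heavy$serial) + seq_len(nrow(light))
  atoms <- rbind(heavy, light)

  fv <- structure(
    list(atoms = atoms, heavy_chain_id = "H", light_chain_id = "L",
         source_id = paste0("synthetic:", kind),
         has_hydrogens = any(atoms$element == "H")),
    class = "fv_structure"
  )
  numbering <- synthetic_numbering(fv, loop_resnos = if (kind == "buried_loop")
    unique(heavy$resno[heavy$serial %in% extras$loop_serials]) else integer(0))
  annotation <- annotate_regions(numbering)
  c(list(fv = fv, numbering = numbering, annotation = annotation,
         kind = kind), extras)
}

atom_rows <- function(xyz, element, chain, resno_start = 1) {
  n <- nrow(xyz)
  data.frame(serial = seq_len(n),
             name = if (element == "C") "CA" else element,
             element = element, chain = chain,
             resname = "GLY",
             resno = resno_start + seq_len(n) - 1,
             insert = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, altloc = "",
             stringsAsFactors = FALSE)
}

# Idealized glycine backbone trace: one N, CA, C, O per residue along x.
gly_backbone <- function(n_res, origin = c(0, 0, 0)) {
  rows <- list()
  serial <- 1L
  for (r in seq_len(n_res)) {
    base <- origin + c((r - 1) * 3.8, 0, 0)
    offs <- rbind(N = c(-1.3, 0.5, 0), CA = c(0, 0, 0),
                  C = c(1.2, 0.6, 0), O = c(1.4, 1.8, 0))
    for (a in rownames(offs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = a, element = substr(a, 1, 1),
        chain = "H", resname = "GLY", resno = r, insert = "",
        x = base[1] + offs[a, 1], y = base[2] + offs[a, 2],
        z = base[3] + offs[a, 3], occupancy = 1, altloc = "",
        stringsAsFactors = FALSE)
      serial <- serial + 1L
    }
  }
  do.call(rbind, rows)
}

# Numbering for a synthetic structure: loop residues get Kabat 95.., i.e.
# CDR-H3; every other residue takes a Kabat number above the CDR ranges
# (heavy 103.., light 98..) so it is framework by construction.
synthetic_numbering <- function(fv, loop_resnos = integer(0)) {
  res <- fv_residues(fv)
  kab <- integer(nrow(res))
  for (ch in unique(res$chain)) {
    sel <- res$chain == ch
    if (ch == fv$heavy_chain_id) {
      k <- rep(NA_integer_, sum(sel))
      is_loop <- res$resno[sel] %in% loop_resnos
      k[is_loop] <- 95L + seq_len(sum(is_loop)) - 1L
      k[!is_loop] <- 103L + seq_len(sum(!is_loop)) - 1L
      kab[sel] <- k
    } else {
      kab[sel] <- 98L + seq_len(sum(sel)) - 1L
    }
  }
  out <- data.frame(chain = res$chain, seq_index = res$seq_index,
                    kabat_number = kab, insertion = "",
                    residue = "G", stringsAsFactors = FALSE)
  class(out) <- c("kabat_numbering", "data.frame")
  out
}

#' Monte-Carlo solvent-accessible surface area oracle
#'
#' Independent SASA estimator: for each atom, points are sampled uniformly at
#' random on the probe-expanded sphere and counted when they fall outside all
#' other expanded spheres. Unbiased, with a binomial standard error; shares no
#' code with the deterministic Shrake-Rupley point set.
#'
#' @param atoms Atom data.frame (as for [shrake_rupley()]).
#' @param n_samples Random samples per atom (default 1e5).
#' @param seed Integer seed.
#' @inheritParams shrake_rupley
#' @return data.frame with per-atom `area` and `std_error`.
#' @export
monte_carlo_sasa <- function(atoms, n_samples = 1e5, seed = 1,
                             probe_radius = NULL, radii = default_radii()) {
  if (!is.null(probe_radius)) radii$probe_radius <- probe_radius
  atoms <- complete_atom_columns(atoms)
  partner <- assign_h_partners(atoms)
  r <- vapply(seq_len(nrow(atoms)), function(i) {
    atom_radius(atoms$element[i], partner[i], radii)
  }, numeric(1))
  keep <- !is.na(r)
  atoms <- atoms[keep, , drop = FALSE]
  R <- r[keep] + radii$probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)

  set.seed(seed)
  area <- numeric(n)
  se <- numeric(n)
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * R[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_samples)
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    for (j in which(d2 < (R + R[i])^2 & d2 > 0)) {
      still <- which(exposed)
      if (!length(still)) break
      dj2 <- (p[still, 1] - xyz[j, 1])^2 + (p[still, 2] - xyz[j, 2])^2 +
        (p[still, 3] - xyz[j, 3])^2
      exposed[still[dj2 < R[j]^2]] <- FALSE
    }
    f <- mean(exposed)
    a_tot <- 4 * pi * R[i]^2
    area[i] <- f * a_tot
    se[i] <- a_tot * sqrt(f * (1 - f) / n_samples)
  }
  data.frame(serial = atoms$serial, area = area, std_error = se)
}

#' Monte-Carlo interior (cavity) volume oracle
#'
#' Estimates the volume of the cavity region inside a synthetic shell by
#' rejection sampling: points drawn uniformly in the ball of radius
#' `enclosing_radius` about `center` count toward the cavity when they lie
#' outside every probe-expanded atom sphere. Intended for analytically
#' constructed cavities where the enclosing ball is known to contain the
#' cavity and no exterior free space.
#'
#' @param atoms Atom data.frame.
#' @param center Cavity center (length-3).
#' @param enclosing_radius Radius of the sampling ball (A).
#' @param n_samples Number of sampled points.
#' @param seed Integer seed.
#' @inheritParams shrake_rupley
#' @return List with `volume` (cubic Angstrom) and `std_error`.
#' @export
monte_carlo_interior_volume <- function(atoms, center = c(0, 0, 0),
                                        enclosing_radius, n_samples = 2e5,
                                        seed = 1, probe_radius = NULL,
                                        radii = default_radii()) {
  if (!is.null(probe_radius)) radii$probe_radius <- probe_radius
  atoms <- complete_atom_columns(atoms)
  r <- vapply(atoms$element, function(e) atom_radius(e, NA, radii), numeric(1))
  R2 <- (r + radii$probe_radius)^2
  xyz <- as.matrix(atoms[, c("x", "y", "z")])

  set.seed(seed)
  # uniform in ball: direction x radius^(1/3)
  u <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- enclosing_radius * stats::runif(n_samples)^(1 / 3)
  p <- sweep(u * rad, 2, center, "+")

  free <- rep(TRUE, n_samples)
  for (j in seq_len(nrow(xyz))) {
    still <- which(free)
    if (!length(still)) break
    d2 <- (p[still, 1] - xyz[j, 1])^2 + (p[still, 2] - xyz[j, 2])^2 +
      (p[still, 3] - xyz[j, 3])^2
    free[still[d2 <= R2[j]]] <- FALSE
  }
  f <- mean(free)
  v_ball <- 4 / 3 * pi * enclosing_radius^3
  list(volume = f * v_ball,
       std_error = v_ball * sqrt(f * (1 - f) / n_samples))
}

#' Synthetic labeled feature dataset
#'
#' Two Gaussian clusters in the (cavity volume, CDR-H3 hydrophobic area)
#' plane, labels by cluster. `separation` is the between-cluster distance in
#' units of the within-cluster standard deviation, so large values give a
#' linearly separable set and 0 gives chance-level classes.
#'
#' @param n_per_class Samples per class (>= 3).
#' @param separation Cluster separation in sigma units.
#' @param seed Integer seed.
#' @param sigma Within-cluster standard deviation (feature units).
#' @return An `antibody_dataset`-style data.frame with `antibody`,
#'   `cavity_volume`, `h3_hydrophobic_area`, `gly_count`,
#'   `gly_h2_turn_present`, `label`.
#' @export
make_feature_dataset <- function(n_per_class, separation, seed = 1,
                                 sigma = 30) {
  stopifnot(n_per_class >= 3)
  set.seed(seed)
  offset <- separation * sigma / sqrt(2)
  center0 <- c(800, 450)
  center1 <- center0 - offset
  n <- n_per_class
  f0 <- cbind(stats::rnorm(n, center0[1], sigma), stats::rnorm(n, center0[2], sigma))
  f1 <- cbind(stats::rnorm(n, center1[1], sigma), stats::rnorm(n, center1[2], sigma))
  out <- data.frame(
    antibody = paste0("syn", seq_len(2 * n)),
    cavity_volume = pmax(0, c(f1[, 1], f0[, 1])),
    h3_hydrophobic_area = pmax(0, c(f1[, 2], f0[, 2])),
    gly_count = rep(c(0L, 1L), each = n),
    label = rep(c(1L, 0L), each = n),
    stringsAsFactors = FALSE
  )
  out$gly_h2_turn_present <- gly_present(out$gly_count)
  class(out) <- c("antibody_dataset", "data.frame")
  out
}

#' Synthetic PSI-BLAST ASCII PSSM
#'
#' Renders a PSSM in the PSI-BLAST ASCII dialect for a given query sequence,
#' with self-substitution scores drawn around the BLOSUM62 diagonal minus
#' `humanness_offset` (0 gives a fully "human" profile with all humanness
#' scores 0).
#'
#' @param sequence Query sequence (1-letter codes).
#' @param humanness_offset Mean amount subtracted from each diagonal score.
#' @param seed Integer seed.
#' @return List with `text` (the ASCII PSSM) and `scores` (the matrix).
#' @export
synthetic_pssm <- function(sequence, humanness_offset = 0, seed = 1) {
  res <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(all(res %in% PSSM_ALPHABET))
  set.seed(seed)
  n <- length(res)
  scores <- matrix(sample(-4:1, n * 20, replace = TRUE), nrow = n,
                   dimnames = list(NULL, PSSM_ALPHABET))
  diag_b <- blosum62_diagonal()
  for (i in seq_len(n)) {
    jitter <- sample(0:2, 1)
    scores[i, res[i]] <- diag_b[[res[i]]] - round(humanness_offset) - jitter +
      sample(0:1, 1)
  }
  header <- paste0("\nLast position-specific scoring matrix computed\n",
                   "            ", paste(PSSM_ALPHABET, collapse = "  "), "\n")
  rows <- vapply(seq_len(n), function(i) {
    sprintf("%5d %s %s", i, res[i],
            paste(sprintf("%3d", scores[i, ]), collapse = ""))
  }, character(1))
  list(text = paste0(header, paste(rows, collapse = "\n"), "\n"),
       scores = scores)
}

#' Write a synthetic structure as PDB + numbering CSV
#'
#' Makes the full command-line path exercisable offline: the structure is
#' written in PDB format and its numbering in the
#' `chain,seq_index,kabat_number,insertion,residue` dialect.
#'
#' @param synth Result of [synthetic_structure()].
#' @param pdb_path,numbering_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_structure_files <- function(synth, pdb_path, numbering_path) {
  a <- synth$fv$atoms
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resname,
                   eleno = a$serial, elety = a$name,
                   elesy = a$element, o = a$occupancy)
  utils::write.csv(
    data.frame(chain = synth$numbering$chain,
               seq_index = synth$numbering$seq_index,
               kabat_number = synth$numbering$kabat_number,
               insertion = synth$numbering$insertion,
               residue = synth$numbering$residue),
    numbering_path, row.names = FALSE, quote = FALSE)
  invisible(c(pdb = pdb_path, numbering = numbering_path))
}
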