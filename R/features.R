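#' Extract the three immunogenicity features from a structure
#'
#' Runs the full structural pipeline on one antibody: CDR cavity volume (from
#' a supplied pocket report or, failing that, the built-in grid detector),
#' CDR-H3 hydrophobic solvent-accessible surface area, and the glycine count
#' and presence at the CDR-H2 turn.
#'
#' @param fv An `fv_structure` from [parse_pdb()].
#' @param numbering A `kabat_numbering` from [read_numbering()].
#' @param pocket_report Optional fpocket-style report text/path; when given,
#'   cavity volumes come from the parser path instead of the built-in
#'   detector.
#' @param pocket_atoms Per-pocket atom listings for the report (see
#'   [parse_pocket_report()]).
#' @param heavy_chain,light_chain Chain identifiers in the numbering table.
#' @param n_sphere_points,probe_radius Passed to the surface engine.
#' @return List with `cavity_volume`, `h3_hydrophobic_area`, `gly_count`,
#'   `gly_h2_turn_present`, and `provenance` (detector used, hydrogen
#'   handling, structure id).
#' @export
extract_features <- function(fv, numbering, pocket_report = NULL,
                             pocket_atoms = NULL,
                             heavy_chain = fv$heavy_chain_id,
                             light_chain = fv$light_chain_id,
                             n_sphere_points = 960, probe_radius = NULL) {
  annotation <- annotate_regions(numbering, heavy_chain, light_chain)
  mapped <- atom_regions(fv, annotation)

  if (!is.null(pocket_report)) {
    pockets <- parse_pocket_report(pocket_report, pocket_atoms)
    detector <- "pocket_report"
  } else {
    pockets <- detect_pockets(fv$atoms, probe_radius = probe_radius)
    detector <- "builtin_grid"
  }
  cavity <- if (length(pockets)) {
    cdr_cavity_volume(pockets, mapped)$total_volume
  } else 0

  h3 <- region_hydrophobic_area(fv, annotation, region = "CDR-H3",
                                n_sphere_points = n_sphere_points,
                                probe_radius = probe_radius)
  gcount <- h2_turn_gly_count(annotation)

  list(cavity_volume = cavity,
       h3_hydrophobic_area = h3$hydrophobic_area,
       gly_count = gcount,
       gly_h2_turn_present = gly_present(gcount),
       provenance = list(source_id = fv$source_id,
                         cavity_detector = detector,
                         no_hydrogens = h3$no_hydrogens,
                         n_sphere_points = n_sphere_points))
}
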