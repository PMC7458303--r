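#' Read a Kabat numbering table
#'
#' Consumes an ANARCI-style per-residue numbering CSV with columns
#' `chain,seq_index,kabat_number,insertion,residue`. Numbering is an input:
#' this package never assigns Kabat numbers to raw sequences.
#'
#' @param table_text CSV text (scalar or lines) or a path to a CSV file.
#' @return A `kabat_numbering` data.frame with columns `chain`, `seq_index`
#'   (integer, ordinal position of the residue in its chain), `kabat_number`
#'   (integer), `insertion` (letter or `""`), `residue` (1-letter code).
#' @export
read_numbering <- function(table_text) {
  if (length(table_text) == 1 && !grepl("\n", table_text) &&
      file.exists(table_text)) {
    df <- utils::read.csv(table_text, stringsAsFactors = FALSE,
                          colClasses = "character")
  } else {
    txt <- paste(table_text, collapse = "\n")
    df <- utils::read.csv(text = txt, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  needed <- c("chain", "seq_index", "kabat_number", "insertion", "residue")
  if (!all(needed %in% names(df))) {
    stop("numbering table must have columns ", paste(needed, collapse = ","),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("no entries in numbering table", call. = FALSE)

  kab <- suppressWarnings(as.integer(df$kabat_number))
  if (anyNA(kab)) {
    bad <- which(is.na(kab))[1]
    stop("non-integer kabat_number at row ", bad, ": '",
         df$kabat_number[is.na(kab)][1], "'", call. = FALSE)
  }
  seqi <- suppressWarnings(as.integer(df$seq_index))
  if (anyNA(seqi)) stop("non-integer seq_index", call. = FALSE)

  key <- paste(df$chain, seqi)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, seq_index) entry: ", key[duplicated(key)][1],
         call. = FALSE)
  }

  out <- data.frame(chain = df$chain,
                    seq_index = seqi,
                    kabat_number = kab,
                    insertion = ifelse(is.na(df$insertion), "", df$insertion),
                    residue = toupper(df$residue),
                    stringsAsFactors = FALSE)
  class(out) <- c("kabat_numbering", "data.frame")
  out
}

# Expanded CDR definitions (Kabat numbering). The heavy-chain loops are
# widened relative to classical Kabat: H1 takes in positions 26-30 and H2
# takes in position 49; light-chain loops are the classical Kabat ranges.
# Insertion-coded positions (35A, 52A, 100B, ...) belong to the range of
# their base number.
cdr_ranges <- function() {
  list(H = list("CDR-H1" = c(26L, 35L),
                "CDR-H2" = c(49L, 65L),
                "CDR-H3" = c(95L, 102L)),
       L = list("CDR-L1" = c(24L, 34L),
                "CDR-L2" = c(50L, 56L),
                "CDR-L3" = c(89L, 97L)))
}

H2_TURN_RANGE <- c(52L, 56L)

#' Annotate CDR and framework regions from Kabat numbers
#'
#' Assigns every numbered residue exactly one region label: one of the six
#' CDR loops or `FR` (framework). Heavy-chain loops use the expanded
#' definition (CDR-H1 Kabat 26-35 including 35A/35B, CDR-H2 49-65, CDR-H3
#' 95-102); light-chain loops are classical Kabat (L1 24-34, L2 50-56, L3
#' 89-97). The CDR-H2 beta-turn is heavy-chain Kabat 52-56 including
#' insertion-coded positions.
#'
#' @param numbering A `kabat_numbering` table from [read_numbering()].
#' @param heavy_chain,light_chain Values of the `chain` column playing the
#'   heavy and light roles.
#' @return A `region_annotation` data.frame: the numbering table plus
#'   `chain_role` (`"H"`/`"L"`), `region`, and logical `h2_turn`.
#' @export
annotate_regions <- function(numbering, heavy_chain = "H", light_chain = "L") {
  stopifnot(inherits(numbering, "kabat_numbering"))
  if (!any(numbering$chain == heavy_chain)) {
    stop("heavy chain '", heavy_chain, "' absent from numbering", call. = FALSE)
  }
  if (!any(numbering$chain == light_chain)) {
    stop("light chain '", light_chain, "' absent from numbering", call. = FALSE)
  }
  ann <- numbering[numbering$chain %in% c(heavy_chain, light_chain), ,
                   drop = FALSE]
  ann$chain_role <- ifelse(ann$chain == heavy_chain, "H", "L")

  ranges <- cdr_ranges()
  ann$region <- "FR"
  for (role in c("H", "L")) {
    sel <- ann$chain_role == role
    for (lab in names(ranges[[role]])) {
      rg <- ranges[[role]][[lab]]
      inr <- sel & ann$kabat_number >= rg[1] & ann$kabat_number <= rg[2]
      ann$region[inr] <- lab
    }
  }
  ann$h2_turn <- ann$chain_role == "H" &
    ann$kabat_number >= H2_TURN_RANGE[1] &
    ann$kabat_number <= H2_TURN_RANGE[2]

  class(ann) <- c("region_annotation", "data.frame")
  ann
}

#' Number of glycines at the CDR-H2 beta-turn
#'
#' Counts residues with 1-letter code `G` at heavy-chain Kabat positions
#' 52-56 (insertions included). Antibodies with no glycine at this turn are
#' enriched for clinical immunogenicity.
#'
#' @param annotation A `region_annotation`.
#' @return Integer count; the binary feature used by the classifier is
#'   `count > 0` (see [gly_present()]).
#' @export
h2_turn_gly_count <- function(annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  if (!any(annotation$chain_role == "H")) {
    stop("heavy chain absent from annotation", call. = FALSE)
  }
  sum(annotation$h2_turn & annotation$residue == "G")
}

#' @rdname h2_turn_gly_count
#' @param count Integer vector of glycine counts.
#' @export
gly_present <- function(count) as.integer(count > 0)

#' Length of the CDR-H3 loop
#'
#' Counts numbered heavy-chain residues at Kabat 95-102, insertions included.
#'
#' @param annotation A `region_annotation`.
#' @return Integer length (0 when the loop is absent from the numbering).
#' @export
cdr_h3_length <- function(annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  sum(annotation$region == "CDR-H3" & annotation$chain_role == "H")
}

#' Map structure atoms to region labels
#'
#' Joins an Fv atom table to a region annotation through the ordinal residue
#' index within each chain (the numbering table's `seq_index`).
#'
#' @param fv An `fv_structure`.
#' @param annotation A `region_annotation` whose `chain` values match the
#'   structure's chain identifiers.
#' @return The structure's atom data.frame with added columns `seq_index`,
#'   `chain_role`, `region`, `h2_turn` (NA for atoms of residues absent from
#'   the numbering).
#' @export
atom_regions <- function(fv, annotation) {
  stopifnot(inherits(fv, "fv_structure"), inherits(annotation, "region_annotation"))
  res <- fv_residues(fv)
  a <- fv$atoms
  ord <- match(paste(a$chain, a$resno, a$insert),
               paste(res$chain, res$resno, res$insert))
  a$seq_index <- res$seq_index[ord]
  hit <- match(paste(a$chain, a$seq_index),
               paste(annotation$chain, annotation$seq_index))
  a$chain_role <- annotation$chain_role[hit]
  a$region <- annotation$region[hit]
  a$h2_turn <- annotation$h2_turn[hit]
  a
}
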