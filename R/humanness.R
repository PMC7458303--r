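#' Diagonal of the BLOSUM62 substitution matrix
#'
#' Self-substitution scores for the 20 standard residues, used as the
#' reference in the humanness score.
#'
#' @return Named integer vector (1-letter residue codes).
#' @export
blosum62_diagonal <- function() {
  c(A = 4L, R = 5L, N = 6L, D = 6L, C = 9L, Q = 5L, E = 5L, G = 6L, H = 8L,
    I = 4L, L = 4L, K = 5L, M = 5L, F = 6L, P = 7L, S = 4L, T = 5L, W = 11L,
    Y = 7L, V = 4L)
}

PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the `-out_ascii_pssm` dialect: a header line naming the 20 residue
#' columns followed by one row per position with the position number, the
#' query residue and (at least) 20 integer log-odds scores. Only the first 20
#' score columns are used.
#'
#' @param ascii_text PSSM text (scalar, lines, or a file path).
#' @return A `pssm`: list with `positions` (integer), `query` (1-letter
#'   residues), and `scores` (positions x 20 integer matrix, columns in the
#'   header's residue order, renamed to the standard alphabet).
#' @export
read_pssm <- function(ascii_text) {
  if (length(ascii_text) == 1 && !grepl("\n", ascii_text) &&
      file.exists(ascii_text)) {
    lines <- readLines(ascii_text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(ascii_text, "\n", fixed = TRUE))
  }
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])

  header_at <- NA_integer_
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) >= 20 && all(tk[1:20] %in% PSSM_ALPHABET) &&
        !anyDuplicated(tk[1:20])) {
      header_at <- i
      break
    }
  }
  if (is.na(header_at) || header_at >= length(toks)) {
    stop("no PSSM rows", call. = FALSE)
  }
  col_order <- toks[[header_at]][1:20]

  positions <- integer(0); query <- character(0); scores <- NULL
  for (i in (header_at + 1):length(toks)) {
    tk <- toks[[i]]
    if (!length(tk)) next
    pos <- suppressWarnings(as.integer(tk[1]))
    if (is.na(pos) || length(tk) < 2) break   # footer or non-row line
    if (!(tk[2] %in% PSSM_ALPHABET)) {
      stop("unknown residue letter '", tk[2], "' at position ", pos,
           call. = FALSE)
    }
    if (length(tk) < 22) {
      stop("PSSM row with fewer than 20 scores at position ", pos,
           call. = FALSE)
    }
    vals <- suppressWarnings(as.integer(tk[3:22]))
    if (anyNA(vals)) {
      stop("non-integer score in PSSM row at position ", pos, call. = FALSE)
    }
    positions <- c(positions, pos)
    query <- c(query, tk[2])
    scores <- rbind(scores, vals)
  }
  if (!length(positions)) stop("no PSSM rows", call. = FALSE)
  colnames(scores) <- col_order
  scores <- scores[, PSSM_ALPHABET, drop = FALSE]
  rownames(scores) <- positions
  structure(list(positions = positions, query = query, scores = scores),
            class = "pssm")
}

#' Per-residue humanness score
#'
#' The humanness score of residue type `r` at a profile position with
#' self-substitution score `M_ir` is `min(M_ir - B_rr, 0)`, where `B_rr` is
#' the BLOSUM62 diagonal entry for `r`. Scores are always non-positive: zero
#' means the residue is at least as conserved in the human profile as in
#' itself; strongly negative scores flag residues rarely seen at that
#' position in human sequences.
#'
#' @param m_ir Integer self-substitution score(s) from the profile.
#' @param r 1-letter residue code(s), recycled against `m_ir`.
#' @return Numeric score(s), all `<= 0`.
#' @export
residue_humanness <- function(m_ir, r) {
  b <- blosum62_diagonal()[toupper(r)]
  if (anyNA(b)) {
    stop("nonstandard residue: ", paste(unique(r[is.na(b)]), collapse = ", "),
         call. = FALSE)
  }
  pmin(m_ir - unname(b), 0)
}

#' @rdname residue_humanness
#' @param s_human Humanness score(s).
#' @return `is_rare_residue()`: logical; a residue is rare when its humanness
#'   score is strictly below -6.
#' @export
is_rare_residue <- function(s_human) s_human < -6

#' Humanness summary over CDR and framework regions
#'
#' Sums per-position humanness scores and counts rare residues separately for
#' CDR and framework positions.
#'
#' @param pssm A `pssm` from [read_pssm()].
#' @param regions Character vector, one label per PSSM position, each one of
#'   the CDR labels, `"FR"`, or `NA` to skip a position.
#' @param allow_skip When `FALSE` (default) an `NA` region is an error;
#'   set `TRUE` to silently skip unmapped positions.
#' @return List with `per_position_score`, `cdr_sum`, `framework_sum`,
#'   `cdr_rare_count`, `framework_rare_count`.
#' @export
region_humanness <- function(pssm, regions, allow_skip = FALSE) {
  stopifnot(inherits(pssm, "pssm"))
  n <- length(pssm$positions)
  if (length(regions) != n) {
    stop("regions must have one label per PSSM position (", n, ")",
         call. = FALSE)
  }
  if (anyNA(regions) && !allow_skip) {
    stop("unmapped PSSM position(s) without skip flag: ",
         paste(pssm$positions[is.na(regions)], collapse = ", "), call. = FALSE)
  }
  m_ir <- pssm$scores[cbind(seq_len(n), match(pssm$query, PSSM_ALPHABET))]
  s <- residue_humanness(m_ir, pssm$query)

  keep <- !is.na(regions)
  is_cdr <- keep & regions != "FR"
  is_fr <- keep & regions == "FR"
  if (!any(is_cdr)) warning("no CDR positions in mapping; cdr_sum is 0")

  list(per_position_score = stats::setNames(s, pssm$positions),
       cdr_sum = sum(s[is_cdr]),
       framework_sum = sum(s[is_fr]),
       cdr_rare_count = sum(is_rare_residue(s[is_cdr])),
       framework_rare_count = sum(is_rare_residue(s[is_fr])))
}
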