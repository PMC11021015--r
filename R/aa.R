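# Amino-acid lookup tables shared across modules.

#' Standard amino acids
#'
#' One-letter codes for the twenty proteinogenic amino acids, in
#' alphabetical order. The stop symbol is `"*"` and is not included.
#'
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# three-letter <-> one-letter, stop rendered "Ter" in HGVS output
.AA_THREE <- c(
  A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
  H = "His", I = "Ile", K = "Lys", L = "Leu", M = "Met", N = "Asn",
  P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr", V = "Val",
  W = "Trp", Y = "Tyr", `*` = "Ter"
)
.AA_ONE <- stats::setNames(names(.AA_THREE), unname(.AA_THREE))

#' Convert between one-letter and three-letter amino-acid codes
#'
#' @param x Character vector of codes. `aa_three()` expects one-letter codes
#'   (stop as `"*"`); `aa_one()` expects three-letter codes (stop as `"Ter"`).
#' @return Character vector of the converted codes.
#' @examples
#' aa_three(c("E", "K", "*"))
#' aa_one(c("Glu", "Ter"))
#' @export
aa_three <- function(x) {
  out <- unname(.AA_THREE[x])
  if (anyNA(out) && !anyNA(x)) {
    bad <- unique(x[is.na(out)])
    stop("unknown one-letter amino-acid code(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  out <- unname(.AA_ONE[x])
  if (anyNA(out) && !anyNA(x)) {
    bad <- unique(x[is.na(out)])
    stop("unknown three-letter amino-acid code(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Theoretical maximum solvent accessibility per residue
#'
#' Theoretical maximum accessible surface areas (in square angstrom) used to
#' normalize absolute per-residue SASA to relative solvent accessibility
#' (rASA). Values follow the theoretically derived maxima of Tien and
#' colleagues, the standard normalization in structural bioinformatics.
#' The table is plain data and can be swapped for an empirical one via the
#' `max_asa` argument of [compute_rasa()].
#'
#' @format Named numeric vector, names are one-letter amino-acid codes.
#' @export
MAX_ASA_THEORETICAL <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  E = 223.0, Q = 225.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# van der Waals radii (angstrom) by element for the surface computation;
# hydrogens are excluded upstream so no H radius is needed.
.VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)
.VDW_DEFAULT <- 1.70

# backbone heavy-atom names used to split sidechain from backbone
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Parse simple protein-level HGVS strings
#'
#' Parses strings of the form `p.Glu157Lys`, `p.Trp99Ter` (or `p.Trp99*`),
#' and the synonymous forms `p.Glu157=` / `p.Glu157Glu` into a
#' (position, wt_aa, alt_aa) triple. Only single-substitution descriptions
#' are supported.
#'
#' @param x Character vector of HGVS protein strings.
#' @return A tibble with columns `position`, `wt_aa`, `alt_aa`.
#' @examples
#' parse_pro_hgvs(c("p.Glu157Lys", "p.Trp99Ter", "p.Ala12="))
#' @export
parse_pro_hgvs <- function(x) {
  m <- regmatches(x, regexec("^p\\.([A-Za-z]{3})([0-9]+)(=|\\*|[A-Za-z]{3})$", x))
  bad <- which(lengths(m) != 4L)
  if (length(bad) > 0L) {
    stop(
      "malformed protein HGVS string(s) at element(s) ",
      paste(utils::head(bad, 5L), collapse = ", "), ": ",
      paste(utils::head(x[bad], 5L), collapse = ", ")
    )
  }
  wt <- aa_one(vapply(m, `[`, "", 2L))
  pos <- as.integer(vapply(m, `[`, "", 3L))
  alt_raw <- vapply(m, `[`, "", 4L)
  alt <- ifelse(alt_raw == "=", wt,
    ifelse(alt_raw == "*", "*", aa_one(ifelse(alt_raw %in% c("=", "*"), "Ter", alt_raw)))
  )
  tibble::tibble(position = pos, wt_aa = wt, alt_aa = alt)
}

#' Format variants as simple protein-level HGVS strings
#'
#' The inverse of [parse_pro_hgvs()]: stop gains are rendered with `Ter`,
#' synonymous changes with the `=` shorthand.
#'
#' @param position Integer residue positions.
#' @param wt_aa,alt_aa One-letter codes (stop as `"*"`).
#' @return Character vector of `p.` strings.
#' @examples
#' format_pro_hgvs(157, "E", "K")
#' @export
format_pro_hgvs <- function(position, wt_aa, alt_aa) {
  suffix <- ifelse(alt_aa == wt_aa, "=", aa_three(alt_aa))
  paste0("p.", aa_three(wt_aa), position, suffix)
}
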