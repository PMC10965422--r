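#' Amino-acid alphabet used throughout the package
#'
#' Twenty canonical one-letter amino-acid codes in alphabetical order plus
#' the symbol \code{"X"} for unknown/non-canonical residues. Internal token
#' ids are the positions 1..20 in this vector; token 21 is the special
#' MASK token used for residues whose identity is hidden from the model.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_ALPHABET
#' @export
AA_UNKNOWN <- "X"

#' @rdname AA_ALPHABET
#' @export
MASK_TOKEN <- 21L

# three-letter <-> one-letter maps (PDB residue names)
AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

aa_to_three <- function(aa) {
  out <- unname(AA_THREE[aa])
  out[is.na(out)] <- "UNK"
  out
}

aa_from_three <- function(resid) {
  out <- unname(AA_ONE[resid])
  out[is.na(out)] <- AA_UNKNOWN
  out
}

#' Convert amino-acid letters to integer tokens
#'
#' Canonical residues map to 1..20 (alphabetical order of one-letter
#' codes); unknown residues map to \code{NA}; pass \code{mask = TRUE}
#' rows to obtain the MASK token (21).
#'
#' @param aa character vector of one-letter codes.
#' @return integer vector; \code{NA} for unknown residues.
#' @keywords internal
aa_to_token <- function(aa) {
  match(aa, AA_ALPHABET)
}

token_to_aa <- function(tok) {
  out <- rep(AA_UNKNOWN, length(tok))
  ok <- !is.na(tok) & tok >= 1L & tok <= 20L
  out[ok] <- AA_ALPHABET[tok[ok]]
  out
}
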