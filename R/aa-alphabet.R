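#' Residue alphabet and atom naming conventions
#'
#' The package uses the fixed AlphaFold-style integer encoding of amino
#' acids: the twenty canonical residues in the order
#' A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V map to indices 0--19, unknown
#' (X) maps to 20, and the shared gap/mask symbol to 21.  Heavy atoms are
#' stored in the fixed 37-slot ("atom37") layout.
#'
#' @name residue-alphabet
#' @keywords internal
NULL

# one-letter codes, index 0-based: 0..19 canonical, 20 = X
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' @rdname residue-alphabet
#' @format NULL
#' @export
AA_UNKNOWN <- 20L

#' Integer index of the shared gap/mask symbol (no one-letter code).
#' @rdname residue-alphabet
#' @format NULL
#' @export
AA_GAP <- 21L

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
              X = "UNK")

# atom37 heavy-atom slot names (AlphaFold2 ordering); slot indices are
# 1-based in R, so CA is slot 2.
ATOM37 <- c("N", "CA", "C", "CB", "O", "CG", "CG1", "CG2", "OG", "OG1",
            "SG", "CD", "CD1", "CD2", "ND1", "ND2", "OD1", "OD2", "SD",
            "CE", "CE1", "CE2", "CE3", "NE", "NE1", "NE2", "NH1", "NH2",
            "NZ", "OE1", "OE2", "OH", "CZ", "CZ2", "CZ3", "CH2", "OXT")

SLOT_N  <- 1L
SLOT_CA <- 2L
SLOT_C  <- 3L
SLOT_CB <- 4L
SLOT_O  <- 5L

#' Encode a residue string as integer indices
#'
#' @param sequence character scalar using the one-letter amino-acid
#'   alphabet (plus \code{X} for unknown).
#' @return integer vector of indices in \code{[0, 20]}.
#' @examples
#' encode_sequence("ACDEF")
#' @export
encode_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_LETTERS)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("illegal residue character '%s' at position %d",
                 chars[bad], bad), call. = FALSE)
  }
  idx - 1L
}

#' Decode integer residue indices back to a string
#'
#' Gap/mask cells (index 21) decode to \code{"-"}.
#'
#' @param aatype integer vector with values in \code{[0, 21]}.
#' @return character scalar.
#' @export
decode_sequence <- function(aatype) {
  stopifnot(all(aatype >= 0L & aatype <= AA_GAP))
  out <- c(AA_LETTERS, "-")[aatype + 1L]
  paste(out, collapse = "")
}

aa_three_letter <- function(aatype) {
  unname(AA_THREE[c(AA_LETTERS, "-")[pmin(aatype, AA_UNKNOWN) + 1L]])
}

aa_from_three <- function(resname) {
  idx <- match(resname, AA_THREE)
  ifelse(is.na(idx), AA_UNKNOWN + 1L, idx) - 1L
}

atom_slot <- function(atom_name) match(atom_name, ATOM37)

atom_element <- function(slot) substr(ATOM37[slot], 1L, 1L)
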