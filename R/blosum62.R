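# Amino-acid alphabet and BLOSUM62 substitution scoring.

#' Canonical amino-acid codes
#'
#' The 20 canonical one-letter amino-acid codes, in the conventional
#' substitution-matrix order.
#'
#' @format Character vector of length 20.
#' @export
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Three-letter <-> one-letter residue name maps (canonical residues only).
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

# Standard NCBI BLOSUM62 half-bit integer matrix, rows/cols in AA_CODES order.
BLOSUM62_MATRIX <- matrix(c(
   4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,  # A
  -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,  # R
  -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,  # N
  -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,  # D
   0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,  # C
  -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,  # Q
  -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,  # E
   0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,  # G
  -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,  # H
  -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,  # I
  -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,  # L
  -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,  # K
  -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,  # M
  -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,  # F
  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,  # P
   1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,  # S
   0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,  # T
  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,  # W
  -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,  # Y
   0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4   # V
), nrow = 20, byrow = TRUE, dimnames = list(AA_CODES, AA_CODES))

check_aa <- function(aa, arg = "amino acid") {
  bad <- !(aa %in% AA_CODES)
  if (any(bad)) {
    stop(sprintf("non-canonical %s code(s): %s (must be one of %s)",
                 arg, paste(unique(aa[bad]), collapse = ", "),
                 paste(AA_CODES, collapse = "")),
         call. = FALSE)
  }
  invisible(aa)
}

#' BLOSUM62 substitution penalty
#'
#' Returns the difference between the BLOSUM62 self-substitution score of the
#' reference residue and the score of the reference-to-alternate substitution:
#' `S(ref, ref) - S(ref, alt)`, with `S` the standard NCBI BLOSUM62 half-bit
#' integer matrix. The value is 0 exactly when `ref == alt` and positive
#' otherwise (the diagonal dominates every row of BLOSUM62); larger values
#' mark substitutions that are more evolutionarily disfavoured.
#'
#' @param ref_aa,alt_aa One-letter amino-acid codes (vectorised; recycled to
#'   common length). Only the 20 canonical codes are accepted; ambiguity
#'   codes (B, Z, X), selenocysteine (U) and stops (`*`) are rejected.
#' @return Integer vector of half-bit score differences.
#' @examples
#' delta_blosum62("A", "A")  # 0
#' delta_blosum62("M", "V")  # 4
#' delta_blosum62("W", "A")  # 14
#' @export
delta_blosum62 <- function(ref_aa, alt_aa) {
  check_aa(ref_aa, "reference amino acid")
  check_aa(alt_aa, "alternate amino acid")
  n <- max(length(ref_aa), length(alt_aa))
  ref_aa <- rep_len(ref_aa, n)
  alt_aa <- rep_len(alt_aa, n)
  as.integer(BLOSUM62_MATRIX[cbind(ref_aa, ref_aa)] -
             BLOSUM62_MATRIX[cbind(ref_aa, alt_aa)])
}
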