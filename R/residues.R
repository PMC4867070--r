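#' Hydrophobic residue alphabet
#'
#' The fixed nine-residue set counted as hydrophobic throughout the package:
#' phenylalanine (F), isoleucine (I), leucine (L), methionine (M), valine
#' (V), tryptophan (W), glycine (G), cysteine (C) and alanine (A). The
#' hydrophobic percentage of a sequence is the percent of its residues that
#' belong to this set; no graded hydrophobicity scale is used.
#'
#' @format character vector of 9 one-letter residue codes.
#' @export
HYDROPHOBIC_RESIDUES <- c("F", "I", "L", "M", "V", "W", "G", "C", "A")

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes. Sequences containing anything
#' else (including ambiguity codes B, Z, X and the rare U, O) are rejected
#' rather than silently classified, since a misclassified residue would
#' corrupt the hydrophobic percentage.
#'
#' @format character vector of 20 one-letter residue codes.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
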